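#' @export
print.mmcp <- function(x, ...) {
  cat(sprintf(
    "Multi-metric change-point fit (c = %d, %s search)\n",
    x$c, x$method
  ))
  if (!x$feasible) {
    cat("  no migration estimable under the given constraints\n")
    return(invisible(x))
  }
  cat(sprintf("  change-points: %s\n", paste(signif(x$params$t, 6),
    collapse = ", "
  )))
  cat(sprintf(
    "  rho0 = %.4g, rho_mig = %s | kappa0 = %.4g, kappa_mig = %s\n",
    x$params$rho0, paste(signif(x$params$rho_mig, 4), collapse = ", "),
    x$params$kappa0, paste(signif(x$params$kappa_mig, 4), collapse = ", ")
  ))
  cat(sprintf(
    "  NLL = %.4f, AIC = %.4f (k = %d), R = %s\n",
    x$nll, x$aic, x$k, paste(signif(x$R, 5), collapse = ", ")
  ))
  invisible(x)
}

#' @export
summary.mmcp <- function(object, ...) {
  out <- list(
    fit = object,
    coef = if (object$feasible) coef(object) else numeric(0),
    durations = if (object$feasible) {
      tv <- object$params$t
      tv[seq(2, length(tv), 2)] - tv[seq(1, length(tv), 2)]
    } else {
      numeric(0)
    },
    n_candidates = object$n_evaluated
  )
  class(out) <- "summary.mmcp"
  out
}

#' @export
print.summary.mmcp <- function(x, ...) {
  print(x$fit)
  if (x$fit$feasible) {
    cat(sprintf(
      "  migration duration(s): %s; %d terms (%d steps, %d angles); %d candidates evaluated\n",
      paste(x$durations, collapse = ", "), x$fit$n_r + x$fit$n_phi,
      x$fit$n_r, x$fit$n_phi, x$n_candidates
    ))
    cat("  stage log:\n")
    print(x$fit$stages, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.mmcp <- function(object, ...) {
  if (!object$feasible) {
    return(numeric(0))
  }
  p <- object$params
  tv <- p$t
  out <- c(
    tv, p$rho0, p$rho_mig, p$kappa0, p$kappa_mig
  )
  names(out) <- c(
    paste0("t", seq_along(tv)), "rho0",
    paste0("rho", seq_along(p$rho_mig)), "kappa0",
    paste0("kappa", seq_along(p$kappa_mig))
  )
  out
}

#' @export
logLik.mmcp <- function(object, ...) {
  structure(-object$nll,
    df = object$k, nobs = object$n_r + object$n_phi,
    class = "logLik"
  )
}

#' Classify evaluation times as migratory or not from a fit
#'
#' Applies the fitted migratory indicator at each time: label 1 exactly where
#' the time lies in some fitted \eqn{(t_{2n-1}, t_{2n}]}. An infeasible fit
#' yields all zeros with attribute \code{"infeasible" = TRUE}.
#'
#' @param fit An \code{mmcp} fit.
#' @param times Evaluation time grid.
#' @return Integer 0/1 labels.
#' @export
classify_timesteps <- function(fit, times) {
  stopifnot(inherits(fit, "mmcp"))
  if (!fit$feasible) {
    return(structure(integer(length(times)), infeasible = TRUE))
  }
  as.integer(migratory_indicator(times, fit$params))
}

#' @export
predict.mmcp <- function(object, times = object$steps$time, ...) {
  classify_timesteps(object, times)
}

#' @export
fitted.mmcp <- function(object, ...) {
  stopifnot(object$feasible)
  active_params(object$steps$time, object$params)$rho
}

#' @export
residuals.mmcp <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  stopifnot(object$feasible)
  rho <- fitted(object)
  res <- object$steps$r - rho
  if (type == "pearson") res <- res / rho # exponential: sd == mean
  res
}

#' @export
plot.mmcp <- function(x, ...) {
  steps <- x$steps
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  shade <- function() {
    if (x$feasible) {
      tv <- x$params$t
      for (j in seq(1, length(tv), 2)) {
        graphics::rect(tv[j], graphics::par("usr")[3], tv[j + 1],
          graphics::par("usr")[4],
          col = grDevices::adjustcolor("steelblue", 0.2), border = NA
        )
      }
    }
  }
  graphics::plot(steps$time, steps$r,
    type = "h", xlab = "time (days)",
    ylab = "step length", main = "step lengths", ...
  )
  shade()
  if (x$feasible) {
    graphics::lines(steps$time, fitted(x), col = "firebrick", lwd = 2)
  }
  graphics::plot(steps$time, steps$phi,
    pch = 16, cex = 0.5,
    xlab = "time (days)", ylab = "turning angle",
    ylim = c(-pi, pi), main = "turning angles"
  )
  shade()
  invisible(x)
}

#' Simulate step series from a fitted model
#'
#' Parametric simulation used by the bootstrap: each replicate preserves the
#' template's times and validity masks ("same size and temporal extent"),
#' drawing valid step lengths from the exponential regime and valid turning
#' angles from the zero-mean von Mises regime active at that entry's time.
#'
#' @param object A feasible \code{mmcp} fit.
#' @param nsim Number of replicate series.
#' @param seed Optional seed set before drawing.
#' @param template Step series providing times and masks (default: the data
#'   the model was fitted to).
#' @param ... Unused.
#' @return A list of \code{nsim} \code{mmcp_steps} objects.
#' @export
simulate.mmcp <- function(object, nsim = 1, seed = NULL,
                          template = object$steps, ...) {
  stopifnot(object$feasible)
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simulate_from_fit(object$params, template), simplify = FALSE)
}

#' @export
confint.mmcp <- function(object, parm, level = 0.95, boot = NULL,
                         n_paths = 100, seed = 1, ...) {
  if (is.null(boot)) {
    boot <- mmcp_bootstrap(object, n_paths = n_paths, seed = seed,
      level = level)
  }
  ci <- boot$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
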