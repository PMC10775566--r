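#' Per-timestep classification profile across replicate fits
#'
#' The replicate-level evaluation: for each time on the grid, the fraction of
#' replicate fits that classify it migratory. When the true change-points
#' are supplied, per-replicate change-point errors
#' (\eqn{\hat t_i - t_i}) are reported with their median and median absolute
#' deviation (robust to the occasional wild fit).
#'
#' @param fits List of \code{mmcp} fits of replicates of one condition.
#' @param times Evaluation time grid.
#' @param true_changepoints Optional numeric vector of the generating
#'   change-points.
#' @param model_tag Optional label for the condition.
#' @return A list of class \code{mmcp_profile}: \code{times},
#'   \code{prop_migratory}, \code{n_reps}, and (when truth is given)
#'   \code{errors}, \code{median_error}, \code{mad_error}.
#' @export
build_profile <- function(fits, times, true_changepoints = NULL,
                          model_tag = NULL) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "mmcp")))
  lab <- vapply(fits, classify_timesteps, integer(length(times)),
    times = times
  )
  lab <- matrix(lab, nrow = length(times))
  out <- list(
    times = times, prop_migratory = rowMeans(lab), n_reps = length(fits),
    model_tag = model_tag
  )
  if (!is.null(true_changepoints)) {
    est <- t(vapply(fits, function(f) {
      if (f$feasible) f$params$t else rep(NA_real_, length(true_changepoints))
    }, numeric(length(true_changepoints))))
    err <- sweep(est, 2, true_changepoints)
    colnames(err) <- paste0("t", seq_along(true_changepoints), "_err")
    out$errors <- err
    out$median_error <- apply(err, 2, stats::median, na.rm = TRUE)
    out$mad_error <- apply(err, 2, stats::mad, na.rm = TRUE)
  }
  structure(out, class = "mmcp_profile")
}

#' @export
print.mmcp_profile <- function(x, ...) {
  cat(sprintf(
    "classification profile%s: %d replicates, %d times\n",
    if (!is.null(x$model_tag)) paste0(" [", x$model_tag, "]") else "",
    x$n_reps, length(x$times)
  ))
  if (!is.null(x$median_error)) {
    cat("  median change-point error: ",
      paste(sprintf("%s = %g", names(x$median_error), x$median_error),
        collapse = ", "
      ), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Non-migratory range segments of a two-migration fit
#'
#' For a \code{c = 2} fit, partitions a track's locations into the three
#' non-migratory ranges: before \eqn{t_1}, between \eqn{t_2} and \eqn{t_3},
#' and after \eqn{t_4}. Boundaries follow the indicator's half-open
#' convention: a location at exactly \eqn{t_1} is non-migratory, at exactly
#' \eqn{t_2} migratory.
#'
#' @param track An \code{mmcp_track}.
#' @param fit A feasible \code{mmcp} fit with \code{c = 2}.
#' @return A list of three data frames (possibly empty, with a warning).
#' @export
segment_ranges <- function(track, fit) {
  stopifnot(inherits(track, "mmcp_track"), inherits(fit, "mmcp"),
    fit$feasible, fit$c == 2)
  tv <- fit$params$t
  tt <- track$time
  sets <- list(
    before = tt <= tv[1],
    between = tt > tv[2] & tt <= tv[3],
    after = tt > tv[4]
  )
  out <- lapply(sets, function(keep) {
    as.data.frame(track)[keep, c("time", "x", "y"), drop = FALSE]
  })
  empty <- vapply(out, nrow, integer(1)) == 0
  if (any(empty)) {
    warning(sprintf(
      "empty non-migratory segment(s): %s",
      paste(names(out)[empty], collapse = ", ")
    ))
  }
  out
}

#' Bhattacharyya affinity between two location sets under Gaussian ranges
#'
#' Fits a bivariate Gaussian (sample mean and covariance) to each segment and
#' evaluates the closed-form Bhattacharyya affinity
#' \eqn{BA = \exp(-D_B)} with
#' \deqn{D_B = \tfrac18 (\mu_A-\mu_B)^\top \bar\Sigma^{-1} (\mu_A-\mu_B)
#'   + \tfrac12 \log\left(\det\bar\Sigma / \sqrt{\det\Sigma_A\det\Sigma_B}\right),}
#' \eqn{\bar\Sigma = (\Sigma_A + \Sigma_B)/2}. BA lies in [0, 1]; 1 iff the
#' two fitted Gaussians coincide. A deliberately simple parametric surrogate
#' for range overlap: it is exact for the Gaussian range model and fully
#' closed-form.
#'
#' @param segA,segB Data frames with columns \code{x}, \code{y} and at least
#'   3 non-collinear locations each.
#' @return A list: \code{ba} (NA when undefined), \code{defined}.
#' @export
gaussian_bhattacharyya <- function(segA, segB) {
  fitg <- function(s) {
    if (nrow(s) < 3) return(NULL)
    m <- c(mean(s$x), mean(s$y))
    S <- stats::cov(cbind(s$x, s$y))
    if (!all(is.finite(S)) || det(S) <= 1e-12) return(NULL)
    list(mu = m, S = S)
  }
  ga <- fitg(segA)
  gb <- fitg(segB)
  if (is.null(ga) || is.null(gb)) {
    return(list(ba = NA_real_, defined = FALSE))
  }
  Sbar <- (ga$S + gb$S) / 2
  dmu <- ga$mu - gb$mu
  db <- as.numeric(dmu %*% solve(Sbar, dmu)) / 8 +
    0.5 * log(det(Sbar) / sqrt(det(ga$S) * det(gb$S)))
  list(ba = exp(-db), defined = TRUE)
}

#' Pairwise non-migratory range overlaps for a two-migration fit
#'
#' Convenience wrapper: segments the track with \code{\link{segment_ranges}}
#' and computes the Gaussian Bhattacharyya affinity for each pair of ranges.
#'
#' @inheritParams segment_ranges
#' @return A data frame with columns \code{pair} and \code{ba}.
#' @export
range_overlaps <- function(track, fit) {
  segs <- segment_ranges(track, fit)
  pairs <- utils::combn(names(segs), 2)
  data.frame(
    pair = apply(pairs, 2, paste, collapse = "-"),
    ba = apply(pairs, 2, function(p) {
      gaussian_bhattacharyya(segs[[p[1]]], segs[[p[2]]])$ba
    })
  )
}
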