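#' Construct an MMCP parameter set
#'
#' Parameters of the multi-metric change-point model with \code{c} migratory
#' periods: change-point times \eqn{t_1 < \dots < t_{2c}}, a baseline mean
#' step length \eqn{\rho_0 > 0} and angular concentration
#' \eqn{\kappa_0 \ge 0}, and non-negative per-period increments
#' \eqn{\rho_n, \kappa_n} that apply while the animal is migrating. With
#' \code{shared_mig = TRUE} a single increment pair applies to every period.
#'
#' @param t Change-point times, strictly increasing, length \code{2c}.
#' @param rho0 Baseline mean step length (> 0).
#' @param rho_mig Per-period step-length increments (length \code{c}, or 1 if
#'   shared), all \eqn{\ge 0}.
#' @param kappa0 Baseline concentration (\eqn{\ge 0}).
#' @param kappa_mig Per-period concentration increments, all \eqn{\ge 0}.
#' @param shared_mig Single shared increment pair across periods?
#' @return An object of class \code{mmcp_params}.
#' @export
mmcp_params <- function(t, rho0, rho_mig, kappa0, kappa_mig,
                        shared_mig = FALSE) {
  stopifnot(
    length(t) >= 2, length(t) %% 2 == 0, all(diff(t) > 0),
    is.finite(rho0), rho0 > 0, all(rho_mig >= 0), kappa0 >= 0,
    all(kappa_mig >= 0)
  )
  c_periods <- length(t) / 2
  n_mig <- if (shared_mig) 1L else c_periods
  stopifnot(length(rho_mig) == n_mig, length(kappa_mig) == n_mig)
  structure(
    list(
      c = c_periods, t = as.numeric(t), rho0 = rho0,
      rho_mig = as.numeric(rho_mig), kappa0 = kappa0,
      kappa_mig = as.numeric(kappa_mig), shared_mig = shared_mig
    ),
    class = "mmcp_params"
  )
}

#' @export
print.mmcp_params <- function(x, ...) {
  cat(sprintf(
    "MMCP parameters (c = %d%s)\n  t: %s\n  rho0 = %.4g, rho_mig = %s\n  kappa0 = %.4g, kappa_mig = %s\n",
    x$c, if (x$shared_mig) ", shared increments" else "",
    paste(signif(x$t, 6), collapse = ", "), x$rho0,
    paste(signif(x$rho_mig, 4), collapse = ", "), x$kappa0,
    paste(signif(x$kappa_mig, 4), collapse = ", ")
  ))
  invisible(x)
}

# Migratory period index for each time: n when t_{2n-1} < time <= t_{2n},
# else 0. Uses the half-open (t_{2n-1}, t_{2n}] convention throughout.
mig_period <- function(time, t_changepoints) {
  pos <- findInterval(time, t_changepoints, left.open = TRUE)
  ifelse(pos %% 2 == 1, (pos + 1) / 2, 0L)
}

#' Migratory indicator
#'
#' Evaluates the model's behavioural indicator: 1 when \eqn{t} lies in
#' \eqn{(t_{2n-1}, t_{2n}]} for some migratory period \eqn{n}, else 0. The
#' left endpoint is excluded and the right endpoint included. The period
#' index (0 outside migration) is attached as attribute \code{"period"} for
#' parameter lookup.
#'
#' @param time Numeric time(s) in days.
#' @param params An \code{mmcp_params} object, or a numeric vector of
#'   change-point times.
#' @return Integer vector of 0/1 with attribute \code{"period"}.
#' @export
migratory_indicator <- function(time, params) {
  tv <- if (inherits(params, "mmcp_params")) params$t else as.numeric(params)
  per <- mig_period(time, tv)
  structure(as.integer(per > 0), period = as.integer(per))
}

#' Per-point negative log-likelihood
#'
#' One location's contribution under the active regime: an exponential term
#' \eqn{\log\rho + r/\rho} for the step length (when present) plus a von
#' Mises term \eqn{\log 2\pi + \log I_0(\kappa) - \kappa\cos\phi} for the
#' turning angle (when present, mean direction fixed at 0). Absent
#' (\code{NA}) components contribute nothing. \eqn{\log I_0} is evaluated on
#' the log scale so large concentrations never overflow.
#'
#' @param r Step length(s), \code{NA} where absent.
#' @param phi Turning angle(s), \code{NA} where absent.
#' @param active_rho Active mean step length (> 0), recycled.
#' @param active_kappa Active concentration (\eqn{\ge 0}), recycled.
#' @return Numeric vector of negative log-likelihood contributions.
#' @export
point_nll <- function(r, phi, active_rho, active_kappa) {
  if (any(!is.na(r) & !is.finite(r)) || any(!is.na(phi) & !is.finite(phi))) {
    stop("numeric error: non-finite step length or turning angle")
  }
  stopifnot(all(is.finite(active_rho)), all(active_rho > 0),
    all(is.finite(active_kappa)), all(active_kappa >= 0))
  n <- max(length(r), length(phi))
  r <- rep_len(r, n)
  phi <- rep_len(phi, n)
  rho <- rep_len(active_rho, n)
  kap <- rep_len(active_kappa, n)
  out <- numeric(n)
  hr <- !is.na(r)
  out[hr] <- log(rho[hr]) + r[hr] / rho[hr]
  hp <- !is.na(phi)
  out[hp] <- out[hp] + log(2 * pi) + log_bessel_i0(kap[hp]) -
    kap[hp] * cos(phi[hp])
  out
}

# Active (rho, kappa) per entry time for a parameter set.
active_params <- function(time, params) {
  per <- mig_period(time, params$t)
  idx <- if (params$shared_mig) pmin(per, 1L) else per
  rho_inc <- c(0, params$rho_mig)[idx + 1L]
  kap_inc <- c(0, params$kappa_mig)[idx + 1L]
  list(rho = params$rho0 + rho_inc, kappa = params$kappa0 + kap_inc)
}

#' Total negative log-likelihood of a step series
#'
#' Sum of \code{\link{point_nll}} over all entries, each evaluated under the
#' regime selected by the migratory indicator at that entry's time. Masked
#' components contribute nothing.
#'
#' @param steps An \code{mmcp_steps} object.
#' @param params An \code{mmcp_params} object.
#' @return The total negative log-likelihood (scalar).
#' @export
total_nll <- function(steps, params) {
  stopifnot(inherits(steps, "mmcp_steps"), inherits(params, "mmcp_params"))
  ap <- active_params(steps$time, params)
  sum(point_nll(steps$r, steps$phi, ap$rho, ap$kappa))
}

#' Profile maximum-likelihood estimates at fixed change-points
#'
#' With the change-points held fixed, the step-length and turning-angle
#' components separate and the distributional parameters have (near-)closed
#' forms: \eqn{\hat\rho_0} is the mean of all non-migratory step lengths,
#' \eqn{\hat\kappa_0} inverts the Bessel ratio against the mean cosine of the
#' non-migratory turning angles (mean direction fixed at 0), and each
#' migratory period's increments are the same estimates computed within the
#' period minus the baselines, truncated at 0 (migration is hypothesized to
#' be faster and more directed, not less).
#'
#' @param steps An \code{mmcp_steps} object.
#' @param t Candidate change-point times (length \code{2c}).
#' @param shared_mig Pool all migratory periods into one increment pair?
#' @param min_segment Minimum valid step-length entries per pool (default 2);
#'   each pool additionally needs at least one valid turning angle.
#' @param kappa_cap Upper clamp for concentration estimates.
#' @return An \code{mmcp_params} object with a logical
#'   \code{"kappa_capped"} attribute, or \code{NULL} when some pool is too
#'   small or degenerate (the candidate is infeasible).
#' @export
profile_mle <- function(steps, t, shared_mig = FALSE, min_segment = 2,
                        kappa_cap = 500) {
  stopifnot(inherits(steps, "mmcp_steps"), length(t) %% 2 == 0, all(diff(t) > 0))
  c_periods <- length(t) / 2
  per <- mig_period(steps$time, t)
  pool <- if (shared_mig) pmin(per, 1L) else per
  n_pools <- if (shared_mig) 1L else c_periods
  r <- steps$r[steps$valid_r]
  pr <- pool[steps$valid_r]
  cphi <- cos(steps$phi[steps$valid_phi])
  pp <- pool[steps$valid_phi]
  for (g in 0:n_pools) {
    if (sum(pr == g) < min_segment || sum(pp == g) < 1) return(NULL)
  }
  rho0 <- mean(r[pr == 0])
  if (!(rho0 > 0)) return(NULL)
  k0 <- kappa_from_meancos(mean(cphi[pp == 0]), cap = kappa_cap)
  capped <- attr(k0, "capped")
  rho_mig <- kappa_mig <- numeric(n_pools)
  for (g in seq_len(n_pools)) {
    rho_mig[g] <- max(0, mean(r[pr == g]) - rho0)
    kg <- kappa_from_meancos(mean(cphi[pp == g]), cap = kappa_cap)
    capped <- capped | attr(kg, "capped")
    kappa_mig[g] <- max(0, as.numeric(kg) - as.numeric(k0))
  }
  out <- mmcp_params(
    t = t, rho0 = rho0, rho_mig = rho_mig, kappa0 = as.numeric(k0),
    kappa_mig = kappa_mig, shared_mig = shared_mig
  )
  attr(out, "kappa_capped") <- any(capped)
  out
}

#' Speed ratio of a migratory period
#'
#' \eqn{R = (\rho_0 + \rho_n)/\rho_0}: the proportional increase in mean
#' step length during migration. \eqn{R = 1} means no increase.
#'
#' @param params An \code{mmcp_params} object.
#' @param period Migratory period index (default 1).
#' @return The speed ratio, \eqn{\ge 1}.
#' @export
speed_ratio <- function(params, period = 1) {
  stopifnot(inherits(params, "mmcp_params"), params$rho0 > 0)
  idx <- if (params$shared_mig) 1L else as.integer(period)
  stopifnot(idx >= 1, idx <= length(params$rho_mig))
  (params$rho0 + params$rho_mig[idx]) / params$rho0
}
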