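#' Specification for a switching correlated velocity movement (CVM) process
#'
#' The CVM is a continuous-time movement model whose 2D velocity follows an
#' Ornstein-Uhlenbeck process with autocorrelation timescale \eqn{\tau} and
#' stationary per-axis standard deviation \eqn{\sigma = \nu\sqrt{2/\pi}}, so
#' the stationary mean speed is \eqn{\nu}. Parameters follow a three-phase
#' schedule (before / during / after migration) switching at the switch
#' times; a time \eqn{t} is in the migratory phase iff
#' \eqn{s_1 < t \le s_2}.
#'
#' @param nu Mean speed per phase (length 3, spatial units per time unit).
#' @param tau Autocorrelation timescale per phase (length 3).
#' @param switch_times Phase switch times (default \code{c(100, 200)}).
#' @param T Path duration in output timesteps (default 300).
#' @param dt_out Output sampling interval (default 1).
#' @param dt_internal Integration substep (default 0.1).
#' @return A list of class \code{cvm_spec}.
#' @export
cvm_spec <- function(nu = c(1, 5, 1), tau = c(2, 2, 2),
                     switch_times = c(100, 200), T = 300, dt_out = 1,
                     dt_internal = 0.1) {
  stopifnot(
    length(nu) == 3, length(tau) == 3, all(nu > 0), all(tau > 0),
    length(switch_times) == 2, all(diff(switch_times) > 0),
    switch_times[1] > 0, switch_times[2] < T, dt_internal <= dt_out
  )
  structure(
    list(
      nu = nu, tau = tau, switch_times = switch_times, T = T,
      dt_out = dt_out, dt_internal = dt_internal
    ),
    class = "cvm_spec"
  )
}

#' Preset simulator specifications from the simulation study
#'
#' Three mechanisms of migration over 300 timesteps with migration between
#' times 100 and 200: \code{speed_switch_spec} raises the CVM mean speed
#' from 1 to 5 during migration (constant \eqn{\tau = 2});
#' \code{timescale_switch_spec} keeps speed constant but raises the
#' autocorrelation timescale from 2 to 20 (so directionality, not the speed
#' marginal, changes); \code{bias_switch_spec} is a biased correlated random
#' walk whose attraction point jumps from (0, 0) to (50, 0) and whose
#' attraction strength rises from 0.5 to 0.9 during migration, with
#' unchanged step-length (Weibull shape 1, scale 1) and turning
#' (\eqn{\kappa = 0.5}) distributions.
#'
#' @return A \code{cvm_spec} or \code{bcrw_spec}.
#' @export
speed_switch_spec <- function() cvm_spec(nu = c(1, 5, 1), tau = c(2, 2, 2))

#' @rdname speed_switch_spec
#' @export
timescale_switch_spec <- function() cvm_spec(nu = c(1, 1, 1), tau = c(2, 20, 2))

#' @rdname speed_switch_spec
#' @export
bias_switch_spec <- function() {
  bcrw_spec(
    alpha = 1, beta = 1, kappa_turn = 0.5,
    attraction = rbind(c(0, 0), c(50, 0), c(50, 0)),
    A = c(0.5, 0.9, 0.5)
  )
}

#' Specification for a switching biased correlated random walk (BCRW)
#'
#' A discrete walk whose heading mixes directional persistence with
#' attraction toward a target point: the expected heading is the direction
#' of \eqn{A\,u(\theta) + (1 - A)\,u(h_{prev})} where \eqn{\theta} is the
#' bearing to the phase's attraction point and \eqn{u} the unit vector; the
#' realized heading adds von Mises noise with concentration
#' \code{kappa_turn}, and step lengths are Weibull.
#'
#' @param alpha,beta Weibull shape and scale of step lengths.
#' @param kappa_turn Heading concentration (\eqn{\ge 0}).
#' @param attraction 3 x 2 matrix: attraction point per phase.
#' @param A Attraction strength per phase, each in [0, 1].
#' @param switch_times Phase switch times.
#' @param T Number of steps.
#' @return A list of class \code{bcrw_spec}.
#' @export
bcrw_spec <- function(alpha = 1, beta = 1, kappa_turn = 0.5,
                      attraction = rbind(c(0, 0), c(50, 0), c(50, 0)),
                      A = c(0.5, 0.9, 0.5), switch_times = c(100, 200),
                      T = 300) {
  attraction <- as.matrix(attraction)
  stopifnot(
    alpha > 0, beta > 0, kappa_turn >= 0, nrow(attraction) == 3,
    ncol(attraction) == 2, length(A) == 3, all(A >= 0), all(A <= 1),
    length(switch_times) == 2, all(diff(switch_times) > 0)
  )
  structure(
    list(
      alpha = alpha, beta = beta, kappa_turn = kappa_turn,
      attraction = attraction, A = A, switch_times = switch_times, T = T
    ),
    class = "bcrw_spec"
  )
}

# Phase index at time t: 1 before, 2 during (s1, s2], 3 after.
phase_at <- function(time, switch_times) {
  1L + (time > switch_times[1]) + (time > switch_times[2])
}

labeled_track <- function(time, x, y, switch_times, id, extra = NULL) {
  df <- data.frame(
    time = time, x = x, y = y,
    state = as.integer(time > switch_times[1] & time <= switch_times[2])
  )
  tr <- mmcp_track(df, id = id, dt_nominal = 1)
  for (nm in names(extra)) attr(tr, nm) <- extra[[nm]]
  class(tr) <- c("mmcp_labeled_track", class(tr))
  tr
}

#' Simulate a switching CVM path
#'
#' Velocity is updated with the exact OU transition at each internal substep
#' and position by trapezoidal integration of velocity; output locations are
#' sampled every \code{dt_out}. At a mean-speed switch the current velocity
#' is rescaled by the ratio of stationary standard deviations (keeping its
#' direction, avoiding a boundary transient); at a timescale switch it is
#' carried unchanged. The initial velocity is drawn from the first phase's
#' stationary distribution.
#'
#' @param spec A \code{\link{cvm_spec}}.
#' @param seed Integer seed.
#' @return An \code{mmcp_track} with a \code{state} column (1 = migratory,
#'   exactly for output times in \eqn{(s_1, s_2]}) and a \code{"velocity"}
#'   attribute holding the velocity at each output time.
#' @export
simulate_cvm <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cvm_spec"))
  set.seed(seed)
  dti <- spec$dt_internal
  nsub <- round(spec$T / dti)
  sig <- spec$nu * sqrt(2 / pi)
  v <- stats::rnorm(2, 0, sig[1])
  pos <- matrix(0, nsub + 1, 2)
  vel <- matrix(0, nsub + 1, 2)
  vel[1, ] <- v
  noise <- matrix(stats::rnorm(2 * nsub), nsub, 2)
  ph_prev <- 1L
  for (i in seq_len(nsub)) {
    t_i <- i * dti
    ph <- phase_at(t_i, spec$switch_times)
    if (ph != ph_prev) {
      v <- v * sig[ph] / sig[ph_prev]
      ph_prev <- ph
    }
    a <- exp(-dti / spec$tau[ph])
    vnew <- v * a + noise[i, ] * sig[ph] * sqrt(1 - a^2)
    pos[i + 1, ] <- pos[i, ] + dti * (v + vnew) / 2
    v <- vnew
    vel[i + 1, ] <- v
  }
  stride <- round(spec$dt_out / dti)
  idx <- seq(1, nsub + 1, by = stride)
  times <- (idx - 1) * dti
  labeled_track(times, pos[idx, 1], pos[idx, 2], spec$switch_times,
    id = sprintf("cvm_seed%d", seed),
    extra = list(velocity = vel[idx, , drop = FALSE])
  )
}

#' Simulate a switching BCRW path
#'
#' The first heading is uniform; each subsequent step's expected heading is
#' the vector-weighted circular mean of the previous heading and the bearing
#' to the active phase's attraction point, perturbed by von Mises noise.
#' The phase of the step arriving at time \eqn{t} is migratory iff
#' \eqn{s_1 < t \le s_2}.
#'
#' @param spec A \code{\link{bcrw_spec}}.
#' @param seed Integer seed.
#' @return An \code{mmcp_track} with a \code{state} column.
#' @export
simulate_bcrw <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "bcrw_spec"))
  set.seed(seed)
  n <- spec$T
  pos <- matrix(0, n + 1, 2)
  h <- stats::runif(1, -pi, pi)
  for (t in seq_len(n)) {
    ph <- phase_at(t, spec$switch_times)
    target <- spec$attraction[ph, ]
    A <- spec$A[ph]
    th <- atan2(target[2] - pos[t, 2], target[1] - pos[t, 1])
    w <- A * c(cos(th), sin(th)) + (1 - A) * c(cos(h), sin(h))
    mu <- if (sum(w^2) < 1e-24) h else atan2(w[2], w[1])
    h <- rvonmises(1, mu = mu, kappa = spec$kappa_turn)
    r <- stats::rweibull(1, shape = spec$alpha, scale = spec$beta)
    pos[t + 1, ] <- pos[t, ] + r * c(cos(h), sin(h))
  }
  labeled_track(0:n, pos[, 1], pos[, 2], spec$switch_times,
    id = sprintf("bcrw_seed%d", seed)
  )
}

#' Degrade a track with missingness and coordinate jitter
#'
#' Emulates real telemetry: each location after the first is removed
#' independently with probability \code{p_miss} (the first is always kept so
#' the track stays anchored), and surviving coordinates are perturbed by
#' independent Gaussian noise with per-axis variance \code{sigma_e}. State
#' labels follow the retained locations.
#'
#' @param track An \code{mmcp_track} (possibly labeled).
#' @param p_miss Per-location removal probability in [0, 1) (default 1/12).
#' @param sigma_e Jitter variance per axis (default 0).
#' @param seed Integer seed.
#' @return The degraded track.
#' @export
degrade_track <- function(track, p_miss = 1 / 12, sigma_e = 0, seed = 1) {
  stopifnot(
    inherits(track, "mmcp_track"), p_miss >= 0, p_miss < 1,
    sigma_e >= 0
  )
  set.seed(seed)
  n <- nrow(track)
  keep <- c(TRUE, stats::runif(n - 1) >= p_miss)
  d <- as.data.frame(track)[keep, , drop = FALSE]
  m <- nrow(d)
  if (sigma_e > 0) {
    d$x <- d$x + stats::rnorm(m, 0, sqrt(sigma_e))
    d$y <- d$y + stats::rnorm(m, 0, sqrt(sigma_e))
  }
  out <- mmcp_track(d,
    id = attr(track, "id"),
    dt_nominal = attr(track, "dt_nominal")
  )
  if (inherits(track, "mmcp_labeled_track")) {
    class(out) <- c("mmcp_labeled_track", class(out))
  }
  out
}
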