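#' Search configuration for the change-point grid search
#'
#' @param grid_schedule Strictly decreasing grid resolutions, in units of the
#'   sampling interval (default \code{c(14, 7, 3, 1)}: the coarse grid is
#'   halved repeatedly, truncating decimals so every resolution stays an
#'   integer, down to the finest resolution).
#' @param top_k Number of lowest-NLL candidates carried from each stage to
#'   the next (default 5).
#' @param min_duration Minimum migration duration: every period must satisfy
#'   \eqn{t_{2n} - t_{2n-1} > \code{min_duration}} (default 7; use 14 for
#'   slower terrestrial migrants).
#' @param min_gap Minimum separation between consecutive migratory periods
#'   (default 0: only strict ordering is required).
#' @param min_segment Minimum valid step lengths per parameter pool.
#' @param kappa_cap Upper clamp for concentration estimates.
#' @param bounds Feasible time window for change-points (default: the range
#'   of step times).
#' @param exhaustive_guard Refuse exhaustive searches whose candidate count
#'   exceeds this (default 1e6).
#' @return A list of class \code{mmcp_control}.
#' @export
mmcp_control <- function(grid_schedule = c(14, 7, 3, 1), top_k = 5,
                         min_duration = 7, min_gap = 0, min_segment = 2,
                         kappa_cap = 500, bounds = NULL,
                         exhaustive_guard = 1e6) {
  stopifnot(
    length(grid_schedule) >= 1, all(diff(grid_schedule) < 0) || length(grid_schedule) == 1,
    all(grid_schedule > 0), top_k >= 1, min_duration > 0, min_gap >= 0,
    min_segment >= 1, kappa_cap > 0
  )
  structure(
    list(
      grid_schedule = grid_schedule, top_k = as.integer(top_k),
      min_duration = min_duration, min_gap = min_gap,
      min_segment = as.integer(min_segment), kappa_cap = kappa_cap,
      bounds = bounds, exhaustive_guard = exhaustive_guard
    ),
    class = "mmcp_control"
  )
}

# Precomputed cumulative sums over the valid entries of a step series,
# allowing O(1) pooled sums over any (a, b] time window via findInterval.
steps_cache <- function(steps) {
  rt <- steps$time[steps$valid_r]
  rv <- steps$r[steps$valid_r]
  pt <- steps$time[steps$valid_phi]
  cv <- cos(steps$phi[steps$valid_phi])
  list(
    rt = rt, csr = c(0, cumsum(rv)), pt = pt, csc = c(0, cumsum(cv)),
    n_r = length(rt), n_phi = length(pt)
  )
}

# Vectorized profile NLL over a matrix of candidate change-point tuples.
# cand: n x 2c matrix with strictly increasing rows. Returns the profile
# negative log-likelihood per candidate (Inf where a parameter pool is
# infeasible: fewer than min_segment valid steps or no valid angle or a zero
# baseline mean).
eval_candidates <- function(cache, cand, shared_mig = FALSE, min_segment = 2,
                            kappa_cap = 500) {
  n <- nrow(cand)
  n2c <- ncol(cand)
  c_periods <- n2c / 2
  # pooled counts/sums per migratory period from cumulative sums
  idx_r <- matrix(findInterval(cand, cache$rt), n, n2c)
  idx_p <- matrix(findInterval(cand, cache$pt), n, n2c)
  nr_mig <- sr_mig <- np_mig <- sc_mig <- matrix(0, n, c_periods)
  for (j in seq_len(c_periods)) {
    lo <- 2 * j - 1
    hi <- 2 * j
    nr_mig[, j] <- idx_r[, hi] - idx_r[, lo]
    sr_mig[, j] <- cache$csr[idx_r[, hi] + 1] - cache$csr[idx_r[, lo] + 1]
    np_mig[, j] <- idx_p[, hi] - idx_p[, lo]
    sc_mig[, j] <- cache$csc[idx_p[, hi] + 1] - cache$csc[idx_p[, lo] + 1]
  }
  nr0 <- cache$n_r - rowSums(nr_mig)
  sr0 <- cache$csr[cache$n_r + 1] - rowSums(sr_mig)
  np0 <- cache$n_phi - rowSums(np_mig)
  sc0 <- cache$csc[cache$n_phi + 1] - rowSums(sc_mig)
  if (shared_mig && c_periods > 1) {
    nr_mig <- matrix(rowSums(nr_mig), n, 1)
    sr_mig <- matrix(rowSums(sr_mig), n, 1)
    np_mig <- matrix(rowSums(np_mig), n, 1)
    sc_mig <- matrix(rowSums(sc_mig), n, 1)
  }
  n_pools <- ncol(nr_mig)
  feasible <- nr0 >= min_segment & np0 >= 1
  for (j in seq_len(n_pools)) {
    feasible <- feasible & nr_mig[, j] >= min_segment & np_mig[, j] >= 1
  }
  rho0 <- sr0 / nr0
  feasible <- feasible & is.finite(rho0) & rho0 > 0
  nll <- rep(Inf, n)
  if (!any(feasible)) return(nll)
  f <- which(feasible)
  k0 <- as.numeric(kappa_from_meancos(sc0[f] / np0[f], cap = kappa_cap))
  # baseline pools
  v <- nr0[f] * log(rho0[f]) + sr0[f] / rho0[f] +
    np0[f] * (log(2 * pi) + log_bessel_i0(k0)) - k0 * sc0[f]
  for (j in seq_len(n_pools)) {
    rho_a <- rho0[f] + pmax(0, sr_mig[f, j] / nr_mig[f, j] - rho0[f])
    kj <- as.numeric(kappa_from_meancos(sc_mig[f, j] / np_mig[f, j],
      cap = kappa_cap
    ))
    kap_a <- k0 + pmax(0, kj - k0)
    v <- v + nr_mig[f, j] * log(rho_a) + sr_mig[f, j] / rho_a +
      np_mig[f, j] * (log(2 * pi) + log_bessel_i0(kap_a)) - kap_a * sc_mig[f, j]
  }
  nll[f] <- v
  nll
}

# Order candidate rows lexicographically (t1, then t2, ...).
lex_order <- function(m) {
  do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# First candidate (in lexicographic order) whose NLL is within a relative
# whisker of the minimum: numerically equal NLLs tie, and ties break toward
# the earliest tuple, making the search fully deterministic.
select_best <- function(cand, nll) {
  ord <- lex_order(cand)
  nll <- nll[ord]
  cand <- cand[ord, , drop = FALSE]
  tol <- 1e-9 * max(1, abs(min(nll[is.finite(nll)])))
  cand[which(nll <= min(nll[is.finite(nll)]) + tol)[1], ]
}

# Filter candidate rows for strict ordering, duration and gap constraints.
feasible_geometry <- function(m, min_duration, min_gap) {
  keep <- rep(TRUE, nrow(m))
  n2c <- ncol(m)
  for (j in seq(1, n2c - 1, by = 2)) {
    keep <- keep & (m[, j + 1] - m[, j] > min_duration)
  }
  if (n2c > 2) {
    for (j in seq(2, n2c - 2, by = 2)) {
      keep <- keep & (m[, j + 1] - m[, j] > min_gap) & (m[, j + 1] > m[, j])
    }
  }
  m[keep, , drop = FALSE]
}

#' Enumerate candidate change-point tuples on a grid
#'
#' Without \code{centers}: all ordered tuples on the lattice
#' \eqn{\{t_{min}, t_{min}+g, \dots\}} within bounds satisfying the duration
#' and gap constraints. With \code{centers}: the union over centers of local
#' lattices covering center \eqn{\pm} \code{prev_g} in each coordinate at
#' resolution \code{g} (so the finer lattice always covers the coarse cell),
#' deduplicated and filtered the same way.
#'
#' @param steps An \code{mmcp_steps} object (supplies the default bounds).
#' @param c_periods Number of migratory periods.
#' @param g Grid resolution.
#' @param control An \code{\link{mmcp_control}}.
#' @param centers Optional matrix of carried candidate tuples to refine.
#' @param prev_g Previous (coarser) resolution, required with \code{centers}.
#' @return A matrix with \code{2 * c_periods} columns, rows in lexicographic
#'   order (possibly zero rows when no candidate is feasible).
#' @export
enumerate_changepoints <- function(steps, c_periods, g, control = mmcp_control(),
                                   centers = NULL, prev_g = NULL) {
  bounds <- control$bounds
  if (is.null(bounds)) bounds <- range(steps$time)
  n2c <- 2 * c_periods
  if (is.null(centers)) {
    lattice <- seq(bounds[1], bounds[2], by = g)
    if (length(lattice) < n2c) {
      return(matrix(numeric(0), 0, n2c))
    }
    if (c_periods == 1) {
      i <- rep(seq_along(lattice), each = length(lattice))
      j <- rep(seq_along(lattice), times = length(lattice))
      sel <- j > i
      m <- cbind(lattice[i[sel]], lattice[j[sel]])
    } else {
      m <- t(utils::combn(lattice, n2c))
    }
  } else {
    stopifnot(!is.null(prev_g))
    centers <- as.matrix(centers)
    pieces <- lapply(seq_len(nrow(centers)), function(k) {
      local <- lapply(seq_len(n2c), function(j) {
        v <- seq(centers[k, j] - prev_g, centers[k, j] + prev_g, by = g)
        v[v >= bounds[1] & v <= bounds[2]]
      })
      if (any(lengths(local) == 0)) {
        return(matrix(numeric(0), 0, n2c))
      }
      as.matrix(expand.grid(local))
    })
    m <- do.call(rbind, pieces)
    if (nrow(m) == 0) {
      return(matrix(numeric(0), 0, n2c))
    }
    ord <- rep(TRUE, nrow(m))
    for (j in seq_len(n2c - 1)) ord <- ord & (m[, j + 1] > m[, j])
    m <- m[ord, , drop = FALSE]
    m <- m[!duplicated(m), , drop = FALSE]
  }
  dimnames(m) <- NULL
  m <- feasible_geometry(m, control$min_duration, control$min_gap)
  if (nrow(m) == 0) {
    return(m)
  }
  m[lex_order(m), , drop = FALSE]
}

# Shared finishing step: package the best candidate into an mmcp fit object.
build_fit <- function(steps, c_periods, control, shared_mig, method,
                      best_t, stages, n_evaluated, call) {
  n_r <- sum(steps$valid_r)
  n_phi <- sum(steps$valid_phi)
  k <- if (shared_mig) 2 * c_periods + 4 else 4 * c_periods + 2
  if (is.null(best_t)) {
    fit <- list(
      feasible = FALSE, c = c_periods, params = NULL, nll = NA_real_,
      n_r = n_r, n_phi = n_phi, k = k, aic = NA_real_, R = NA_real_,
      method = method, stages = stages, n_evaluated = n_evaluated,
      control = control, steps = steps, call = call
    )
    class(fit) <- "mmcp"
    return(fit)
  }
  params <- profile_mle(steps, best_t,
    shared_mig = shared_mig,
    min_segment = control$min_segment, kappa_cap = control$kappa_cap
  )
  nll <- total_nll(steps, params)
  fit <- list(
    feasible = TRUE, c = c_periods, params = params, nll = nll,
    n_r = n_r, n_phi = n_phi, k = k, aic = 2 * k + 2 * nll,
    R = vapply(
      seq_len(if (shared_mig) 1 else c_periods),
      function(j) speed_ratio(params, j), numeric(1)
    ),
    method = method, stages = stages, n_evaluated = n_evaluated,
    control = control, steps = steps, call = call
  )
  class(fit) <- "mmcp"
  fit
}

#' Fit the multi-metric change-point model
#'
#' Estimates when migration starts and ends from a step series by minimizing
#' the profile negative log-likelihood over change-point tuples with a
#' multi-resolution grid search: the full coarse lattice is scanned first,
#' the \code{top_k} lowest-NLL tuples are carried to each finer resolution
#' (searching a window of one coarse cell around each), and the fit with the
#' global minimum NLL among all evaluated candidates is returned. Ties are
#' broken lexicographically on the change-point times, so the search is
#' fully deterministic. \code{method = "exhaustive"} instead scans the
#' complete finest-resolution lattice (exact, and used as the testing
#' oracle), refusing when the candidate count exceeds the control's guard.
#'
#' @param steps An \code{mmcp_steps} object (see \code{\link{compute_steps}}).
#' @param c_periods Number of migratory periods \code{c} (default 1).
#' @param control An \code{\link{mmcp_control}}.
#' @param shared_mig Share one increment pair across periods?
#' @param method \code{"grid"} (multi-resolution search, default) or
#'   \code{"exhaustive"}.
#' @return An object of class \code{mmcp} with components \code{params}
#'   (an \code{\link{mmcp_params}}), \code{nll}, \code{aic}, \code{R},
#'   \code{feasible}, \code{stages} (candidate counts per resolution) among
#'   others; \code{feasible = FALSE} signals that no migration was estimable
#'   under the constraints. Standard methods (\code{print}, \code{summary},
#'   \code{coef}, \code{logLik}, \code{predict}, \code{plot},
#'   \code{simulate}, \code{confint}, \code{residuals}) apply.
#' @examples
#' set.seed(1)
#' tr <- simulate_cvm(speed_switch_spec(), seed = 1)
#' fit <- mmcp(compute_steps(tr))
#' coef(fit)
#' @export
mmcp <- function(steps, c_periods = 1, control = mmcp_control(),
                 shared_mig = FALSE, method = c("grid", "exhaustive")) {
  stopifnot(inherits(steps, "mmcp_steps"), c_periods >= 1)
  method <- match.arg(method)
  call <- match.call()
  cache <- steps_cache(steps)
  if (method == "exhaustive") {
    g_min <- control$grid_schedule[length(control$grid_schedule)]
    bounds <- control$bounds
    if (is.null(bounds)) bounds <- range(steps$time)
    n_lattice <- length(seq(bounds[1], bounds[2], by = g_min))
    est <- choose(n_lattice, 2 * c_periods)
    if (est > control$exhaustive_guard) {
      stop(sprintf(
        "exhaustive search refused: about %.3g candidates exceed the guard (%g)",
        est, control$exhaustive_guard
      ))
    }
    cand <- enumerate_changepoints(steps, c_periods, g_min, control)
    stages <- data.frame(g = g_min, n_candidates = nrow(cand))
    if (nrow(cand) == 0) {
      return(build_fit(
        steps, c_periods, control, shared_mig, "exhaustive",
        NULL, stages, 0L, call
      ))
    }
    nll <- eval_candidates(cache, cand, shared_mig, control$min_segment,
      control$kappa_cap)
    if (!any(is.finite(nll))) {
      return(build_fit(
        steps, c_periods, control, shared_mig, "exhaustive",
        NULL, stages, nrow(cand), call
      ))
    }
    best <- select_best(cand, nll)
    return(build_fit(
      steps, c_periods, control, shared_mig, "exhaustive",
      best, stages, nrow(cand), call
    ))
  }
  sched <- control$grid_schedule
  all_cand <- NULL
  all_nll <- NULL
  stages <- data.frame(g = numeric(0), n_candidates = integer(0))
  carried <- NULL
  for (s in seq_along(sched)) {
    if (s > 1 && is.null(carried)) {
      stages <- rbind(stages, data.frame(g = sched[s], n_candidates = 0L))
      next
    }
    cand <- if (s == 1) {
      enumerate_changepoints(steps, c_periods, sched[s], control)
    } else {
      enumerate_changepoints(steps, c_periods, sched[s], control,
        centers = carried, prev_g = sched[s - 1]
      )
    }
    stages <- rbind(stages, data.frame(g = sched[s], n_candidates = nrow(cand)))
    if (nrow(cand) == 0) {
      if (s == 1) {
        return(build_fit(
          steps, c_periods, control, shared_mig, "grid",
          NULL, stages, 0L, call
        ))
      }
      next
    }
    nll <- eval_candidates(cache, cand, shared_mig, control$min_segment,
      control$kappa_cap)
    all_cand <- rbind(all_cand, cand)
    all_nll <- c(all_nll, nll)
    fin <- which(is.finite(nll))
    if (length(fin) == 0) next
    top <- fin[order(nll[fin])[seq_len(min(control$top_k, length(fin)))]]
    carried <- cand[top, , drop = FALSE]
  }
  if (is.null(all_nll) || !any(is.finite(all_nll))) {
    return(build_fit(
      steps, c_periods, control, shared_mig, "grid",
      NULL, stages, length(all_nll), call
    ))
  }
  best <- select_best(all_cand, all_nll)
  build_fit(
    steps, c_periods, control, shared_mig, "grid",
    best, stages, length(all_nll), call
  )
}

#' @rdname mmcp
#' @export
mmcp_exhaustive <- function(steps, c_periods = 1, control = mmcp_control(),
                            shared_mig = FALSE) {
  fit <- mmcp(steps, c_periods, control, shared_mig, method = "exhaustive")
  fit$call <- match.call()
  fit
}

#' AIC difference between two fits of the same step series
#'
#' \eqn{\Delta AIC = AIC_1 - AIC_2}; positive values favour the second fit.
#' Both fits must have been computed on the identical series (same valid
#' entries), otherwise their likelihoods are not comparable.
#'
#' @param fit1,fit2 \code{mmcp} fits of the same \code{mmcp_steps}.
#' @return The AIC difference (scalar).
#' @export
delta_aic <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "mmcp"), inherits(fit2, "mmcp"))
  same <- fit1$n_r == fit2$n_r && fit1$n_phi == fit2$n_phi &&
    nrow(fit1$steps) == nrow(fit2$steps) &&
    isTRUE(all.equal(fit1$steps$time, fit2$steps$time))
  if (!same) {
    stop("contract violation: fits were computed on different likelihood term sets")
  }
  fit1$aic - fit2$aic
}
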