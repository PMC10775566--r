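# Shared fixtures and independent oracles for the test suite.

# Von Mises negative log-likelihood with mean direction fixed at 0,
# written directly from the density (independent of the package's
# log-scale Bessel path).
vm_nll_direct <- function(phi, kappa) {
  -sum(kappa * cos(phi) - log(2 * pi * besselI(kappa, 0)))
}

# Brute-force concentration MLE: numeric maximization of the von Mises
# likelihood with mu = 0.
kappa_mle_oracle <- function(phi, cap = 500) {
  stats::optimize(function(k) vm_nll_direct(phi, k), c(0, cap), tol = 1e-9)$minimum
}

# Build a track from coordinate vectors at unit spacing.
make_track <- function(x, y, time = seq_along(x) - 1, id = "t", dt = 1) {
  mmcp_track(data.frame(time = time, x = x, y = y), id = id, dt_nominal = dt)
}

# A fully-valid synthetic step series drawn straight from the model.
make_model_series <- function(T = 120, t_cp = c(40, 80), rho0 = 1, rho1 = 4,
                              kappa0 = 0.5, kappa1 = 1.5, seed = 1) {
  params <- mmcp_params(t_cp, rho0, rho1, kappa0, kappa1)
  template <- mmcp_steps(
    time = seq_len(T), r = rep(1, T), phi = c(NA, rep(0, T - 1)),
    valid_r = rep(TRUE, T), valid_phi = c(FALSE, rep(TRUE, T - 1))
  )
  simulate_from_fit(params, template, seed = seed)
}

# Piecewise-constant noiseless-ish series: r jumps on (t1, t2], angles are
# tiny fixed wiggles so every pool has angular terms without affecting the
# step-length optimum.
make_piecewise_series <- function(T = 110, t1 = 50, t2 = 80, r_lo = 1,
                                  r_hi = 10) {
  tt <- seq_len(T)
  r <- ifelse(tt > t1 & tt <= t2, r_hi, r_lo)
  phi <- c(NA, rep(c(0.01, -0.01), length.out = T - 1))
  mmcp_steps(tt, r, phi,
    valid_r = rep(TRUE, T),
    valid_phi = c(FALSE, rep(TRUE, T - 1))
  )
}

# 2D quadrature Bhattacharyya-affinity oracle between two Gaussians.
ba_quadrature <- function(muA, SA, muB, SB, lim = 12, n = 400) {
  gx <- seq(min(muA[1], muB[1]) - lim, max(muA[1], muB[1]) + lim, length.out = n)
  gy <- seq(min(muA[2], muB[2]) - lim, max(muA[2], muB[2]) + lim, length.out = n)
  dens <- function(mu, S) {
    Si <- solve(S)
    cst <- 1 / (2 * pi * sqrt(det(S)))
    outer(gx, gy, function(x, y) {
      dx <- x - mu[1]
      dy <- y - mu[2]
      cst * exp(-(Si[1, 1] * dx^2 + 2 * Si[1, 2] * dx * dy + Si[2, 2] * dy^2) / 2)
    })
  }
  fA <- dens(muA, SA)
  fB <- dens(muB, SB)
  sum(sqrt(fA * fB)) * diff(gx)[1] * diff(gy)[1]
}

# Sample points whose sample mean/covariance equal a target Gaussian exactly
# (affine-standardized cloud), so the fitted-Gaussian BA is the target BA.
make_gaussian_segment <- function(n, mu, S, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(2 * n), n, 2)
  z <- scale(z, center = TRUE, scale = FALSE)
  z <- z %*% solve(chol(stats::cov(z))) # identity sample covariance
  pts <- z %*% chol(S)
  data.frame(x = pts[, 1] + mu[1], y = pts[, 2] + mu[2])
}
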