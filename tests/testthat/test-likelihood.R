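test_that("migratory indicator uses the half-open (t1, t2] convention", {
  p <- mmcp_params(c(10, 20), 1, 1, 0, 0)
  expect_equal(as.integer(migratory_indicator(15, p)), 1L)
  expect_equal(as.integer(migratory_indicator(10, p)), 0L) # left end excluded
  expect_equal(as.integer(migratory_indicator(20, p)), 1L) # right end included
  expect_equal(as.integer(migratory_indicator(20.0001, p)), 0L)
  # multiple periods: the period index is returned for parameter lookup
  p2 <- mmcp_params(c(10, 20, 30, 40), 1, c(1, 2), 0, c(0, 0))
  ind <- migratory_indicator(c(5, 15, 25, 35, 45), p2)
  expect_equal(as.integer(ind), c(0L, 1L, 0L, 1L, 0L))
  expect_equal(attr(ind, "period"), c(0L, 1L, 0L, 2L, 0L))
})

test_that("point_nll matches independent density evaluations", {
  # r = 0, rho = 1, kappa = 0: only the uniform-angle constant survives
  expect_equal(point_nll(0, 0.3, 1, 0), log(2 * pi))
  # general case against exponential + von Mises densities evaluated directly
  cases <- expand.grid(r = c(0.5, 3), rho = c(0.7, 2), phi = c(0, 1.2, -2.5),
    kappa = c(0.5, 1, 8))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    direct <- -(stats::dexp(cs$r, rate = 1 / cs$rho, log = TRUE)) +
      -(cs$kappa * cos(cs$phi) - log(2 * pi * besselI(cs$kappa, 0)))
    expect_equal(point_nll(cs$r, cs$phi, cs$rho, cs$kappa), direct,
      tolerance = 1e-12
    )
  }
  # the documented reference value
  expect_equal(point_nll(3, 0, 2, 1),
    log(2) + 1.5 + log(2 * pi) + log(besselI(1, 0)) - 1,
    tolerance = 1e-12
  )
  expect_equal(round(point_nll(3, 0, 2, 1), 4), 3.2669)
  # an absent angle leaves the exponential term alone
  expect_equal(point_nll(3, NA, 2, 1), log(2) + 1.5)
  # an absent step leaves the angular term alone
  expect_equal(point_nll(NA, 0, 2, 1), log(2 * pi) + log(besselI(1, 0)) - 1)
  expect_error(point_nll(Inf, 0, 1, 1), "non-finite")
})

test_that("point_nll stays finite at extreme concentrations", {
  v <- point_nll(NA, 0.01, 1, 500)
  expect_true(is.finite(v))
  expect_true(is.finite(point_nll(NA, 0, 1, 5000)))
})

test_that("total_nll is additive and collapses when increments vanish", {
  st <- make_model_series(T = 60, seed = 3)
  p <- mmcp_params(c(20, 40), 1.2, 0.8, 0.3, 0.7)
  # matches the elementwise sum computed independently
  per <- as.integer(attr(migratory_indicator(st$time, p), "period"))
  rho <- p$rho0 + c(0, p$rho_mig)[per + 1]
  kap <- p$kappa0 + c(0, p$kappa_mig)[per + 1]
  direct <- sum(point_nll(st$r, st$phi, rho, kap))
  expect_equal(total_nll(st, p), direct)
  # doubling the series doubles the NLL exactly
  st2 <- mmcp_steps(
    c(st$time, st$time + max(st$time)), rep(st$r, 2), rep(st$phi, 2),
    rep(st$valid_r, 2), rep(st$valid_phi, 2)
  )
  p2 <- mmcp_params(c(20, 40, 20 + 60, 40 + 60), 1.2, c(0.8, 0.8), 0.3,
    c(0.7, 0.7))
  expect_equal(total_nll(st2, p2), 2 * total_nll(st, p))
  # zero increments make the NLL independent of the change-points
  pz1 <- mmcp_params(c(10, 30), 1.2, 0, 0.3, 0)
  pz2 <- mmcp_params(c(25, 55), 1.2, 0, 0.3, 0)
  expect_equal(total_nll(st, pz1), total_nll(st, pz2))
  # with kappa terms absent the NLL equals the exponential log-likelihood
  st_r <- mmcp_steps(st$time, st$r, rep(NA_real_, nrow(st)),
    valid_r = st$valid_r, valid_phi = rep(FALSE, nrow(st))
  )
  pk <- mmcp_params(c(20, 40), 1.2, 0.8, 0, 0)
  expo <- -sum(stats::dexp(st_r$r[st_r$valid_r],
    rate = 1 / rho[st$valid_r], log = TRUE
  ))
  expect_equal(total_nll(st_r, pk), expo)
})

test_that("profile MLEs are pool means with truncation at zero", {
  tt <- 1:9
  r <- c(1, 2, 3, 5, 7, 9, 2, 2, 2) # non-mig pool (t <= 3, t > 6): 1,2,3,2,2,2
  phi <- c(NA, rep(pi / 3, 8))
  st <- mmcp_steps(tt, r, phi,
    valid_r = rep(TRUE, 9),
    valid_phi = c(FALSE, rep(TRUE, 8))
  )
  p <- profile_mle(st, c(3, 6))
  expect_equal(p$rho0, 2) # mean of {1,2,3,2,2,2}
  expect_equal(p$rho_mig, 7 - 2) # migratory mean 7 minus baseline
  # all angles pi/3: mean cos 0.5 -> kappa about 1.16, equal pools, increment 0
  expect_equal(p$kappa0, kappa_mle_oracle(rep(pi / 3, 6)), tolerance = 1e-4)
  expect_equal(p$kappa0, 1.16, tolerance = 0.01)
  expect_equal(p$kappa_mig, 0)
  # a slower migratory pool truncates rho_mig to zero
  r2 <- c(3, 3, 3, 1, 1, 1, 3, 3, 3)
  st2 <- mmcp_steps(tt, r2, phi,
    valid_r = rep(TRUE, 9),
    valid_phi = c(FALSE, rep(TRUE, 8))
  )
  expect_equal(profile_mle(st2, c(3, 6))$rho_mig, 0)
  # pools below min_segment are infeasible, not an error
  expect_null(profile_mle(st, c(3, 4)))
})

test_that("kappa estimation matches brute-force likelihood maximization", {
  for (mc in c(-0.2, 0, 0.3, 0.5, 0.9)) {
    # sample with exact mean cosine mc: angles +/- acos(mc)
    phi <- rep(c(1, -1), 10) * acos(mc)
    k_hat <- as.numeric(kappa_from_meancos(mean(cos(phi))))
    if (mc <= 0) {
      expect_equal(k_hat, 0)
    } else {
      expect_equal(k_hat, kappa_mle_oracle(phi), tolerance = 1e-4)
    }
  }
  # monotone non-decreasing in the mean cosine
  ks <- as.numeric(kappa_from_meancos(seq(-0.5, 0.99, by = 0.01)))
  expect_true(all(diff(ks) >= 0))
  # near-degenerate angles hit the cap and are flagged
  kc <- kappa_from_meancos(0.99999)
  expect_equal(as.numeric(kc), 500)
  expect_true(attr(kc, "capped"))
})

test_that("profile MLEs maximize the likelihood at fixed change-points", {
  st <- make_model_series(T = 100, t_cp = c(30, 70), seed = 11)
  p <- profile_mle(st, c(30, 70))
  base <- total_nll(st, p)
  perturb <- function(p, field, idx, delta) {
    q <- p
    q[[field]][idx] <- max(q[[field]][idx] + delta,
      if (field == "rho0") 1e-6 else 0)
    mmcp_params(q$t, q$rho0, q$rho_mig, q$kappa0, q$kappa_mig, q$shared_mig)
  }
  for (field in c("rho0", "rho_mig")) {
    for (delta_frac in c(-0.01, 0.01)) {
      q <- perturb(p, field, 1, delta_frac * max(p[[field]][1], 0.5))
      expect_gte(total_nll(st, q), base - 1e-9)
    }
  }
  for (field in c("kappa0", "kappa_mig")) {
    for (delta in c(-0.05, 0.05)) {
      q <- perturb(p, field, 1, delta)
      expect_gte(total_nll(st, q), base - 1e-9)
    }
  }
})

test_that("AIC counts 4c + 2 parameters (2c + 4 when increments are shared)", {
  st <- make_model_series(T = 120, seed = 5)
  fit1 <- mmcp(st, c_periods = 1)
  expect_equal(fit1$k, 6)
  expect_equal(fit1$aic, 2 * 6 + 2 * fit1$nll)
  expect_equal(AIC(fit1), fit1$aic) # via logLik
  fit2 <- mmcp(st, c_periods = 2)
  expect_equal(fit2$k, 10)
  expect_equal(fit2$aic, 2 * 10 + 2 * fit2$nll)
  fit2s <- mmcp(st, c_periods = 2, shared_mig = TRUE)
  expect_equal(fit2s$k, 8)
  expect_equal(delta_aic(fit1, fit2), fit1$aic - fit2$aic)
  # fits on different term sets cannot be compared
  other <- make_model_series(T = 80, seed = 6)
  expect_error(delta_aic(fit1, mmcp(other)), "different likelihood term sets")
})

test_that("speed ratio is the proportional step-length increase", {
  expect_equal(speed_ratio(mmcp_params(c(1, 2), 1, 0, 0, 0)), 1)
  expect_equal(speed_ratio(mmcp_params(c(1, 2), 1, 4, 0, 0)), 5)
  # hawk-scale means: rho0 = 4.562 km, rho1 = 140.2 km
  p <- mmcp_params(c(1, 20), 4.562, 140.2, 0, 0)
  expect_equal(speed_ratio(p), (4.562 + 140.2) / 4.562)
  expect_equal(speed_ratio(p), 31.74, tolerance = 0.01)
})
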