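# mmcp — multi-metric change-point estimation of animal migration timing

`mmcp` estimates *when* an animal's migration starts and ends from
discrete-time tracking data. It is aimed at movement ecologists working with
regularized (e.g., daily) GPS or ARGOS tracks of migratory animals — raptors,
caribou, or any species whose migration shows up as faster and/or more
directed movement — and at simulation studies of segmentation methods.

## The model

A track is summarized by its step lengths `r_t` (Euclidean distance between
consecutive fixes) and turning angles `phi_t` (signed angle between
consecutive headings). Step lengths are exponential and turning angles
von Mises with mean direction 0. A migratory period is delimited by a pair of
change-points and shifts both distributions by a non-negative increment:

    I_mig(t) = 1  if  t_1 < t <= t_2   (else 0; one pair per period)

    r_t   ~ Exponential(mean = rho_0 + I_mig(t) * rho_1)
    phi_t ~ vonMises(mu = 0, kappa = kappa_0 + I_mig(t) * kappa_1)

The joint negative log-likelihood (NLL) is minimized over the change-points
with a multi-resolution grid search: the full coarse lattice (default
resolution 14 sampling intervals) is scanned, the five best tuples are
refined at resolutions 7, 3, 1, and the global minimum over everything
evaluated wins. At fixed change-points the distributional parameters have
closed-form profile maximum-likelihood estimates (pool means, with a
truncated Bessel-ratio inversion for `kappa`), which makes the scan cheap.
Uncertainty comes from a parametric bootstrap (simulate from the fitted
model, refit, take percentile quantiles) because the indicator makes the
likelihood discontinuous in the change-points. The derived statistic
`R = (rho_0 + rho_1) / rho_0` summarizes how many times faster the animal
moves while migrating, and AIC (with `4c + 2` parameters for `c` migratory
periods) compares fits with different numbers of periods.

The package also ships the generative simulators used to validate the
method — a switching correlated-velocity (Ornstein–Uhlenbeck) movement model,
a biased correlated random walk with a moving attraction point, and a
missingness/jitter degradation model — plus an evaluation harness
(per-timestep classification profiles, change-point error summaries, and a
closed-form Gaussian Bhattacharyya affinity for range overlap).

## Worked example

Simulate one speed-switch migration (mean speed 1 → 5 → 1, migration on
(100, 200]), fit, and bootstrap:

```r
library(mmcp)
tr  <- simulate_cvm(speed_switch_spec(), seed = 3)   # 301 fixes, unit interval
fit <- mmcp(compute_steps(tr), c_periods = 1)
summary(fit)
#> Multi-metric change-point fit (c = 1, grid search)
#>   change-points: 100, 200
#>   rho0 = 0.8845, rho_mig = 3.906 | kappa0 = 1.456, kappa_mig = 0.1637
#>   NLL = 862.2729, AIC = 1736.5457 (k = 6), R = 5.4157
#>   migration duration(s): 100; 599 terms (300 steps, 299 angles); 506 candidates evaluated

mmcp_bootstrap(fit, n_paths = 10, seed = 2)
#> Parametric bootstrap: 10 paths, 0 failed (seed 2, 95% CIs)
#>        estimate    lower    upper
#> t1     100.0000  98.4500 105.3250
#> t2     200.0000 198.0000 200.0000
#> rho0     0.8845   0.8183   0.9697
#> rho1     3.9058   3.3961   4.7237
#> kappa0   1.4560   1.2738   1.6718
#> kappa1   0.1637   0.0000   0.4903
```

The fitted change-points land exactly on the generating switch times; `R`
of about 5.4 says the simulated animal moved roughly five times faster
during migration, matching the generating mean-speed ratio; the small
`kappa_mig` reflects that this generator changes speed, not directionality.
`plot(fit)` draws the step-length and turning-angle series with the fitted
migratory window shaded.

A thin command-line front end (`inst/scripts/mmcp`) wraps the same
functions: `mmcp prep`, `mmcp fit`, `mmcp bootstrap`, `mmcp simulate`,
`mmcp evaluate`, `mmcp fixtures`.

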