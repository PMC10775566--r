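---
title: "Estimating migration timing with a multi-metric change-point model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating migration timing with a multi-metric change-point model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmcp)
```

## The problem

Migration is a bounded period in which an animal moves faster and/or more
directedly than during range residency. Given a regularized track — one fix
per sampling interval, planar coordinates — we want the *times* at which
migration starts and ends, with uncertainty, and interpretable estimates of
how movement changed. Methods built on a single metric (e.g., net squared
displacement) can miss migrations that express only in directionality;
combining step lengths and turning angles in one likelihood addresses both.

## Model and assumptions

For the step arriving at time $t$, let $r_t \ge 0$ be the step length and
$\phi_t \in (-\pi, \pi]$ the turning angle (defined by three consecutive
on-interval fixes). With $c$ migratory periods delimited by change-points
$t_1 < \dots < t_{2c}$, the indicator $I(t)$ is 1 exactly when
$t_{2n-1} < t \le t_{2n}$ for some period $n$ (left endpoint excluded, right
included — the convention used everywhere in the package, including in
simulator labels and range segmentation). Then

$$r_t \sim \mathrm{Exp}\!\left(\text{mean} = \rho_0 + I(t)\,\rho_n\right),
\qquad
\phi_t \sim \mathrm{vM}\!\left(\mu = 0,\; \kappa = \kappa_0 + I(t)\,\kappa_n\right),$$

with $\rho_n, \kappa_n \ge 0$. Assumptions worth stating plainly:

* steps and turns are conditionally independent given the regime — no
  temporal autocorrelation and no step/turn cross-correlation is modelled;
* the mean turning direction is fixed at 0 (straight-ahead persistence).
  A generic von Mises fitter would also free $\mu$; the likelihood's
  $\kappa \cos\phi_t$ form pins $\mu = 0$, so the concentration MLE reduces
  to inverting $A(\kappa) = I_1(\kappa)/I_0(\kappa)$ against the mean
  cosine. We implement that; freeing $\mu$ is a deliberate non-feature;
* increments are truncated at zero: migration is *a priori* faster and more
  directed. A "migration" slower than residency is not representable —
  by design, not by accident;
* exponential steps and von Mises turns are the simplest usable pair;
  heavier-tailed step models (gamma, Weibull) or wrapped-Cauchy turns would
  slot into the same structure but are not implemented.

## Estimation

At fixed change-points the likelihood separates. $\hat\rho_0$ is the mean of
non-migratory step lengths; $\hat\kappa_0$ inverts the Bessel ratio against
the non-migratory mean cosine; each migratory period contributes
$\hat\rho_n = \max(0, \bar r_n - \hat\rho_0)$ and
$\hat\kappa_n = \max(0, \hat\kappa(n) - \hat\kappa_0)$. The change-points
are then found by scanning: all ordered tuples on a coarse lattice
(resolution 14 sampling intervals by default), carrying the `top_k = 5`
lowest-NLL tuples to finer lattices at resolutions 7, 3, 1 — each finer
window spans one coarse cell ($\pm$ previous resolution per coordinate), so
the refinement always covers the cell it came from. Halving with truncation
to integers motivates the 14/7/3/1 default; animals migrating on other
timescales should rescale the schedule and the minimum duration. The
returned fit is the global NLL minimum over *all* evaluated candidates;
an exhaustive scan of the finest lattice (`method = "exhaustive"`) serves
as the exact reference and is what the test suite compares against.

Numerical choices:

* $\log I_0$ is evaluated via exponentially scaled Bessel functions, so
  concentrations up to the cap never overflow;
* $\hat\kappa$ solves $A(\kappa) = \overline{\cos\phi}$ by a vectorized
  Newton iteration from the Best–Fisher starting value; mean cosines at or
  below zero give $\hat\kappa = 0$ (uniform boundary), and estimates are
  clamped at `kappa_cap = 500` and flagged — far beyond any biologically
  plausible concentration, and the likelihood diverges when all angles
  are nearly equal;
* candidate tuples are infeasible (skipped, not errors) when any parameter
  pool has fewer than `min_segment = 2` valid steps or no valid angle, when
  a period is shorter than `min_duration` (default 7 sampling intervals,
  strict), or when a baseline mean is zero;
* NLL ties — exact or within a $10^{-9}$ relative whisker, as on constant
  series — break lexicographically on $(t_1, t_2, \dots)$, making the
  search fully deterministic;
* the search evaluates pooled sums via cumulative-sum differences, so a
  full stage is one vectorized pass; a typical `c = 1`, 300-step fit
  evaluates ~500 candidates in ~15 ms.

Confidence intervals are percentile parametric-bootstrap: simulate step
series from the fitted parameters — preserving the template's exact times
and validity masks, i.e. the observed missingness pattern — refit each with
the same configuration, and take the 2.5%/97.5% quantiles per parameter.
Replicate $b$ uses seed `seed + b`. Infeasible refits are excluded and
counted; results with over half the refits failing are flagged unreliable.
Wald and profile intervals are unavailable on principle: the likelihood is
discontinuous in the change-points.

## Track preparation

Raw tracks are filtered (DOP > 5 in either axis removed, when DOP columns
exist), optionally rarefied to one fix per day — the fix nearest noon wins,
ties to the earlier fix, and retained times snap to the integer day index so
the rarefied track is exactly regular — and screened for gaps. The gap
screen is an *exclusion* filter (defaults 400 km / 14 days): a track with
any violation fails as a whole rather than being split. Steps spanning
missing fixes are masked out of the likelihood by default rather than
rescaled by elapsed time; `rescale_gaps = TRUE` selects the alternative.
Masking loses a few terms but avoids pretending a multi-day displacement is
a one-day step. A turning angle is valid only when its two supporting steps
are valid, contiguous, and of positive length. Coordinates must be planar
(km); nothing here computes geographic distances.

## What the simulators emulate

Three generative processes, each 300 timesteps with migration on
$(100, 200]$, emulate distinct mechanisms:

* **speed switch** — correlated-velocity model (2D Ornstein–Uhlenbeck
  velocity) with mean speed $\nu: 1 \to 5 \to 1$, timescale $\tau = 2$;
* **timescale switch** — $\nu = 1$ throughout, $\tau: 2 \to 20 \to 2$: the
  *marginal* speed distribution is constant (the stationary per-axis spread
  is $\sigma = \nu\sqrt{2/\pi}$ regardless of $\tau$) while directionality
  rises;
* **bias switch** — discrete biased correlated random walk, Weibull(1, 1)
  steps, turn concentration 0.5, attraction point $(0,0) \to (50,0)$ and
  strength $0.5 \to 0.9 \to 0.5$: step and turn marginals are essentially
  unchanged; only where the walk is headed changes.

The CVM uses exact OU transitions at an internal substep of 0.1 and
trapezoidal position integration; $\nu$ is the stationary *mean speed*
(Rayleigh mean), and at a $\nu$-switch the current velocity is rescaled by
the ratio of stationary spreads so no boundary transient is introduced. The
BCRW expected heading is the direction of the vector-weighted mean
$A\,u(\theta_{\text{target}}) + (1-A)\,u(h_{\text{prev}})$ with von Mises
noise — the standard construction. Degradation removes each location after
the first with probability 1/12 (the first is kept as an anchor) and adds
per-axis Gaussian jitter with variance $\sigma_e \in \{0, 1, 25\}$; at
$\sigma_e = 25$ the mean displacement is $5\sqrt{\pi/2} \approx 6.27$
spatial units.

What passing tests on these simulators do **not** show: real tracks have
tortuosity regimes, stopovers, tag-dependent error structure, diel rhythms
and non-stationary residency that none of the generators produce. The
harness demonstrates correctness of the machinery and the qualitative
ordering of difficulty (speed switch easy, timescale switch moderate, bias
switch near-impossible for step/turn metrics — the last is expected and is
asserted only as "runs and reports"), not field performance.

## Study conditions fixed by this package

Where a protocol quantity was open, the package fixes it once:

* the evaluation harness's replicate property test uses 20 clean paths per
  generator (no missingness, $\sigma_e = 0$); the full degradation protocol
  (1/12 missingness) is exercised in the 50-replicate speed-switch
  experiment that `scripts/acceptance.R` re-runs;
* bootstrap-coverage experiments use $\rho_0 = 1, \rho_1 = 4$ (so $R = 5$),
  $\kappa_0 = 0.5, \kappa_1 = 2$, $T = 300$, change-points (100, 200), 100
  datasets, 50 bootstrap paths each — $\rho_0$ and $\kappa_0$ are the
  package's choice of a realistic moderately-directed baseline;
* oracle-equivalence experiments use 100 series of length 120 with a 5×
  mean-speed switch on (40, 80) and increments $\kappa_1 = 1.5$;
* problem sizes throughout (50 replicates, $10^5$ jitter draws, 100
  bootstrap datasets) are the sizes the reported experiments actually use.

## Known limitations

* `c` is user-chosen; the package compares candidate `c` values only via
  AIC on the identical series (`delta_aic`), it does not auto-select.
* The exhaustive oracle is guarded (refuses > $10^6$ candidates), so exact
  verification is limited to short series or coarse lattices — inherent to
  a $\binom{T}{2c}$ candidate space.
* Profile MLEs within a candidate are exact per pool but the truncation at
  zero couples pools weakly; the perturbation tests verify the fitted point
  is a local maximum under the constraints.
* The Bhattacharyya range overlap uses Gaussian range fits — exact for the
  surrogate, simpler than autocorrelated kernel densities, and intended for
  comparing segmentations, not as a home-range estimator.
* Time is a single numeric day clock; calendar handling (time zones,
  daylight saving) is limited to what `as.POSIXct` provides at read time.

## A compact end-to-end run

```{r example, eval = FALSE}
tr <- simulate_cvm(speed_switch_spec(), seed = 3)
tr <- degrade_track(tr, p_miss = 1 / 12, sigma_e = 0, seed = 4)
fit <- mmcp(compute_steps(tr), c_periods = 1)
summary(fit)
confint(fit, n_paths = 100, seed = 1)
plot(fit)
```
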