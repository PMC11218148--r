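---
title: "Methods: building and applying methylation passage clocks"
author: "passclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and applying methylation passage clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passclock)
```

## The problem

Serially passaged primary human cells (fibroblasts being the canonical
system) accumulate reproducible DNA-methylation changes as the population
ages towards replicative senescence. A small minority of CpG sites drifts
monotonically with passage number — some losing methylation
(hypomethylating), some gaining it (hypermethylating) — against a largely
static, bimodal background in which most CpGs sit near beta 0.1
(unmethylated) or 0.9 (methylated). A sparse linear predictor trained on
those drifting CpGs can read the *passage number* of a culture off its
methylome. Because the readout integrates the methylation state of the whole
population, a compound that slows population ageing shows up as a
systematically *under-predicted* passage — a deceleration signal usable for
anti-ageing drug screening without waiting for lifespan endpoints.

`passclock` implements that workflow end to end: probe-level quality
filtering, per-CpG screening against passage, elastic-net clock fitting,
the deceleration readout, the surrounding screening statistics (robust Z
scores of senescence-marker panels, population-doubling arithmetic), and a
fully seeded synthetic-methylome generator that makes every stage testable
with known ground truth.

## Per-CpG screening

For each probe the model is ordinary least squares on the beta scale,

$$\beta_{ij} = a_j + b_j \, p_i + \varepsilon_{ij},$$

with the two-sided t-test on the slope ($n-2$ degrees of freedom) giving
the per-probe p-value. Probes with $p < \tau$ (default $\tau = 10^{-11}$)
are the differentially methylated positions (DMPs) passed to clock fitting.
Design choices:

* **Beta scale, not M-values.** The clock consumes and is trained on
  methylation fractions; no logit transform is applied anywhere, so slopes
  are directly interpretable as delta-beta per passage and the drift
  calibration below is on the same scale.
* **No covariates.** Cell type and donor are not modelled in the per-probe
  regression; cohorts are pooled. With few donors the covariate would be
  nearly collinear with passage range; users screening heterogeneous panels
  should stratify upstream.
* **Perfect fits.** An exactly linear probe has zero residual sum of
  squares; its t-statistic is undefined. Such probes are flagged, assigned
  the sentinel $p = 0$ and $t = \pm\infty$, which keeps the ranking
  deterministic. Numerically, "zero RSS" means RSS $< 10^{-24}$ (absolute,
  beta$^2$ units — far below anything reachable by noise but far above
  accumulation of double-precision rounding). A constant probe (zero total
  sum of squares under the same cut-off) instead gets slope 0, $t = 0$,
  $p = 1$.
* **Threshold selection.** `select_threshold_loo()` evaluates a descending
  grid of candidate thresholds (default $10^{-5}, 10^{-7}, 10^{-9},
  10^{-11}, 10^{-13}$) by leave-one-out validation: for each held-out
  sample, screen and fit on the rest, predict the held-out passage; the
  threshold minimising LOO RMSE wins, with ties broken toward the most
  stringent value. RMSE of predicted passage is used as the criterion
  because it is the clock's own headline metric; a threshold that screens
  zero probes in any fold is marked infeasible (infinite RMSE) rather than
  fatal.

## The clock: elastic net on screened CpGs

`fit_clock()` minimises

$$\frac{1}{2n}\sum_i \left(p_i - w_0 - x_i^{\top} w\right)^2 +
  \lambda\left[\alpha \lVert \tilde w \rVert_1 +
  \tfrac{1-\alpha}{2}\lVert \tilde w \rVert_2^2\right],$$

where $x_i$ are the screened beta values, predictors are standardised
internally (mean 0, variance 1 with the $1/n$ convention,
$\tilde w_j = w_j s_j$), and coefficients are reported back on the original
beta scale. Defaults: $\alpha = 0.5$ (equal lasso/ridge mix), $\lambda$
chosen by 10-fold cross-validation minimising mean squared prediction
error. Both the CV-minimising rule (`"min"`, default) and the
one-standard-error rule (`"1se"`) are exposed, and the choice is recorded in
the model's provenance, because either is a defensible reading of "lambda by
internal cross-validation" — published clocks rarely say which was used.

Implementation notes:

* The fitting engine is **glmnet**, the standard tool for this model class.
  Folds are assigned by a seeded shuffle stratified by passage level, so a
  given seed yields a bit-identical model; with ~6–7 samples per passage
  level this keeps every fold's passage range representative.
* For gaussian responses glmnet standardises $y$ internally, which changes
  what a *fixed* supplied $\lambda$ means. When the user pins `lambda`,
  `fit_clock()` reparameterises: with $s_y$ the $1/n$ standard deviation of
  passage, it solves at $\tilde\lambda = \lambda\alpha/s_y +
  \lambda(1-\alpha)$, $\tilde\alpha = (\lambda\alpha/s_y)/\tilde\lambda$ on
  $y/s_y$ and rescales the solution by $s_y$. The returned fit then
  minimises exactly the objective displayed above at the requested
  $\lambda$ — verifiable against the package's independent solver (below).
* A fixed $\lambda$ at or above $\lambda_{\max} = \max_j |\langle \tilde
  x_j, y - \bar y\rangle| / (n\alpha)$ returns the null model with the
  intercept set analytically to $\bar p$.
* Constant predictor columns are dropped with a warning; the intercept is
  never penalised; a single-predictor fit is solved in closed form (one
  soft-thresholding step on the standardised scale).
* At prediction time every clock CpG must be present and non-missing.
  Missing clock probes are a hard error listing the IDs — silent mean
  imputation would mask platform mismatches and bias the deceleration
  readout toward zero.

### The reference solver

`enet_coordinate_descent()` is a deliberately plain cyclic
coordinate-descent solver for the same objective, written without any shared
code with glmnet, run to a $10^{-12}$ coordinate-change tolerance. Together
with `enet_objective()` and `enet_kkt_residual()` it lets the test suite (and
any sceptical user) verify fits by two independent routes: objective values
must agree and the Karush–Kuhn–Tucker stationarity residuals of both
solutions must be near zero. It is a verification tool, not the production
fitting path.

## The deceleration readout

For each scored sample, $\Delta = \hat p - p$. `compute_acceleration()`
groups $\Delta$ by passage level (or by cumulative-population-doubling bins,
since a compound that slows proliferation would confound the nominal passage
axis) and reports per-level cohort means, the effect
$\overline{\Delta}_{treat} - \overline{\Delta}_{ctrl}$, and the overall mean
effect with a standard error from the per-level variances. Negative effect =
deceleration. The composite `run_screen_compound()` turns this into a
verdict: "decelerated" below $-2$ SE, "accelerated" above $+2$ SE,
otherwise "no effect".

## Screening statistics

* **Robust Z**: $z = (t - \mathrm{median}(c)) / \mathrm{MAD}(c)$ with the
  MAD *unscaled* (no 1.4826 consistency factor) and computed over control
  values only, exactly as screening worksheets print it. "Treatment minus
  control" is read as treatment minus the control *median* — the only
  reading consistent with scoring each treatment observation. Calls use a
  symmetric cutoff (default 0.5) with each marker's senescence polarity
  (p16, p21, SA-β-Gal, IL-6 and nuclear area rise with senescence;
  nucleolin and proliferation fall) deciding which tail is "senescent".
* **Population doublings**: $PD = \ln(\mathrm{final} /
  (\mathrm{seeded}/2)) / 0.6931 - 1$, keeping the truncated constant
  0.6931 verbatim for bit-fidelity with standard culture worksheets; an
  `exact_ln2` switch substitutes $\ln 2$. The fixed point
  $\mathrm{final} = \mathrm{seeded}/2 \Rightarrow PD = -1$ is exact.
  Cumulative PD is the running sum across passages.

## The synthetic methylome generator

`simulate_cohort()` draws, per probe, a baseline from the bimodal background
(Beta(45, 5) and Beta(5, 45) components, modes near 0.9 and 0.1); drifting
CpGs instead start where ageing CpGs start on arrays — hypomethylating
probes at beta ~ U(0.80, 0.95), hypermethylating at U(0.05, 0.20) — and move
linearly with passage at slope $\pm$ `drift_total`/10 per passage, jittered
±20% per probe. The default `drift_total = 0.2` calibrates the mean
|delta-beta| between passages 10 and 20 to 0.2, the magnitude reported for
clock CpGs on real fibroblast series. Observations are
$\beta \sim \mathrm{Beta}(\mu\kappa, (1-\mu)\kappa)$ with $\kappa = 200$
(SD ≈ 0.035 at beta 0.5, comparable to array replicate noise; real data
give no direct estimate, so $\kappa$ is an explicitly free parameter). Mean
trajectories are clipped to [0.01, 0.99], with a warning if more than 10% of
drifter means ever pin at the bounds.

The default design mirrors the serial-passaging study the clock idiom comes
from: a 39-sample training cohort (6 samples at each of P10/12/14, 7 at each
of P16/18/20) and a 26-sample test cohort spread over P9–P20, both
vehicle-treated. Treatment is modelled as *effective-passage compression*:
from onset $p_0$, a cohort with deceleration $d$ behaves as if at
$p_0 + (p - p_0)(1 - d)$. This makes the deceleration cumulative — more
pronounced at later passages — rather than a constant offset, which is what
drug-treated cultures show. $d = 1$ freezes the methylome at onset.
Immortalisation is modelled separately as a *slope* reduction: beyond the
immortalisation passage the drift proceeds at `residual_drift` times its
rate, producing predictions that keep rising yet increasingly underestimate
actual passage — the hTERT signature.

What the generator deliberately does **not** emulate: raw intensities and
probe-type chemistry, batch/chip effects, donor heterogeneity (available as
an option in spirit, but off by default), non-linear or saturating drift,
and correlated probes. Passing tests therefore demonstrate that the
machinery recovers truth under its own stated noise model — not that the
clock will transfer across platforms or cell types without recalibration.

## Problem sizes and runtime choices

The test suite exercises the full design scale where it matters (10,000
probes, the 39 + 26 sample layout, 60 drifters) and a 1,500-probe
miniature elsewhere; leave-one-out threshold selection is tested on the
miniature with a 5-fold inner CV. These sizes keep the whole suite under
half a minute on one core while preserving every property being claimed
(screening power at $\tau = 10^{-11}$ depends on sample count and noise,
both kept at design scale wherever power is asserted).

## Known limitations

* The clock predicts *passage*, a protocol-dependent unit; transferring a
  trained clock across labs requires matched passaging schedules or a
  population-doubling axis.
* Screening assumes complete beta rows; probes with any missing value are
  dropped rather than imputed.
* The per-probe test is OLS on a bounded response; at extreme baselines the
  beta noise is skewed and the nominal t p-values are slightly
  approximate. The null-calibration test (10,000 null probes against
  U(0,1)) bounds the practical impact.
* `select_threshold_loo()` refits the clock once per sample per candidate
  threshold, which is quadratic-ish in cohort size; it is meant for
  design-scale cohorts (tens of samples), not biobanks.
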