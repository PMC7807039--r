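---
title: "Label-free classifier evaluation by binormal decomposition"
author: "rocharvest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free classifier evaluation by binormal decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A continuous classifier assigns subjects to a negative or positive class
by thresholding a measured value. `rocharvest` assumes that, after a
natural-log transform, the value is Gaussian within each class:
`f1 = N(mu1, sigma1^2)` in the negative class and `f2 = N(mu2, sigma2^2)`
in the positive class. The unlabeled population density is then the
binormal mixture

    y(x) = a (1-pr) f1(x) + a pr f2(x)

with `pr` the prevalence (prior probability) of the positive class and `a`
a free scale factor. For the motivating application — serum PSA and
prostate cancer — the biological reading is one homogeneous population of
normal prostate cells whose marker output drifts upward with age (the
negative component, age-dependent `mu1`) and one heterogeneous malignant
population whose output does not depend on age (a single positive
component shared by all age strata). Note that each point of the curve is
the *sum* of the two component densities; this is deliberately not the
three-parameter "two half-Gaussian" binormal sometimes used for ROC
modelling.

Everything downstream is analytic in the four component parameters plus
`pr`: sensitivity `Se(t) = 1 - Phi((t-mu2)/sigma2)`, specificity
`Sp(t) = Phi((t-mu1)/sigma1)`, the ROC curve as the locus of
`(1-Sp, Se)`, its area `Phi((mu2-mu1)/sqrt(sigma1^2+sigma2^2))`,
predictive values by Bayes' rule, likelihood ratios as tail-mass or
density ratios, and the negative-class reference interval
`exp(mu1 +- 1.96 sigma1)`. The only estimation step is the decomposition
itself.

## Histogram construction

The mixture is fitted to the relative-frequency histogram of the
log-values, not to the raw likelihood. Choices, all fixed so the
construction is reproducible:

- **Value window.** Raw values outside `[vmin, vmax]` (defaults 0.1 and
  100, the usual PSA plausibility window in ng/mL) are excluded and
  counted before the log transform.
- **Bin width** follows the Freedman–Diaconis rule `h = 2 IQR / n^(1/3)`
  with the IQR computed by linear interpolation of order statistics
  (`quantile` type 7). Near-constant data (IQR = 0) is an error, not a
  fallback: the decomposition is meaningless there.
- **Bin count and anchoring.** `n_bin = ceiling((max-min)/h)` bins of
  exactly width `h` anchored at the sample minimum, with no cosmetic
  rounding of edges. Bins are half-open `[left, right)`; if the maximum
  falls exactly on the top edge one extra bin is appended so every sample
  is counted exactly once and the relative frequencies sum to one by
  construction.

## Fitting

The decomposition minimises the unweighted sum of squared differences
between bin heights and the model curve at bin centers, using bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) under the constraints
`a >= 0`, `sigma1, sigma2 >= 1e-6` (a numerically safe version of
non-negativity), `0 <= pr <= 1`. Tunable knobs live in
`binorm_control()`: LM tolerances (`ftol`, `ptol`, both `1e-12`),
iteration cap (200), restart count (5) and the restart-jitter seed.

- **Starting values.** The negative mean starts at the 25th
  frequency-weighted percentile of the bin centers, the positive mean at
  the 90th, both sigmas at the weighted SD, `pr = 0.3`, and `a = h` (for
  a relative-frequency histogram the fitted scale is necessarily close to
  the bin width; it is nonetheless estimated freely, per stratum).
- **Multi-start.** LM is a local optimiser and the objective is not
  convex. If the first run fails or terminates on a bound, five jittered
  restarts are taken from a fixed-seed local RNG (the caller's RNG stream
  is never touched); the run with the smallest residual sum of squares
  wins, ties broken by the smaller fitted prevalence.
- **Component identity.** The model is exactly invariant under swapping
  the components together with `pr -> 1-pr`; after fitting, components
  are relabeled so the negative mean is the lower one, which is what the
  class semantics require.
- **Goodness of fit** is reported as `r^2 = 1 - SS_res/SS_tot` about the
  mean bin height — the convention R's nonlinear-fitting ecosystem uses
  for fitted curves; there is no standard `r^2` for nonlinear models, so
  the definition is stated here once.

### The two-pass strategy

With age strata, the positive component is estimated only where it is
well identified: the pooled stratum of ages >= 65 (configurable), where
prevalence is high enough that both components carry comparable weight,
is fitted with all six parameters free; every other stratum is then
refitted with `(mu2, sigma2)` frozen to the anchor estimate, leaving
`a, pr, mu1, sigma1`. This operationalises the age-invariance hypothesis
for the positive class. Freezing a component can only increase the
residual sum of squares relative to the free fit on the same histogram (a
nested-model fact the test suite checks). Strata with fewer than `min_n =
200` records are skipped rather than fitted: Freedman–Diaconis binning
and a six-parameter fit are unstable below that.

### Identifiability

The six-parameter fit of two strongly overlapping Gaussians is weakly
identified: the least-squares surface has a long, flat ridge along which
`pr`, `mu2` and `sigma2` trade off while the fitted curve, and hence
`r^2`, barely changes. Two practical consequences, both visible in the
test suite's recovery harness: single-dataset anchor estimates of the
positive component scatter widely around the truth even at cohort sizes
in the tens of thousands (while remaining unbiased on average across
replicates), and a high `r^2` is *not* evidence that the individual
parameters are precise. Second-pass (four-parameter) fits are much better
behaved because the hardest parameters are frozen. Users should treat
per-stratum prevalence and negative-component estimates as the robust
outputs and anchor positive-component estimates as noisy unless the
anchor cohort is very large or the classes well separated.

## Cut-off selection

The Youden cut-off maximises `Se + Sp - 1`, which occurs where the two
class densities cross; equating log-densities gives a quadratic in `t`
whose admissible root (the one between the component means) is returned,
with bisection on the increasing branch of the likelihood ratio as a
fallback for degenerate configurations, and an explicit error when no
crossing exists. The cost-weighted mode minimises the expected
misclassification cost `C pr (1-Se) + (1-pr)(1-Sp)`, whose first-order
condition is `LR(t*) = (1-pr)/(C pr)`; `C` is the cost of a false
negative relative to a false positive (default 4 for a mid-life screening
context; for the oldest strata a value below 1 may be appropriate, since
over-diagnosis dominates there). With `pr` near 0.2 and `C = 4` the two
criteria nearly coincide — the constant is close to 1 — which is why a
single published cut-off can satisfy both.

Two reporting notes. The trapezoid ROC area at the default 512-point
grid agrees with the closed form to about `1e-3`; published AUCs computed
from coarse discrete cut-off series can differ from the closed form in
the third decimal, so both routes are exposed. All proportions are
returned at full precision; any rounding to one-decimal percentages
happens only in the printed report.

## The synthetic cohort generator

`cohort_spec()`/`generate_cohort()` produce labeled cohorts with exactly
the structure the model assumes, so the whole pipeline can be validated
against a gold standard without any real data: ages drawn over six bands
(20–39, 40–49, 50–59, 60–69, 70–79, 80+), a hidden label drawn with the
band's prevalence, the log-value from the label's component, truncation
to `[0.1, 100]` by resampling (keeping cohort size exact at the price of
slightly reshaping the extreme tails relative to the untruncated
components).

Defaults are chosen once to mimic a PSA screening population: band
prevalences 0.02, 0.08, 0.18, 0.41, 0.545, 0.50 — a steep midlife rise
that flattens and dips after 75, consistent with reported age profiles of
latent prostate cancer; negative-class log-means −0.45, −0.30, −0.124,
0.00, 0.10, 0.20 (monotone drift, with the 50s band at the reference
stratum's value) and common `sigma1 = 0.643`; positive component
`(1.033, 0.766)`, age-invariant. How fast the healthy mean really rises
with age is not well quantified; the drift values are illustrative, not
estimates.

What the generator does *not* emulate: assay measurement error and
calibration drift between laboratories, non-Gaussian within-class shapes,
label noise, and any dependence of the positive component on age. Passing
recovery tests on these cohorts therefore demonstrates correctness of the
estimation machinery under the model's own assumptions — not robustness
of the method to their violation. One deliberate exception: the default
cohort's pooled >= 65 anchor mixes three negative-class means, so its
negative component is itself mildly misspecified as a single Gaussian —
exactly the situation a real age-pooled anchor faces; the per-band test
harness uses a homogeneous anchor when the goal is to measure pure
estimation error.

## Validation problem sizes

The test suite validates at sizes chosen to keep Monte-Carlo error well
below the tolerances being asserted: exact (noise-free model-curve)
histograms for solver correctness at machine-level tolerance; 20,000
draws per stratum and 10–20 replicate seeds for two-pass recovery bias;
100,000 labeled draws for the analytic-vs-contingency oracle comparison
(three binomial standard errors); one million paired draws for the
AUC-as-probability check.

## Known limitations

- The method inherits everything from the distributional assumption; a
  lognormal-within-class violation biases all indices, and nothing in an
  unlabeled fit can detect a well-camouflaged violation.
- Weak identifiability of the free six-parameter fit, as discussed above;
  single-dataset positive-component estimates carry large sampling error.
- Only two components are supported; the general n-component
  superposition exists in the model notes but is not fitted.
- No confidence intervals are produced for the harvested indices.
- Inconclusive-zone handling (two-graph ROC approaches) is out of scope.
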