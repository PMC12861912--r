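---
title: "Restriction spectrum imaging and the NSCLC subtype workflow: models, simulators and statistical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restriction spectrum imaging and the NSCLC subtype workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsilung)
```

## The problem

Squamous cell carcinoma (SCC) and adenocarcinoma (AC), the two dominant
non-small cell lung cancer subtypes, call for different treatment plans,
and the reference standard for telling them apart — biopsy — is invasive.
Multi-b-value diffusion-weighted MRI offers a noninvasive alternative:
water mobility differs between the subtypes, and restriction spectrum
imaging (RSI) resolves that mobility into restricted (intracellular),
hindered (extracellular) and free compartments rather than collapsing it
into a single apparent diffusion coefficient (ADC). This package
implements the full quantitative chain for that setting: signal
simulation, per-voxel model fitting, cohort synthesis and the two-group
statistical analysis leading to a combined diagnostic model.

## Forward models and noise

Signal is acquired at a 12-point b-value schedule (0, 25, 50, 100, 150,
200, 400, 600, 800, 1000, 1500, 2000 s/mm²). Two forward models are
implemented:

* mono-exponential: $S(b) = S_0 e^{-b\,\mathrm{ADC}}$, with ADC in mm²/s;
* three-compartment: $S(b) = S_0 (f_1 e^{-bD_1} + f_2 e^{-bD_2} +
  f_3 e^{-bD_3})$ with $D_1 < D_2 < D_3$ fixed at $1, 2, 3\times10^{-3}$
  mm²/s and the volume fractions $f_i$ on the unit simplex.

Fixing the compartmental diffusivities is what makes the model linear in
its free parameters and keeps voxelwise fitting well-posed with 12
observations; estimating them as well is explicitly out of scope. Since
$b$ is carried in s/mm² and $D$ in mm²/s, the exponents are
dimensionless. Fractions are stored in [0, 1] internally; report layers
print them ×10⁻² and ADC ×10⁻³ mm²/s, the conventional display scales.

Measurement noise is Rician, $\tilde S = \sqrt{(S+g_1)^2 + g_2^2}$ with
independent zero-mean Gaussians of standard deviation $\sigma$: the
standard model for magnitude MR data, reducing to additive Gaussian noise
at high SNR and to Rayleigh noise at zero signal. The acquisition
protocol varies the number of excitations per b-value, which would make
$\sigma$ b-dependent after averaging; the simulator keeps a single
$\sigma$ per acquisition because the per-b averaging actually applied by
the scanner software is not documented. Rician bias is *not* corrected
before fitting — a deliberate simplification, exercised by the noise
robustness tests (mean absolute error of $f_1$ stays below 0.05 at
SNR 50) and listed under limitations.

## Fitting

`fit_adc()` regresses $\log S$ on $b$ by unweighted ordinary least
squares over all strictly positive amplitudes, returning ADC = −slope.
It is exact on noiseless mono-exponential input. All 12 b-values are
used; no subset or weighting scheme is applied. Voxels with fewer than
two positive amplitudes, or with a non-positive fitted ADC, are excluded
from the ADC map's mask rather than reported.

`fit_rsi()` solves non-negative least squares against the fixed basis
$e^{-bD_i}$ using a Lawson–Hanson active-set solver written for this
package (the active-set method terminates cleanly on the exact-fit
degenerate cases that arise constantly here, e.g. pure free-water voxels
whose residual is exactly zero). $S_0$ is recovered as the sum of the
basis weights and the fractions as weights/$S_0$, so $f_1+f_2+f_3 = 1$
holds by construction and the noisy $b=0$ measurement is never used as a
divisor. Zero amplitudes are tolerated (the linear model is defined
there), unlike in the log-linear ADC fit.

`fit_parameter_maps()` applies both fits per masked voxel of a 3D/4D
stack and `summarize_roi()` takes arithmetic means over a region of
interest, restricted to voxels that survived fitting. There is no
spatial regularization or smoothing: maps are strictly per-voxel.

## What the synthetic data emulate

Two simulators make the downstream analysis testable without patient
data.

**Phantoms** (`generate_phantom()`) place an elliptical lesion with known
compartment ground truth (constant or a linear ramp) in a free-water
background, evaluate the tri-exponential model over the schedule and add
Rician noise. They validate round-tripping: at $\sigma = 0$ the fitting
chain reproduces ground truth to solver precision.

**Cohorts** (`generate_cohort()`) draw 30 SCC and 67 AC patients (by
default) whose per-variable distributions are calibrated to published
group summaries:

* age, $f_1$ and ADC: normal, truncated to their physical ranges, with
  the underlying parameters solved numerically so the *truncated*
  distribution has the published mean and SD (naive truncation would
  shift the AC $f_1$ mean by ≈0.035);
* lesion diameter and SUVmax: log-normal with $\mu = \log(\text{median})$
  and $\sigma$ matched to the published interquartile range — positive,
  right-skewed, and parameterizable from median/IQR summaries;
* sex and smoking: Bernoulli at the published group rates;
* $f_2, f_3$: the remainder $1 - f_1$ is split by a Beta draw whose
  *median* matches the published $f_2{:}f_3$ median ratio, with
  concentration $\kappa = 1.5$ to reproduce the heavy right skew of the
  published hindered-fraction quartiles. The published marginal summaries
  for $f_1$, $f_2$, $f_3$ cannot all hold simultaneously under an exact
  simplex (mixed mean/median group summaries do not sum to 100%), so
  $f_1$ — the variable that matters diagnostically — gets distributional
  priority and the split is a modelled compromise. Matching the Beta
  *mean* instead was rejected: at a median ratio of 0.028 it pushes
  essentially all AC $f_2$ mass below $10^{-6}$, destroying the overlap
  the published quartiles show.

Two modes ship. In *summary* mode ADC is drawn from its own generator,
independent of the fractions — fast, and sufficient for testing the
statistics. In *image* mode each patient's imaging values come from
fitting a small simulated phantom whose ground-truth fractions were drawn
from the same generators, so ADC is physically consistent with the
tri-exponential signal (it emerges from the fit, not from a second random
draw). At $\sigma = 0$ the two modes agree exactly on the fractions,
which the tests assert.

What the generator deliberately does **not** model: inter-variable
correlations beyond the simplex coupling (only marginal summaries are
published), anatomical realism, and reader variability. Consequences:
the synthetic predictors are *independently* informative, so the combined
model discriminates somewhat better (AUC ≈ 0.90–0.96 across seeds) than
the published cohort model (0.909 apparent, 0.895 after bootstrap);
passing tests demonstrate correctness of the machinery under these
conditions, not clinical performance on real data.

## Statistical conventions

All tests are two-sided at $\alpha = 0.05$.

* **Welch t** (unequal variances, Welch–Satterthwaite df), not the pooled
  t: the Welch form reproduces the published age and $f_1$ statistics
  (0.508 and −5.426) exactly from the printed group moments; pooled does
  not. A summary-moment interface and a raw-sample interface both exist.
* **Chi-square** without Yates continuity correction: reproduces the
  published 12.613 (smoking) and 5.235 (sex) exactly.
* **Mann–Whitney U** via midranks with tie-corrected normal
  approximation and no continuity correction. Published z values for the
  skewed variables are not reproducible without raw data, so the
  convention is documented rather than tuned.
* **Test selection**: Shapiro–Wilk per group at $\alpha = 0.05$; both
  normal → Welch t, else Mann–Whitney. The branch is recorded in the
  result and decides the display form (mean ± SD vs median (IQR)).
* **ICC**: two-way random effects, absolute agreement, single measure,
  from the ANOVA decomposition; absolute agreement (not consistency) so
  systematic reader offsets are penalized.
* **Odds ratios**: cross-product with Wald 95% intervals; zero cells
  raise an error rather than receiving a silent continuity correction.

## Classification layer

The positive class is SCC throughout (smoking OR > 1, $f_1$ OR < 1 fix
the orientation); model output is P(SCC). Logistic models are fitted by
IRLS (tolerance $10^{-8}$, max 100 iterations) with Wald inference.
Perfect separation and collinearity raise classed errors naming the
offending predictor — with one systematic case: because
$f_1+f_2+f_3 = 1$ exactly, entering all three fractions alongside an
intercept is singular, and the pipeline drops the aliased fraction and
records it in the manifest.

ROC analysis uses the empirical AUC (ties count ½), DeLong
structural-component variance for intervals (clipped to [0, 1]), and a
Youden-optimal cutoff with thresholds placed midway between adjacent
observed scores; Youden ties break toward the higher-sensitivity cutoff.
For a marker lower in SCC (like $f_1$ or ADC) the default direction
handling flips orientation so AUC ≥ 0.5 and reports the cutoff in
original units. The published combined-model cutoff is a predicted
probability, implemented as Youden on the fitted probabilities. The
paired DeLong test compares correlated AUCs on the same cases.

Bootstrap validation draws `B` = 1000 stratified resamples, refits,
and reports three summaries — bootstrap mean AUC, the 2.5/97.5 percentile
interval of the resample AUCs, and the optimism-corrected AUC
(apparent − mean(resample AUC − original-data AUC)) — because a single
published bootstrap number is ambiguous between the conventions (and the
published interval is too narrow for a percentile interval at n = 97).
Within resamples, refits that merely separate are retained: divergent
coefficients still rank the cases, so the AUC is well defined, which is
the standard convention for optimism bootstraps; outright failures are
logged and at least 95% of replicates must succeed. Calibration uses
equal-count decile bins plus a logistic recalibration slope/intercept;
decision curves use net benefit
$TP/n - (FP/n)\,p_t/(1-p_t)$ against treat-all and treat-none.

In the univariate screen, fractions enter ×10⁻² and ADC ×10⁻³ mm²/s so
odds ratios are per conventional display unit; computation elsewhere
stays in base units.

## Numerical choices and degenerate inputs

* Simplex validation tolerance $10^{-9}$ absolute; inputs within
  tolerance are renormalized.
* NNLS tolerance $10\,\varepsilon\,\|A\|_F \max(\dim A)$; active-set
  iterations capped at 30 per column.
* Unfittable voxels (all-zero signal, < 2 positive amplitudes,
  non-positive ADC, zero NNLS solution) are dropped from map masks, not
  imputed; an ROI that loses all its voxels raises an empty-ROI error.
* Constant predictions collapse calibration to a single bin; fewer cases
  than bins reduces the bin count with a warning.
* All simulators accept a seed and are bit-reproducible given it; the
  pipeline writes byte-identical bundles for identical configuration.

## Problem sizes in the test suite

The suite runs at desk scale, chosen to keep the full run around a
minute while leaving the statistical bounds meaningful: 100 random
simplex draws for the fitting oracle; 1000 voxels for noise robustness;
10,000 replicates for the Welch type-I check; 100 replicates at n = 5000
for coefficient recovery; 10,000–40,000 draws for distributional
fidelity; 60 replicates of 20 + 20 image-mode patients for the power
property; bootstrap checks at B = 50–200 (determinism does not depend on
B; the pipeline default stays 1000).

## Known limitations

* No Rician bias correction before fitting; at low SNR fraction
  estimates are biased toward the slow compartment.
* The vendor's proprietary fitting algorithm is undocumented, so
  numerical agreement with scanner-produced maps cannot be claimed —
  only agreement with the two models as written.
* Synthetic cohorts model marginals, not joint structure; effect sizes
  combine more favorably than in real patients.
* No exact (permutation) Mann–Whitney p-values; no multiple-testing
  correction (none is part of the emulated workflow); no penalized
  regression, nomograms or external validation.
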