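# rsilung

Quantitative diffusion-MRI analysis for discriminating non-small cell lung
cancer (NSCLC) subtypes — squamous cell carcinoma (SCC) versus
adenocarcinoma (AC) — from multi-b-value diffusion-weighted imaging (DWI),
restriction spectrum imaging (RSI) parameters, clinical covariates and PET
SUVmax. The package is aimed at imaging researchers who want to simulate,
fit and statistically evaluate this kind of multiparametric protocol
end-to-end without access to patient data.

## The models

**Mono-exponential (ADC).** Conventional DWI summarizes diffusion with a
single apparent diffusion coefficient:

$$S(b) = S_0 \, e^{-b \cdot \mathrm{ADC}}$$

fitted here by ordinary least squares of $\log S$ on $b$ over the full
12-point schedule (0–2000 s/mm²).

**Three-compartment RSI.** Restriction spectrum imaging decomposes the
signal into restricted (intracellular), hindered (extracellular) and free
water pools with *fixed* diffusivities $D_1 < D_2 < D_3$
($1, 2, 3 \times 10^{-3}$ mm²/s):

$$S(b) = S_0\left(f_1 e^{-b D_1} + f_2 e^{-b D_2} + f_3 e^{-b D_3}\right),
\qquad f_1 + f_2 + f_3 = 1,\; f_i \ge 0$$

Fixing the diffusivities linearizes the model; the volume fractions are
estimated voxelwise by non-negative least squares (Lawson–Hanson), with
$S_0$ recovered as the sum of the basis weights so the simplex constraint
holds exactly. Magnitude-MRI noise is modelled as Rician.

**Cohort analysis.** On top of the fitting layer the package implements
the complete two-group statistical workflow: Welch *t* / Mann–Whitney U /
chi-square comparisons with a Shapiro–Wilk normality gate,
absolute-agreement ICC for reader reliability, univariate logistic
screening, multivariate logistic modelling (optional backward
elimination), ROC analysis with DeLong intervals and Youden cutoffs,
paired DeLong AUC comparisons, optimism-corrected bootstrap validation,
calibration curves and decision curve analysis. A synthetic-cohort
generator calibrated to published SCC/AC group summaries (30 vs 67
patients) makes every stage testable.

## Worked example

Simulate one voxel at SNR 50, fit both models, then reproduce two of the
published cohort statistics from their printed summaries:

```r
library(rsilung)

sched <- bvalue_schedule()                      # 0 ... 2000 s/mm^2
truth <- compartment_params(0.67, 0.09, 0.24, S0 = 100)
noisy <- add_rician_noise(tri_exp_signal(truth, sched), sigma = 2, seed = 1)

fit_rsi(noisy, sched)$f
#> [1] 0.7378 0.0000 0.2622          # restricted/hindered/free fractions
fit_adc(noisy, sched)$ADC
#> [1] 0.001118                      # mm^2/s

welch_t(67.11, 17.27, 30, 86.27, 13.01, 67)
#> Welch t: statistic = -5.4262 (df = 44.35), p = 2.285e-06

odds_ratio_2x2(21, 9, 21, 46)$or   # smokers 21/30 (SCC) vs 21/67 (AC)
#> [1] 5.111111
```

The Welch *t* of −5.426 says the restricted fraction f1 is markedly lower
in SCC than AC; the odds ratio says smoking multiplies the odds of SCC
about five-fold. The full pipeline (`run_pipeline(run_config(seed = 1))`)
writes descriptive, regression, ROC, validation, calibration and
decision-curve tables plus a manifest to an output directory,
byte-identically for a fixed seed. A thin CLI over the same functions
ships in `inst/cli/rsilung.R`.

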