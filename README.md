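# echoagree

Duplicate-measurement agreement and discrimination analysis for automated
(deep-learning) echocardiography readers, with a synthetic right-heart
cohort generator for method validation.

## The problem

When an automated reader measures right-heart parameters — peak tricuspid
regurgitation velocity (TRV, m/s), RV basal diameter (mm), TAPSE (mm),
right atrial area (cm²), RV end-diastolic/end-systolic areas (cm²), and RV
fractional area change (RVFAC, %) — its clinical usefulness hinges on how
it agrees with expert core-laboratory reads and how well it discriminates
pulmonary hypertension (PH). `echoagree` implements the duplicate-analysis
statistics this evaluation needs:

- **Relative yield**: the proportion of reference reads for which the
  comparator also produced a value, `100 · n_common / n_ref`.
- **Robust bias**: the median paired difference `d_i = comp_i − ref_i`
  (or relative, `r_i = 100 · d_i / pair mean`).
- **Scaled percentile precision**: `½ (P84 − P16) / √2`. The 16th/84th
  percentiles correspond to ∓1 SD of a normal distribution, so the half
  spread is a robust SD of the *differences*; dividing by √2 converts it to
  per-measurement dispersion. Percentiles use the (k−1)/(n−1) linear
  interpolation rule throughout.
- **Percentile bootstrap 95% CIs** (default B = 1000, seed-reproducible;
  the paired difference is the resampling unit).
- Classical companions: **Bland-Altman limits of agreement**
  (mean ± 1.96 SD), **RMS error** (`√mean(d²)`, satisfying
  RMS² = bias² + variance), **Spearman correlation**.
- **Reference change values**: `RCV = √2 · Z · CV_total`,
  `CV_total = √(CV_analytic² + CV_biological²)` — the smallest serial
  change exceeding combined analytic and biological variation.
- **Precision-range equations**: exact linear quantile regression of the
  differences on the pair mean at τ = 0.16 / 0.50 / 0.84 (pinball loss
  minimised by vertex enumeration, never approximated), giving
  `p(x) = ½ (q₀.₈₄(x) − q₀.₁₆(x)) / √2` across the measurement range.
- **Image-quality impact**: Likert scores 1–5 collapsed to low (1–2) /
  moderate (3) / good (4–5); Kruskal-Wallis for median differences and the
  Brown-Forsythe Levene test for equality of variance across categories.
- **Discrimination**: midrank (Mann-Whitney) AUC, paired AUC comparison by
  the DeLong method, greedy age- and sex-matched case-control
  construction, and PH labelling from hemodynamics (strict MPAP >
  20 mm Hg; referral band MPAP ≤ 35 mm Hg).

A fully parameterised synthetic cohort generator
(`generate_case_control_cohort`, `generate_referral_cohort`) produces
case-control and RHC-referral cohorts with known ground truth — latent
severity coupling across parameters, per-reader multiplicative bias and
imprecision, quality-dependent error inflation, per-reader yields, and a
Bernoulli TRV–hemodynamics coupling — so every statistic is testable for
parameter recovery without clinical data.

## Worked example

```r
library(echoagree)

cc  <- generate_case_control_cohort(cohort_config(), seed = 11)
compute_yield(cc$measurements, "TRV", "CL1", "DL")
ds  <- paired_differences(cc$measurements, "TRV", "CL1", "DL")
summary(agreement(ds, scale = "relative", B = 1000, seed = 11))
predict(precision_range(ds), newdata = c(2.5, 4.0))
reference_change_value(10, 5, 1.96)
```

prints

```
TRV: DL yield relative to CL1 = 92.8% (361/389; DL reads 402)
Agreement: TRV, DL vs CL1 (relative scale, n = 361)
  bias (median diff):         0.911%  [-0.251, 2.251]
  precision (scaled):         6.999%  [6.277, 7.807]
  precision (unscaled):       9.898%
  Bland-Altman LoA:           0.941 [-20.260, 22.142]
  RMS error:                 10.843%
  bootstrap: B = 1000, conf = 0.95
    x  tau_0.16   tau_0.5 tau_0.84 precision
1 2.5 -9.163493 0.7564504 10.53962  6.966102
2 4.0 -8.425916 1.6488804 11.65315  7.099023
RCV = sqrt(2) x 1.96 x CV_total(11.2%) = 31.0%
  (analytic CV 10%, biological CV 5%)
```

The automated reader in the default configuration carries a +0.9%
systematic TRV difference and a per-read relative SD near 7%; the fitted
bias (0.91%) and scaled precision (7.0%) recover both, and the
precision-range curve is flat because the default TRV error model is
homoscedastic on the relative scale. An RCV of 31% means a serial TRV
change smaller than ~31% is indistinguishable from combined measurement
and biological noise at α = 0.05.

A thin CLI mirrors the main stages:

```sh
inst/exec/echoagree simulate --config cohort.yaml --seed 17 --out sim/
inst/exec/echoagree agree --input sim/measurements.csv --param TRV --ref CL1 --comp DL --out agree
inst/exec/echoagree rcv --cv-analytic 10 --cv-biological 5 --z 1.96
```

## Documentation

The methods vignette (`vignettes/duplicate-agreement.Rmd`) describes the
estimators, the generative model behind the synthetic cohorts, the
numerical conventions (percentile interpolation, quantile-regression
tie-breaks, bootstrap construction), and known limitations.
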