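---
title: "Duplicate-measurement agreement analysis for automated echocardiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplicate-measurement agreement analysis for automated echocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echoagree)
```

## Scope and model

`echoagree` evaluates a comparator echocardiography reader (typically an
automated deep-learning pipeline, `DL`) against a reference reader
(core-laboratory, `CL1`) on right-heart parameters: peak TRV (m/s), RV
basal diameter (mm), TAPSE (mm), RA area (cm²), RVEDA/RVESA (cm²), and
RVFAC (%). The data model is a long table with one row per
(subject, parameter, reader) read; missingness is real missingness (empty
fields), because yield accounting is part of the analysis.

For one parameter and one reader pair, the paired differences are

* nominal: $d_i = \mathrm{comp}_i - \mathrm{ref}_i$ (positive when the
  comparator reads higher),
* relative: $r_i = 100\, d_i / \bar m_i$ with $\bar m_i$ the pair mean,
  which is also the measurement-range axis $x_i$.

The pair-mean denominator is symmetric in the two readers, the standard
choice in agreement analysis; a reference-value denominator would
attribute all truth to one reader. Pairs with nonpositive pair means have
no defined relative difference; they are excluded from relative-scale
analyses and counted (`n_excluded_relative`).

### Robust bias and scaled percentile precision

Bias is the sample median of the differences; precision is

$$ p = \tfrac12\,(P_{84} - P_{16}) \big/ \sqrt 2 . $$

The 16th and 84th percentiles sit at $\mp 1$ SD of a normal distribution,
so the half spread is a robust analogue of the SD of the differences while
being far less outlier-sensitive. Division by $\sqrt2$ converts
difference-scale dispersion to per-measurement dispersion: a difference of
two reads with common per-read SD $s$ has SD $s\sqrt2$. On generator
output where both readers share relative SD $s$, the scaled relative
precision estimates $\sqrt{(s_\mathrm{ref}^2+s_\mathrm{comp}^2)/2} = s$ up
to the small factor $\Phi^{-1}(0.84) \approx 0.9945$.

**Percentile convention.** All percentiles use linear interpolation with
the $k$-th of $n$ order statistics at probability $(k-1)/(n-1)$ (R's
type-7 rule). Conventions differ at small $n$; fixing one makes
$P_{84}/P_{16}$ reproducible across implementations. On the grid
$0,1,\dots,100$ this gives exactly $P_{16}=16$, $P_{84}=84$.

**Bootstrap.** CIs are percentile-bootstrap with $B = 1000$ resamples by
default: the paired difference (i.e. the subject) is the resampling unit,
preserving pairing; the interval is the 2.5th/97.5th percentile of the $B$
recomputed statistics. The percentile method is the minimal, fully
seed-reproducible reading of "bootstrap CI"; BCa would need jackknife
acceleration and adds nothing at these sample sizes. A degenerate resample
(all values equal) simply yields precision 0 — never an error.

**Companions.** Bland-Altman limits of agreement (mean ± 1.96·SD, $n-1$
denominator) and the RMS error $\sqrt{\overline{d^2}}$ are provided for
comparability with the wider literature; RMS obeys the exact decomposition
$\mathrm{RMS}^2 = \bar d^2 + \sigma_\mathrm{pop}^2$, so in the presence of
bias it always exceeds either robust or SD-based dispersion alone.

**Reference change values.** For serial monitoring,
$\mathrm{RCV} = \sqrt2\, Z\, \mathrm{CV}_\mathrm{total}$ with
$\mathrm{CV}_\mathrm{total} = \sqrt{\mathrm{CV}_A^2 + \mathrm{CV}_I^2}$
combining analytic and within-subject biological variation. With
$\mathrm{CV}_A = 10\%$, $\mathrm{CV}_I = 5\%$ and $Z = 1.96$ the RCV is
31.0%.

### Precision-range equations

Dispersion can vary across the measurement range. Quantile lines
$q_\tau(x) = a_\tau + b_\tau x$ are fitted independently at
$\tau = 0.16, 0.50, 0.84$ by minimising the pinball loss
$\sum_i \rho_\tau(d_i - a - b x_i)$, $\rho_\tau(u) = u(\tau - 1\{u<0\})$.
The precision-range curve is $p(x) = \tfrac12 (q_{0.84}(x) - q_{0.16}(x))$,
divided by $\sqrt2$ by default — the same per-measurement scaling as the
pointwise precision, applied for consistency (a flag disables it, since
the unscaled convention also appears in practice).

Numerical choices:

* The fit is **exact**: the objective is a linear program whose optimum is
  attained on a line through two data points, so the solver enumerates all
  pairwise lines and evaluates the loss in vectorised chunks. No smoothed
  or iterative approximation is involved, which makes the optimum directly
  checkable against a brute-force oracle.
* Ties among optimal lines are broken by smallest slope magnitude, then
  smallest intercept (ties are measure-zero for continuous data).
* If all $x$ are identical the slope is unidentifiable; the fit warns and
  returns the intercept-only solution, the $\tau$-quantile of $d$ (the
  midpoint of the optimal interval when the optimum is not unique, so the
  forced-intercept fit at $\tau = 0.5$ is always the sample median).
* Crossing quantile lines (negative $p(x)$) are reported with a warning,
  never silently clipped or constrained — the three fits are intentionally
  independent.

### Image-quality stratification

Likert scores 1–5 collapse to low (1–2), moderate (3), good (4–5).
Quality is a property of the acquired image, hence shared across readers
of that image. Location shifts across categories are tested with the
Kruskal-Wallis test (midranks, tie-corrected, $\chi^2_{k-1}$ reference);
dispersion differences with the Levene test computed as a one-way ANOVA F
on absolute deviations from the group **median** (the Brown-Forsythe
variant — consistent with the robust theme; mean-centring is available).
Degenerate inputs (all values identical; all deviations zero) return
statistic 0 with $p = 1$.

### Discrimination

AUC uses the midrank (Mann-Whitney) estimator — the mean over all
positive/negative pairs of $1\{x_+ > x_-\} + \tfrac12 1\{x_+ = x_-\}$ —
and paired AUCs are compared with the DeLong method: per-positive and
per-negative structural components computed with midranks, variances and
covariance from their sample covariances scaled by $1/m$ and $1/n$, and a
two-sided normal test on the AUC difference. Markers where lower values
indicate disease (TAPSE, RVFAC) are sign-flipped through a per-parameter
orientation registry, so reported AUCs are on the conventional
$\geq 0.5$ side.

Case-control ROC analysis is preceded by greedy 1:1 age- and sex-matching:
exact sex, nearest age, cases processed hardest-first (fewest eligible
controls), deterministic lexicographic tie-breaks, optional age caliper.
PH labelling from hemodynamics uses the strict rule MPAP > 20 mm Hg (20
itself is no-PH) with referral eligibility MPAP ≤ 35 mm Hg. The guideline
supporting-criteria category (TRV ≤ 2.8 low, 2.9–3.4 intermediate, > 3.4
high; ≥ 2 supporting signs upgrade one level, capped) is encoded as an
editable constant table because those thresholds originate in external
guidelines; the one-level-upgrade reading is one defensible encoding of
how supporting signs modify the TRV band and is isolated behind
`trv_probability_bands()`.

## The synthetic cohort generator

The generator exists so every estimator can be validated for parameter
recovery with known truth. It emulates the statistical structure of a
two-part study design:

**Case-control.** Group sizes default to 213 healthy / 221 PAH. Each
subject carries a latent severity $z \sim N(0,1)$, and the true value of
parameter $p$ in group $g$ is

$$ \theta_p = \mu_{g,p} + \sigma_{g,p}\left(\lambda_p z +
   \sqrt{1-\lambda_p^2}\,\varepsilon_p\right), \qquad
   \varepsilon_p \sim N(0,1), $$

truncated to physiologic bounds by rejection. The default
$(\mu, \sigma)$ pairs are published healthy/PAH reference values (e.g. TRV
2.1 ± 0.5 vs 4.1 ± 0.7 m/s; RVFAC 39.9 ± 3.6 vs 19.7 ± 6.5%). A single
shared severity factor ($|\lambda| = 0.7$ by default, sign following each
parameter's disease direction) is the simplest structure that induces the
jointly shifted parameter distributions seen in disease and supports
matched ROC testing; it does not attempt to reproduce the full empirical
correlation matrix.

**Readers.** Each reader reads the image with probability
`yield_prob[parameter]` and returns $\theta(1+\delta)$,
$\delta \sim N(\mathrm{bias}/100, (\mathrm{sd} \cdot m_q/100)^2)$, where
$m_q \geq 1$ inflates the SD for moderate/low image quality (defaults 1 /
1.3 / 1.6; quality-dependent bias offsets are config-exposed but default
to 0). Reader error is multiplicative because the primary reported
quantities are relative bias and precision. Default yields are per-reader
read counts out of 434 studies; default biases and SDs are calibrated so
that the two pairwise comparisons against the reference reproduce
published relative bias and scaled precision: the two core-lab readers are
assumed exchangeable ($s_{CL1} = s_{CL2} = $ pairwise precision of CL2 vs
CL1), and the automated reader solves
$\sqrt{(s_{CL1}^2 + s_{DL}^2)/2} = $ pairwise precision of DL vs CL1 —
e.g. for TRV, $s_{CL} = 5.35\%$ and $s_{DL} = 7.82\%$ give back 6.70%.
Image quality defaults to good/moderate/low = 0.60/0.25/0.15, a blend of
the reported per-view good-quality rates (44–74%). An optional
contamination component (probability of a 5× error-SD read, default off)
models gross outliers such as non-modal-frequency TRV estimation.

**Referral cohort.** Defaults to 196 subjects with MPAP drawn from a
two-piece uniform on (10, 35) mm Hg with mass 89/196 below the 20 mm Hg
threshold, matching the mild-PH band of an RHC referral population
(pressures above 35 are excluded by construction). Systolic pressure
follows sPAP = a·MPAP + b (defaults a = 1.5, b = 0 — no published
coupling; any monotone map yields the right ROC structure), RAP is fixed
at 5 mm Hg, and true TRV follows the simplified Bernoulli relation
$\mathrm{TRV} = \sqrt{(\mathrm{sPAP}-\mathrm{RAP})/4}$. Other parameters
interpolate between the healthy and case distributions at the subject's
MPAP percentile. Clinical-report reads (`CLINICAL`) are modelled as an
expert reader with core-lab error structure.

**Reproducibility.** One root seed; each subject derives a deterministic
child seed, so cohorts are identical under identical (config, seed) and
stable under partial regeneration. All stochastic analysis functions
(bootstrap, generators) take explicit seeds and restore the caller's RNG
state.

### What the generator does and does not show

Passing recovery tests on this generator demonstrates that the estimators
are correct for multiplicative, normal, conditionally independent reader
error with quality-inflated variance. Real echocardiographic error is not
exactly that: discrepancies cluster (non-modal Doppler frequencies,
segmentation failure in severely dilated ventricles), reader errors can
correlate through the shared image, RVFAC is algebraically tied to the two
areas (the generator draws it as its own parameter), and the true
TRV–MPAP coupling is noisier than a deterministic Bernoulli map — which is
why synthetic referral AUCs run higher than published clinical ones
(~0.75–0.79). Published real-data agreement tables are therefore used
only as calibration defaults, never as reproduction targets.

## Problem sizes used in validation

The bundled suite validates at sizes chosen to keep Monte Carlo error
small relative to the tested tolerances: parameter recovery at 400 pairs ×
200 replicates (median bias within ±0.3 points, precision within 10%
relative), bootstrap coverage over 500 datasets of $n = 200$ with
$B = 1000$ (93–97% band), exact AUC and pinball oracles on 1,000 and 200
random datasets, and 10,000 null simulations per test for type-I control
(rejection in [0.04, 0.06] at $\alpha = 0.05$).

## Known limitations

* Pairwise comparisons only; no variance-components model across three or
  more readers simultaneously.
* Straight quantile lines at three fixed $\tau$; no spline or monotone
  quantile regression, and crossing is reported rather than constrained.
* The DeLong test uses the large-sample normal reference without
  small-sample correction.
* The relative-difference denominator (pair mean) and the $\sqrt2$ scaling
  of the precision-range curve are conventions; both are exposed as
  switches because the literature is not unanimous.
* The supporting-criteria encoding (category upgrade) is one reading of
  how guideline supporting signs combine with TRV; alternatives (logistic
  combination) are out of scope.
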