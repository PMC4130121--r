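---
title: "Validating fasting insulin-sensitivity indices against the euglycemic clamp: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating fasting insulin-sensitivity indices against the euglycemic clamp: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampval)
```

`clampval` implements a complete method-comparison study: fasting
surrogate indices of insulin sensitivity and clinical adiposity
surrogates are validated against insulin-mediated glucose uptake
measured by the hyperinsulinemic euglycemic clamp. This vignette is the
package's own account of the models and the choices behind them. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## The clamp M value

During a clamp, insulin is infused at a constant 80 mU per m² body
surface area per minute and 20% glucose at a variable rate that holds
blood glucose at 100 mg/dL. Once uptake is in steady state, the glucose
infusion rate (GIR) equals whole-body glucose disposal. The package
takes the arithmetic mean of GIR and of blood glucose over the 80–100
min window (endpoints inclusive; samples matched to the 5-min grid
within ±0.5 min), requires at least 3 in-window glucose samples, and
computes the within-window coefficient of variation of glucose. A CV of
5% or more produces a warning, not an exclusion: the protocol quotes a
*mean* CV below 5%, not a per-subject filter.

The M value is

M = mean GIR × (group mean steady-state glucose / individual
steady-state glucose) / kg,

normalised per kg fat-free mass (`m_adjusted`, the headline value) and
per kg body weight (`m_unadjusted`). The multiplicative glucose-space
correction compensates between-subject deviations from the 100 mg/dL
target: uptake scales with the ambient glucose level by mass action, so
a subject clamped slightly high would otherwise look spuriously
insulin-sensitive. The group mean steady-state glucose is computed over
the *analysis* (complete-case) cohort before any per-subject M value.

One definitional point required a decision. The study protocol's text
also says the uptake rate is "divided by the steady-state clamp insulin
concentration", but the reported units (mg·min⁻¹·kg⁻¹) and magnitudes
(≈ 5–12) are incompatible with division by a steady-state insulin of
order 10² µU/mL. We therefore do **not** divide the headline M by
insulin; the insulin-normalised quantity is exposed separately as
`m_over_i = m_adjusted / ss_insulin` for users who want it.

## Fasting indices and units

HOMA-IR and FIRI take glucose in mmol/L (G·I/22.5 and G·I/25; FIRI is
exactly 0.9 × HOMA-IR, an identity the test suite asserts). QUICKI is
1/(log₁₀ I + log₁₀ G) with glucose in mg/dL, and the glucose/insulin
ratio defaults to mg/dL glucose; both are configurable because
published unit conventions vary and the reference study's own unit
labels are internally inconsistent. Two reference-table oddities are
deliberately *not* chased: the printed QUICKI group means (0.11–0.30)
sit far below the range the standard formula can produce for the
printed glucose/insulin means (≈ 0.39 for lean men), and the printed
glucose/insulin ratios are labelled in mmol units but have magnitudes
only consistent with mg/dL. The package implements the standard cited
formulas; reproducing unexplained printed transformations is a
non-goal. Friedewald LDL (TC − HDL − TG/5, mg/dL) errors above the
formula's TG = 400 mg/dL validity bound and warns on negative results.
The lipid unit label "mg/L" in the reference table is treated as a typo
for mg/dL, the only unit in which values of 102–275 are plausible.

## Robust correlation machinery

Associations are estimated on Box-Cox scales: each variable's exponent
is the grid argmax (grid −3 to 3, step 0.01) of the normal profile
log-likelihood including the Jacobian term, selected per variable, after
which each *pair* is fed to an EM estimator of the location and scatter
of a multivariate t distribution with fixed df. The EM weights,
wᵢ = (df + p)/(df + dᵢ²) with dᵢ² the Mahalanobis distance, discount
observations far from the bulk, which is the entire point: a single
aberrant clamp or insulin value should not drive a correlation computed
on 79 subjects. The default df = 4 is the conventional heavy-tailed
choice for robust estimation; the reference analysis cites the method
without stating its tuning, so df is exposed as a parameter. As
df → ∞ the estimate converges to the sample mean and covariance (the
test suite checks agreement with Pearson at df = 10⁶ to 10⁻³, and
agreement with an independent implementation of the same estimator at
df = 4).

Confidence intervals use the Fisher z transform,
tanh(atanh r ± z₀.₉₇₅/√(n−3)). This choice was fixed after verifying it
reproduces the published intervals at n = 79: the lower bound for
r = −0.30 gives −0.49 and both bounds for r = 0.29 give (0.07, 0.48),
exactly as printed. The printed upper bound for r = −0.30 is −0.09
while the rounded input reproduces −0.08; the printed value evidently
derives from the unrounded study correlation (r ≈ −0.305 yields
−0.49/−0.09 exactly), so the acceptance test asserts the value the
method actually produces.

Correlations sharing the clamp variable are compared with the
Williams-modified Steiger t (the form recommended when a single
variable is shared), df = n − 3. The statistic is zero exactly when the
two correlations are equal, and an inconsistent correlation triple
(negative determinant of the implied 3×3 matrix) is a domain error.
When a resistance index (negative correlation) is compared with a
sensitivity index (positive), the pipeline aligns signs by negating the
resistance index's correlations — equivalent to negating that column —
so the comparison is between magnitudes. Two perfectly collinear
indices (HOMA-IR and FIRI) have a singular pair scatter; the
correlation matrix records ±1 there directly and the meaningless
Steiger comparison between them is skipped.

## Robust regression

The adjusted associations are Huber M-estimator fits: IRLS with the
residual scale re-estimated each iteration by the normalised MAD about
zero, tuning constant 1.345 (95% Gaussian efficiency), coefficient
covariance by the standard M-estimator sandwich, p-values from t on
n − p df. Convergence is judged on the maximum coefficient change
*relative to the largest coefficient magnitude* (absolute below 1):
Box-Cox can compress a predictor onto a scale where coefficients are
O(10⁴), making an absolute criterion unattainable at double precision.
With tuning → ∞ the fit equals OLS (tested to 10⁻⁶). Predictors and
outcome enter on their Box-Cox scales by default; because the reference
table's coefficient scaling is not reconstructable from its text,
coefficient magnitudes are not comparison targets, only signs,
p-values and R². R² for a robust fit has no unique definition; the
package uses the squared Pearson correlation of fitted versus observed
values and labels it as such wherever reported.

## Tertile concordance

Each measure is cut into thirds by rank, within sex, with "high" always
meaning high insulin *sensitivity* (resistance indices and adiposity
surrogates are ranked decreasing). For n not divisible by 3 the extra
members go to the extreme groups, low first, then high; ties are broken
by stable original-order ranking, and ties spanning a cut boundary emit
a warning. Because the assignment is rank-based, any strictly monotone
transform of a surrogate gives identical thirds — which is why HOMA-IR
and FIRI produce *identical* concordance rows, as the reference table
also shows. Agreement is summarised by the 3×3 cross-classification,
percent correct within each clamp third, and unweighted Cohen's kappa
(the categories are ordered, but the reference analysis names only "the
kappa test", so no weighting is imposed). The 95% kappa interval is a
percentile bootstrap over 1000 replicates in which subjects are
resampled with replacement and the tertiles recomputed per replicate;
for the all-subjects stratum resampling is unstratified but thirds
remain sex-specific, mirroring how the observed classification is
formed. Replicates with degenerate margins are skipped and counted.

## The synthetic cohort generator

No subject-level data are deposited with the reference study, so the
generator is a first-class module that emulates the study conditions:

- **Stratum structure.** Sex (51/87 male) and BMI category frequencies,
  and within-stratum means/SDs for age, anthropometry, blood pressure,
  lipids, fasting glucose and the adjusted M value, are transcribed
  from the study's descriptive table into a versioned JSON parameter
  file (`inst/extdata/cohort_params.json`). Heights are not reported
  there; sex-level means of 171/160 cm (SD 6.5/6) are used, typical
  adult values for the study region.
- **Latent structure.** A per-subject 4-vector (Z_S, Z_H, Z_B, Z_W) is
  drawn from a Gaussian copula whose correlations are configurable:
  latent insulin sensitivity S_true versus log HOMA-IR (−0.30 default),
  BMI (−0.38) and waist (−0.43), defaults taken from the study's
  observed correlations; cross-correlations among the surrogate
  channels (0.45, 0.45, 0.85) are chosen as realistic adiposity–insulin
  couplings. Positive definiteness is validated at construction.
  S_true and log HOMA-IR are cohort-level lognormals moment-matched to
  the pooled reference summaries, so the configured copula correlation
  *is* the cohort-level correlation — per-stratum insulin and M
  gradients then emerge through the copula rather than being imposed,
  which keeps the headline correlation interpretable. Fasting insulin
  is derived as HOMA·22.5/G with glucose drawn per stratum truncated
  below 7 mmol/L (non-diabetic inclusion). The waist-to-height target
  is reported for reference only: WHtR = waist/height by construction,
  so its correlation is inherited from waist, attenuated by independent
  height variation — the same ordering the study observed (waist −0.43,
  WHtR −0.38).
- **BMI marginals.** BMI is drawn through the sex-level category
  mixture: the copula quantile selects the category band and the
  within-band quantile feeds a truncated normal on the category bin
  whose parent parameters are moment-matched to the printed stratum
  mean and SD. The match weights the mean heavily: for the obese bin
  the printed SD is not attainable by any truncated normal on
  [30, 80) with the printed mean, so the generated obese stratum is
  slightly under-dispersed while its mean is preserved.
- **Clamp traces.** Blood glucose approaches the subject's individual
  steady-state level (100 mg/dL plus an offset with SD 3 mg/dL)
  linearly over 40 min, then holds with 2% within-window CV. GIR ramps
  to S_true × FFM × (achieved glucose/100) over 60 min — the
  mass-action scaling whose removal is precisely the glucose-space
  correction's job — with 4% multiplicative noise per sample. Plasma
  insulin is sampled at 0/80/90/100 min; per-BSA dosing (Du Bois) with
  BSA-proportional clearance makes the steady-state increment
  size-independent at rate/0.6 ≈ 133 µU/mL, with 5% noise. With all
  noise at zero, the M computation recovers S_true to machine
  precision; at the default noise the mean relative error is under 2%
  (both asserted in the tests).

What the generator does **not** emulate: dynamic glucose–insulin
kinetics (steady state is imposed, not simulated), hepatic glucose
production and its incomplete suppression, assay-specific error
structure, or any real skewness/kurtosis beyond what lognormal margins
and truncated-normal strata produce. Passing tests therefore show the
*pipeline's* correctness and calibration under a realistic correlation
structure, not the field behaviour of the indices in any population.

## Descriptive-table tests

Group comparisons use the Kruskal-Wallis test (tie-corrected,
chi-square reference). The study's "p linearity" and interaction
columns name no method; the package implements the trend test as the
two-sided least-squares slope test of the variable on ordinal category
scores 0/1/2, and the heterogeneity test as the 1-df sex × score
product term in a linear model with main effects (a 2-df categorical
variant is available), both stated in the output. Degenerate inputs
take defined paths: identical values across groups give H = 0, p = 1;
empty strata yield NA summaries rather than errors.

## Reproducibility and problem sizes

Every stochastic stage flows from one integer seed: the generator, the
pipeline (`run_config(seed = )`) and the bootstrap. Identical
configurations give identical outputs; changing only the seed of the
bootstrap changes only the interval fields. The test suite exercises
desk-scale problems chosen to keep the full run around a minute:
cohorts of 60–200 for pipeline behaviour, n = 5000 for parameter
recovery (the configured HOMA–clamp correlation of −0.5 is recovered
within ±0.03), 2000 Monte-Carlo replicates at n = 79 for the size of
the Steiger test, and 120 outer replicates for bootstrap coverage.

## Known limitations

- Complete-case analysis only; no imputation (matching the reference
  study's 79/87 complete cases).
- The multivariate-t df and the Box-Cox grid of the original analysis
  are unknown; defaults are conventional and configurable.
- Reference-table regression coefficient magnitudes are not
  reproducible from the published text and are not targeted.
- The bootstrap interval is the simple percentile form; no BCa
  correction.
- Kappa is unweighted; ordered-category weighting is a deliberate
  non-goal, as is any cut-off-based (ROC-style) analysis.
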