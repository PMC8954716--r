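---
title: "Methods: placental lesion severity scoring and postpartum cardiovascular risk screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: placental lesion severity scoring and postpartum cardiovascular risk screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plascreen)
```

## The problem

Preeclampsia marks women for substantially elevated cardiovascular disease
(CVD) risk in later life, and specialized postpartum clinics screen them for
modifiable risk factors around 6 months after delivery. Because such clinics
are resource-intensive, a triage signal available at delivery is valuable.
The placenta is routinely examined after complicated pregnancies, and lesions
of maternal vascular malperfusion (MVM) — infarction, distal villous
hypoplasia, accelerated villous maturation, increased syncytial knots,
perivillous fibrin deposition, villous agglutination — reflect the abnormal
uteroplacental perfusion characteristic of preeclampsia. `plascreen`
implements the full analysis chain that links a synoptic placental pathology
report to the postpartum lifetime CVD risk screen: severity scoring, risk
categorization, association statistics, prediction modelling, and a synthetic
cohort generator that makes every stage testable without patient data.

## Synoptic severity scoring

Each named lesion is scored either binary (0 absent / 1 present) or on a
linear graded scale (0 absent, 1 focal, 2 patchy, 3 diffuse). Lesions are
grouped into seven etiological categories; a category's severity score is the
sum of its member lesion grades, capped at a fixed category maximum:

| category | cap |
|---|---|
| maternal vascular malperfusion | 14 |
| implantation site abnormalities | 4 |
| histological chorioamnionitis | 11 |
| placental villous maldevelopment | 5 |
| fetal vascular malperfusion | 6 |
| maternal-fetal interface disturbance | 5 |
| chronic inflammation | 6 |

The cumulative severity score is the sum over categories, and a placenta is
classified as having **severe MVM** when its MVM category score is at or
above a threshold, default 2 (`mvm_threshold`, exposed everywhere it
matters).

The caps are fixed, but which lesion carries which scale is a design choice
the published category maxima do not fully determine. The shipped scheme
(`inst/extdata/default_scheme.yaml`) assigns scales so member maxima reach
each cap: for MVM, four graded lesions (infarction, distal villous
hypoplasia, accelerated villous maturation, syncytial knots; 4 × 3 = 12) plus
binary perivillous fibrin deposition and villous agglutination give 14.
Retroplacental hematoma is also carried as a binary MVM member because
synoptic report forms group it with maternal malperfusion; its inclusion
makes the member maxima sum to 15, so the cap binds — scoring every MVM
lesion maximal still yields exactly 14. The same happens in chronic
inflammation (graded villitis of unknown etiology and plasma-cell deciduitis
plus binary chronic intervillositis sum to 7 against a cap of 6). For
histological chorioamnionitis, the two reported inflammatory-response lesions
cannot reach the cap of 11 on these scales, so the scheme carries the
standard staged components of the amniotic infection sequence
(subchorionitis, funisitis, chorionic plate vasculitis) as additional
members. The whole assignment lives in the editable scheme file, not in
code; users with the original collection form can replace it and every
operation downstream follows the file.

Missing lesion assessments score 0 (a lesion not recorded cannot contribute
severity) but are never silent: each participant's profile carries
`n_lesions_observed` / `n_lesions_total` and a `complete` flag, because real
pathology reports omit assessments unevenly.

Scoring is deliberately dual-routed internally: `severity_profile()` is the
per-participant reference implementation, and `score_cohort()` is an exactly
equivalent vectorized implementation used on whole cohorts; the test suite
holds the two to exact agreement, along with monotonicity (raising any grade
never lowers any score), cap saturation, idempotence and permutation
invariance.

## The categorical lifetime CVD risk screen

At 6 months postpartum seven risk factors are measured: total cholesterol,
systolic blood pressure, diastolic blood pressure, anti-hypertensive use,
fasting glucose, diabetes diagnosis, and current smoking. Each is stratified
as optimal / not optimal / elevated / major, and the categorical lifetime
risk estimate follows from the counts in highest-severity-first priority
order:

* ≥ 2 major factors → **50%**
* exactly 1 major factor → **39%**
* otherwise ≥ 1 elevated → **39%**
* otherwise ≥ 1 not optimal → **27%**
* all optimal → **8%**

and is dichotomized at 39% into low (< 39%) versus high (≥ 39%) lifetime
risk — 39% being the baseline lifetime risk of an optimal-profile woman in
the Framingham cohort tradition. Reading the rules as
highest-severity-wins is a design decision; the test suite sweeps all
4^7 = 16,384 possible strata assignments against an independent counting
oracle to pin the semantics down, and checks that promoting any single
factor to a worse stratum never lowers the category (monotonicity). The two
39% branches are kept distinct internally even though they collapse under
dichotomization.

The numeric thresholds per factor are not part of the tested contract: they
come from the external lifetime-risk stratification literature and are
shipped as an editable rules file (`inst/extdata/default_risk_rules.yaml`)
with the provenance stated in its header. Boolean factors map TRUE → major,
FALSE → optimal.

Missing measurements follow a configurable policy — `error` (default),
`impute_optimal`, or `exclude` — with the conservative default on the
grounds that silently imputing a clinical screen is unsafe; imputed counts
are reported per participant when imputation is requested.

## Association statistics

The exposure-outcome association (severe MVM × high risk) is summarized by a
2×2 table with the cross-product odds ratio and its 95% confidence interval
on the log-odds scale (the Woolf/logit interval),
exp(ln OR ± 1.96 √(1/a + 1/b + 1/c + 1/d)), and the Pearson chi-square test
without continuity correction. Both choices are deliberate: on the reference
counts (29, 9, 24, 23) they reproduce OR 3.09 with CI (1.20, 7.92) and
p = 0.017, the convention used in the clinical reports this package mirrors.
Yates correction is available as a flag for sensitivity analysis, never the
default. Zero cells make the OR undefined by default (flagged, not silently
fixed); the Haldane–Anscombe +0.5 adjustment is opt-in. The chi-square
statistic is held to the squared two-proportion z-statistic and to a generic
observed-vs-expected oracle to 1e-10 in tests, and the 95% interval's
coverage is verified empirically (93–97% across 2,000 simulated tables with
a known OR of 2, at 200 per group).

Two-group continuous comparisons choose between Student's t and
Mann–Whitney U. The choice rule is not standardized in clinical practice;
here both samples are screened with Shapiro–Wilk at α = 0.05 and the t-test
is used only when neither rejects, with the method always recorded in the
output and overridable. Groups under 3 observations, and degenerate
zero-variance t-tests, fall back to Mann–Whitney with a warning.

Sample size for comparing two proportions uses the standard
normal-approximation formula with pooled variance under the null:
n per group = (z₁₋α/2 √(2 p̄ q̄) + z_power √(p₁q₁ + p₂q₂))² / (p₁ − p₂)².
For proportions 0.547 vs 0.281 at α = 0.05 and power 0.80 it returns 53 per
group. Published reports of comparable designs sometimes print smaller
totals; formulas with and without continuity correction differ, so the
formula used here is stated explicitly rather than reverse-engineered from
any particular printed value.

## Prediction models and ROC analysis

Three pre-registered logistic models predict high-risk screening:

* **clinical**: maternal age, gestational weight gain, systolic and
  diastolic blood pressure at delivery, gestational age at delivery;
* **mvm**: the severe-MVM indicator;
* **combined**: both sets.

"Blood pressure at delivery" is genuinely ambiguous; both pressures enter as
separate covariates by default, with `bp = "systolic"` or `"map"` switches.
The MVM model uses the binary severe-MVM indicator rather than the raw
0–14 score by default: a single-point ROC whose area is
(sensitivity + specificity)/2 is exactly what the dichotomized exposure
produces, matching how the screening question is posed clinically;
`mvm_covariate = "mvm_score"` switches to the raw score.

Fitting is maximum likelihood by iteratively reweighted least squares
(relative deviance tolerance 1e-8, at most 100 iterations) on complete
cases. Rank-deficient designs abort with the collinear columns named;
(quasi-)complete separation — detected from boundary fitted probabilities or
runaway coefficients — is flagged and warned about, with coefficients still
reported. The fit is cross-checked in tests against closed-form group logits
and an independent derivative-free maximizer of the log-likelihood.

The AUC is computed as pairwise concordance with ties counted ½ (the
Mann–Whitney identity, evaluated via midranks in O(n log n)); the test suite
holds it to brute-force pair counting and to the trapezoidal area under the
empirical ROC to 1e-12, and to invariance under strictly increasing score
transforms. The AUC confidence interval uses the Hanley–McNeil standard
error — chosen for determinism and closed form; DeLong-style resampling
alternatives would add a dependency without changing any decision this
package supports. The reported operating point maximizes Youden's J
(ties broken toward higher sensitivity), with Wilson score intervals on
sensitivity and specificity. AUCs are in-sample (apparent), matching
clinical reporting practice for cohort-development studies; no
cross-validation is applied by default.

## The synthetic cohort generator

`generate_cohort()` emulates the data structure of a two-site preeclampsia
cohort so the whole pipeline is testable with known ground truth:

1. lesion presence is Bernoulli per lesion with default prevalences pooled
   from an 85-woman preeclampsia cohort's lesion frequency table; grades
   given presence are uniform over the positive grades (presence frequencies
   are what such tables publish; the conditional grade distribution is a
   transparent default, configurable);
2. MVM severity comes from the scoring engine itself, not a shortcut;
3. clinical covariates are drawn from normal marginals matching the combined
   cohort (maternal age 31.9 ± 6.0 y, gestational weight gain 14.0 ± 7.1 kg,
   delivery systolic/diastolic BP 152 ± 25 / 93 ± 13 mmHg, gestational age
   35.1 ± 4.3 weeks), clipped to plausible clinical ranges;
4. the high-risk outcome is Bernoulli from a logistic model whose exposure
   coefficient is ln(`target_or`) on the severe-MVM indicator; the intercept
   is the closed-form logit of `baseline_highrisk_rate`, the high-risk rate
   among unexposed women (default 24/47 ≈ 0.51, the unexposed rate of the
   reference cohort). Weak standardized clinical effects (+0.15 per SD of
   delivery systolic BP, −0.10 per SD of gestational age) are added so the
   combined model has signal beyond MVM alone;
5. the seven postpartum measurements are back-filled by sampling a strata
   assignment consistent with the drawn outcome (low-risk women split
   between all-optimal and not-optimal profiles, 0.20/0.80; high-risk women
   between elevated, single-major and double-major routes, 0.45/0.30/0.25)
   and then sampling measurements uniformly within each stratum's interval.
   Consistency is by construction, not rejection: the risk calculator
   recomputes the intended group exactly, which the tests verify.

Generation is byte-identical given the seed and leaves the caller's RNG
stream untouched.

**What the generator does not emulate.** Lesions default to independence,
but real MVM lesions co-occur strongly; with independent draws at the pooled
prevalences, roughly 80% of synthetic placentas reach an MVM score ≥ 2,
versus ~45% in real preeclampsia cohorts. An optional shared latent
"placental dysfunction" factor (`lesion_latent_sd` on the logit scale)
induces co-occurrence and lowers that prevalence, but no claim is made that
it matches any real correlation structure. Site effects, gestational-age-
dependent lesion processes, measurement error in the postpartum screen, and
correlation between lesion severity and the clinical covariates are all
absent. Consequently, passing parameter-recovery tests demonstrates that the
pipeline's estimators are consistent for the model that generated the data —
it does not validate the clinical association itself, which only a real
cohort can do. In particular the exposure-marginal odds ratio recovered from
a synthetic cohort estimates the generator's conditional odds ratio with
only negligible attenuation here because the added covariate effects are
weak; users raising `clinical_effects` should expect non-collapsibility to
widen that gap.

## Numerical choices

* IQR and quantiles use linear interpolation (R type 7), stated because
  order-statistic conventions differ across software.
* Descriptives use the same Shapiro–Wilk α = 0.05 gate as the group
  comparisons to choose mean ± SD versus median (IQR); Shapiro–Wilk is
  evaluated on an even 5,000-point subsample for larger columns (its n
  ceiling), and constant columns short-circuit to mean ± SD with SD 0.
* The severe-MVM flag uses ≥ (score 2 is severe), tested to flip exactly at
  the threshold.
* Reports carry unrounded values alongside display strings, so rounding can
  never mask a discrepancy (a cross-product OR of 3.088 prints as 3.09 while
  some sources would print 3.10; both are visible).
* Identical constant samples under Mann–Whitney return p = 1 (no evidence of
  difference) rather than NA.

## Validation scale

The shipped validation exercises the pipeline at the sizes where its
statistical properties are visible: odds-ratio and nested-AUC recovery on a
single seeded cohort of n = 100,000; coefficient recovery at n = 5,000
(± 0.15); interval coverage over 2,000 simulated tables; and the exhaustive
16,384-combination sweep of the risk categorizer. The whole suite runs in
well under a minute on one CPU.

## Known limitations

* The default scheme's per-lesion scale assignment is cap-consistent but not
  guaranteed identical to any particular institution's synoptic form; the
  scheme file is the contract, edit it to match local practice.
* The default risk-factor thresholds are transcribed from external
  literature and are a starting point, not a clinical recommendation.
* Only the categorical lifetime risk estimate is implemented — not 10-year
  or continuous risk equations, and no treatment logic.
* Fisher's exact test and stratified (Mantel–Haenszel) analyses are out of
  scope; the Pearson chi-square without correction is the primary test by
  design.
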