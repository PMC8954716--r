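# plascreen

Placental lesion severity scoring and postpartum cardiovascular risk
screening after preeclampsia.

## What problem this solves

Women who develop preeclampsia carry a markedly elevated lifetime risk of
cardiovascular disease (CVD), and specialized clinics screen them for risk
factors around 6 months postpartum. Screening every preeclamptic woman is
resource-prohibitive, so a triage signal available at delivery is needed.
The placenta — routinely examined after complicated pregnancies — is a
candidate: lesions of **maternal vascular malperfusion (MVM)** reflect the
abnormal uteroplacental perfusion underlying the disorder and may mark the
women most likely to screen high-risk later.

`plascreen` is aimed at perinatal epidemiologists and placental pathology
groups who want this analysis chain as tested, reusable code:

* **Synoptic severity scoring** — each lesion is scored binary
  (0 absent / 1 present) or graded (0 absent, 1 focal, 2 patchy,
  3 diffuse); scores sum within seven etiological categories and are capped
  at the category maxima (MVM 14, implantation site abnormalities 4,
  histological chorioamnionitis 11, villous maldevelopment 5, fetal
  vascular malperfusion 6, maternal–fetal interface disturbance 5, chronic
  inflammation 6). A placenta with MVM score ≥ 2 is classified severe-MVM.
  The scheme is a shipped, editable YAML file.
* **Categorical lifetime CVD risk** — seven postpartum factors (total
  cholesterol, systolic/diastolic BP, anti-hypertensive use, fasting
  glucose, diabetes, smoking) are each stratified optimal / not optimal /
  elevated / major and combined in priority order: ≥2 major → 50%,
  1 major → 39%, ≥1 elevated → 39%, ≥1 not optimal → 27%, all optimal → 8%;
  dichotomized at ≥39% into high vs low lifetime risk.
* **Association statistics** — 2×2 construction, cross-product odds ratio
  OR = ad/bc with the 95% Woolf interval
  exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d)), Pearson chi-square without
  continuity correction, t / Mann–Whitney comparisons behind a stated
  normality gate, and two-proportion sample-size calculation.
* **Prediction models** — multivariable logistic regression (clinical-only,
  MVM-only, combined) evaluated by ROC AUC (Mann–Whitney concordance,
  Hanley–McNeil CI) at the Youden-optimal operating point.
* **Synthetic cohorts** — a generator with known ground truth (target
  severe-MVM→high-risk odds ratio, default 3.1) so every stage is testable
  without patient data.

## Worked example

Score one placenta from pathologist-recorded grades:

```r
library(plascreen)
obs <- data.frame(participant_id = "P001",
                  lesion_id = c("placental_infarction", "syncytial_knots",
                                "accelerated_villous_maturation"),
                  grade = c("focal", "diffuse", "patchy"))
severity_profile(obs, default_scheme())
#> Placental severity profile for participant P001
#>   mvm                      6
#>   implantation_site        0
#>   chorioamnionitis         0
#>   villous_maldevelopment   0
#>   fvm                      0
#>   mfi_disturbance          0
#>   chronic_inflammation     0
#>   cumulative score: 6  severe MVM: TRUE
```

Focal infarction (1) + diffuse syncytial knots (3) + patchy accelerated
villous maturation (2) sum to an MVM score of 6, at or above the severity
cut-point of 2, so this placenta is flagged severe-MVM.

Association from published-style 2×2 counts (29 exposed/high-risk,
9 exposed/low, 24 unexposed/high, 23 unexposed/low):

```r
associate(contingency_2x2(29, 9, 24, 23))
#> OR 3.09 (1.20-7.92), chi-square 5.71, p = 0.017
```

Women with severe MVM lesions have three-fold higher odds of screening
high-risk; the interval excludes 1 and the chi-square test agrees
(p = 0.017).

End-to-end on a synthetic 85-woman cohort with a generating odds ratio of
3.1:

```r
sc <- generate_cohort(cohort_params(n = 85, seed = 4))
run_pipeline(sc)
#> plascreen run report: n = 85 participants
#>   high risk: 62 (72.9%)
#>   severe MVM vs high lifetime CVD risk: OR 4.98 (1.50-16.56), chi-square 7.69, p = 0.006
#> Prediction model comparison (in-sample):
#>     model  n                  auc sensitivity specificity
#>  clinical 85 0.707 (0.591, 0.822)        71.0        65.2
#>       mvm 85 0.626 (0.497, 0.754)        90.3        34.8
#>  combined 85 0.753 (0.647, 0.859)        74.2        69.6
```

At n = 85 the estimated OR (4.98) scatters widely around the generating 3.1
— exactly the sampling variability a cohort of this size implies; at
n = 100,000 the estimate lands within a few percent of 3.1 (see the test
suite). The combined model's apparent AUC exceeds the MVM-only model's, as
expected when clinical covariates carry independent signal.

A thin command-line wrapper over the same functions is shipped at
`inst/cli/pps.R` (subcommands `simulate`, `score`, `risk`, `associate`,
`predict`, `run`).

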