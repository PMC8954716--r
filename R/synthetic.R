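#' Default lesion presence probabilities for the synthetic cohort
#'
#' Pooled presence frequencies of the default-scheme lesions in a
#' preeclampsia cohort (both risk groups combined, n = 85). Lesions absent
#' from the source cohort keep probability 0; the three chorioamnionitis
#' sub-lesions without reported frequencies carry small plausible values.
#'
#' @return Named numeric vector of probabilities, one per default-scheme
#'   lesion.
#' @export
default_lesion_prevalences <- function() {
  c(placental_infarction            = 23 / 85,
    distal_villous_hypoplasia       = 23 / 85,
    accelerated_villous_maturation  = 43 / 85,
    syncytial_knots                 = 51 / 85,
    perivillous_fibrin_deposition   = 11 / 85,
    villous_agglutination           = 8 / 85,
    retroplacental_hematoma         = 2 / 85,
    insufficient_vessel_remodeling  = 9 / 85,
    fibrinoid_necrosis              = 6 / 85,
    maternal_inflammatory_response  = 6 / 85,
    fetal_inflammatory_response     = 4 / 85,
    subchorionitis                  = 0.05,
    funisitis                       = 0.03,
    chorionic_plate_vasculitis      = 0.03,
    delayed_villous_maturation      = 3 / 85,
    chorangiosis                    = 0,
    chorangiomas                    = 0,
    avascular_fibrotic_villi        = 2 / 85,
    thrombosis                      = 2 / 85,
    intramural_fibrin_deposition    = 3 / 85,
    karyorrhexis                    = 0,
    intervillous_thrombi            = 6 / 85,
    massive_perivillous_fibrin_pattern = 1 / 85,
    maternal_floor_infarction_pattern  = 0,
    villitis_unknown_etiology       = 8 / 85,
    chronic_plasma_cell_deciduitis  = 8 / 85,
    chronic_intervillositis         = 0)
}

.default_clinical <- data.frame(
  variable = c("maternal_age", "gestational_weight_gain",
               "systolic_bp_delivery", "diastolic_bp_delivery",
               "gestational_age_delivery"),
  mean = c(31.9, 14.0, 152, 93, 35.1),
  sd   = c(6.0, 7.1, 25, 13, 4.3),
  lower = c(16, -10, 80, 40, 24),
  upper = c(55, 45, 260, 160, 42),
  stringsAsFactors = FALSE
)

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the study conditions: n = 85 participants, lesion
#' prevalences pooled from the observed cohort, a severe-MVM to high-risk
#' odds ratio of 3.1, and a high-risk screening rate of 24/47 among
#' participants without severe MVM lesions (so the intercept of the outcome
#' model is its logit in closed form). Grades given presence are uniform
#' over the positive grades. `clinical_effects` adds weak standardized
#' clinical effects to the outcome logit so that the combined prediction
#' model nests informatively above the MVM-only model.
#'
#' @param n Number of participants.
#' @param target_or Odds ratio linking severe MVM to high-risk screening.
#' @param baseline_highrisk_rate P(high risk) among participants without
#'   severe MVM, at clinical covariate means.
#' @param lesion_prevalences Named presence probabilities per lesion.
#' @param clinical_effects Named vector of logit coefficients per standard
#'   deviation of clinical covariates (default 0.15 for systolic BP at
#'   delivery, -0.10 for gestational age at delivery).
#' @param lesion_latent_sd Standard deviation of a shared latent
#'   "placental dysfunction" factor inducing lesion co-occurrence on the
#'   logit scale (0 = independent lesions, the default).
#' @param mvm_threshold Severe-MVM cut-point on the MVM category score.
#' @param highrisk_mix Probabilities that a high-risk participant's intended
#'   lifetime risk category arises as (elevated-39, one-major-39,
#'   two-major-50).
#' @param lowrisk_mix Probabilities that a low-risk participant is
#'   (all-optimal-8, not-optimal-27).
#' @param seed Integer RNG seed; generation is byte-identical given the seed.
#' @return A validated `cohort_params` object.
#' @export
cohort_params <- function(n = 85L,
                          target_or = 3.1,
                          baseline_highrisk_rate = 24 / 47,
                          lesion_prevalences = default_lesion_prevalences(),
                          clinical_effects = c(systolic_bp_delivery = 0.15,
                                               gestational_age_delivery = -0.10),
                          lesion_latent_sd = 0,
                          mvm_threshold = 2L,
                          highrisk_mix = c(elevated = 0.45, one_major = 0.30,
                                           two_major = 0.25),
                          lowrisk_mix = c(optimal = 0.20, not_optimal = 0.80),
                          seed = 1L) {
  stopifnot(n > 0, target_or > 0,
            baseline_highrisk_rate > 0, baseline_highrisk_rate < 1,
            all(lesion_prevalences >= 0), all(lesion_prevalences <= 1),
            lesion_latent_sd >= 0)
  if (abs(sum(highrisk_mix) - 1) > 1e-8 || abs(sum(lowrisk_mix) - 1) > 1e-8) {
    stop("highrisk_mix and lowrisk_mix must each sum to 1", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), target_or = target_or,
         baseline_highrisk_rate = baseline_highrisk_rate,
         lesion_prevalences = lesion_prevalences,
         clinical_effects = clinical_effects,
         lesion_latent_sd = lesion_latent_sd,
         mvm_threshold = as.integer(mvm_threshold),
         highrisk_mix = highrisk_mix, lowrisk_mix = lowrisk_mix,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

# Uniform sampling ranges used to back-fill measurements within a stratum.
# Upper bounds for the open-ended major strata are clinically plausible caps.
.stratum_ranges <- list(
  total_cholesterol = rbind(optimal = c(3.0, 4.69), not_optimal = c(4.7, 5.19),
                            elevated = c(5.2, 6.19), major = c(6.2, 8.5)),
  systolic_bp       = rbind(optimal = c(95, 119), not_optimal = c(120, 139),
                            elevated = c(140, 159), major = c(160, 200)),
  diastolic_bp      = rbind(optimal = c(60, 79), not_optimal = c(80, 89),
                            elevated = c(90, 99), major = c(100, 130)),
  fasting_glucose   = rbind(optimal = c(3.8, 5.59), not_optimal = c(5.6, 6.09),
                            elevated = c(6.1, 6.99), major = c(7.0, 11.0))
)
.numeric_factors <- names(.stratum_ranges)
.boolean_factors <- c("antihypertensive_use", "diabetes_diagnosis", "current_smoker")

# Sample risk-factor strata and measurements for all participants at once so
# that the lifetime-risk categorization recomputes each intended category
# exactly. Factors not pinned by the category may float between optimal and
# not_optimal (probability 0.3) without changing the category.
.backfill_measurements <- function(category) {
  n <- length(category)
  factors <- c(.numeric_factors, .boolean_factors)
  strata <- matrix("optimal", n, length(factors),
                   dimnames = list(NULL, factors))
  # background not_optimal noise on numeric factors (overridden below)
  for (f in .numeric_factors) {
    strata[stats::runif(n) < 0.3, f] <- "not_optimal"
  }
  # all-optimal category: clear the noise
  strata[category == "8", ] <- "optimal"
  # 27: at least one numeric not_optimal
  i27 <- which(category == "27")
  if (length(i27)) {
    none <- i27[rowSums(strata[i27, .numeric_factors, drop = FALSE] ==
                          "not_optimal") == 0]
    strata[cbind(none, sample.int(length(.numeric_factors), length(none),
                                  replace = TRUE))] <- "not_optimal"
  }
  # 39 via elevated: exactly one numeric factor elevated, none major
  i39e <- which(category == "39_elevated")
  if (length(i39e)) {
    strata[cbind(i39e, sample.int(length(.numeric_factors), length(i39e),
                                  replace = TRUE))] <- "elevated"
  }
  # 39 via a single major factor (numeric or boolean)
  i39m <- which(category == "39_major")
  if (length(i39m)) {
    strata[cbind(i39m, sample.int(length(factors), length(i39m),
                                  replace = TRUE))] <- "major"
  }
  # 50: two distinct major factors
  i50 <- which(category == "50")
  if (length(i50)) {
    f1 <- sample.int(length(factors), length(i50), replace = TRUE)
    f2 <- sample.int(length(factors) - 1L, length(i50), replace = TRUE)
    f2 <- f2 + (f2 >= f1)
    strata[cbind(i50, f1)] <- "major"
    strata[cbind(i50, f2)] <- "major"
  }
  out <- list()
  for (f in .numeric_factors) {
    rg <- .stratum_ranges[[f]]
    lo <- rg[strata[, f], 1]
    hi <- rg[strata[, f], 2]
    out[[f]] <- round(stats::runif(n, lo, hi), 2)
  }
  for (f in .boolean_factors) out[[f]] <- unname(strata[, f] == "major")
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Generate a synthetic study cohort
#'
#' Simulation proceeds in five steps: (1) lesion presence is drawn per
#' lesion prevalence (optionally correlated through a shared latent factor)
#' and grades given presence are uniform over the positive grades; (2) MVM
#' severity is computed with the scoring engine and the shipped scheme;
#' (3) clinical covariates are drawn from truncated normal marginals;
#' (4) the high-risk outcome is drawn from a logistic model with exposure
#' coefficient ln(target_or) on the severe-MVM indicator, intercept
#' logit(baseline_highrisk_rate), plus the configured weak clinical effects;
#' (5) postpartum risk-factor measurements are back-filled by sampling a
#' strata assignment consistent with the drawn outcome and then sampling
#' measurements within each stratum's interval, so the risk calculator
#' recomputes the intended risk group by construction.
#'
#' @param params A [cohort_params] object.
#' @param scheme Scoring scheme used for step (2); default shipped scheme.
#' @param rules Stratification rules used to verify the back-fill; default
#'   shipped rules.
#' @return A `synthetic_cohort`: list with `cohort` (data.frame, one row per
#'   participant: lesion grades in wide format, severity scores, clinical
#'   covariates, risk-factor measurements, `lifetime_risk_percent`,
#'   `risk_group`) and `params` (the generating ground truth).
#' @examples
#' sc <- generate_cohort(cohort_params(n = 50, seed = 7))
#' table(sc$cohort$mvm_severe, sc$cohort$risk_group)
#' @export
generate_cohort <- function(params = cohort_params(), scheme = default_scheme(),
                            rules = default_risk_rules()) {
  stopifnot(inherits(params, "cohort_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  n <- params$n
  prev <- params$lesion_prevalences
  unknown <- setdiff(names(prev), scheme$lesions$lesion_id)
  if (length(unknown)) {
    stop("lesion_prevalences reference lesion(s) not in the scheme: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pid <- sprintf("S%05d", seq_len(n))

  # (1) lesion presence and grades
  latent <- if (params$lesion_latent_sd > 0) {
    stats::rnorm(n, 0, params$lesion_latent_sd)
  } else rep(0, n)
  grades <- matrix(0L, n, length(prev), dimnames = list(NULL, names(prev)))
  for (lid in names(prev)) {
    p <- prev[[lid]]
    pr <- if (p <= 0) rep(0, n) else if (p >= 1) rep(1, n) else
      stats::plogis(stats::qlogis(p) + latent)
    present <- stats::rbinom(n, 1L, pr) == 1L
    max_g <- .lesion_row(lid, scheme)$max_grade
    g <- integer(n)
    g[present] <- sample.int(max_g, sum(present), replace = TRUE)
    grades[, lid] <- g
  }

  # (2) severity via the scoring engine
  long <- do.call(rbind, lapply(colnames(grades), function(lid) {
    data.frame(participant_id = pid, lesion_id = lid, grade = grades[, lid],
               stringsAsFactors = FALSE)
  }))
  scores <- score_cohort(long, scheme, mvm_threshold = params$mvm_threshold)
  scores <- scores[match(pid, scores$participant_id), ]

  # (3) clinical covariates (normal, clipped to plausible ranges)
  clin <- .default_clinical
  clinical <- lapply(seq_len(nrow(clin)), function(i) {
    pmin(pmax(stats::rnorm(n, clin$mean[i], clin$sd[i]), clin$lower[i]),
         clin$upper[i])
  })
  names(clinical) <- clin$variable

  # (4) outcome from the logistic exposure model
  logit <- stats::qlogis(params$baseline_highrisk_rate) +
    log(params$target_or) * as.numeric(scores$mvm_severe)
  for (v in names(params$clinical_effects)) {
    i <- match(v, clin$variable)
    if (is.na(i)) stop("clinical_effects references unknown covariate: ", v,
                       call. = FALSE)
    logit <- logit + params$clinical_effects[[v]] *
      (clinical[[v]] - clin$mean[i]) / clin$sd[i]
  }
  high <- stats::rbinom(n, 1L, stats::plogis(logit)) == 1L

  # (5) back-fill risk-factor measurements consistent with the outcome
  category <- character(n)
  hr_lab <- c("39_elevated", "39_major", "50")
  lr_lab <- c("8", "27")
  category[high] <- sample(hr_lab, sum(high), replace = TRUE,
                           prob = params$highrisk_mix)
  category[!high] <- sample(lr_lab, sum(!high), replace = TRUE,
                            prob = params$lowrisk_mix)
  rf <- .backfill_measurements(category)

  cohort <- data.frame(participant_id = pid, stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(grades), as.data.frame(clinical), rf)
  cohort$mvm_score <- scores$mvm_score
  cohort$cumulative_score <- scores$cumulative_score
  cohort$mvm_severe <- scores$mvm_severe
  cohort <- assess_risk(cohort, rules, missing = "error")
  mismatch <- mean(cohort$risk_group != ifelse(high, "high", "low"))
  if (mismatch > 0.01) {
    stop("risk-factor back-fill failed to reproduce the intended risk group ",
         "for ", round(100 * mismatch, 1), "% of participants; check that the ",
         "rules file matches the generator's stratum ranges", call. = FALSE)
  }
  structure(list(cohort = cohort, params = params), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: n =", nrow(x$cohort), "participants\n")
  if (!is.null(x$params)) {
    cat("  target OR:", x$params$target_or,
        " baseline high-risk rate:", round(x$params$baseline_highrisk_rate, 3),
        " seed:", x$params$seed, "\n")
  }
  cat("  severe MVM:", sum(x$cohort$mvm_severe), sep = " ")
  if (!is.null(x$cohort$risk_group)) {
    cat("  high risk:", sum(x$cohort$risk_group == "high"))
  }
  cat("\n")
  invisible(x)
}

#' Deterministic 12-participant fixture cohort
#'
#' Hand-set records covering every lesion category of the default scheme,
#' all four lifetime-risk categories (8, 27, 39, 50), a maximal-MVM
#' placenta, a pathology-free placenta, and one participant with a missing
#' cholesterol measurement (the missing-data case). Used across the unit
#' tests; risk columns are left uncomputed for the missing-data participant
#' until a missing-data policy is chosen via [assess_risk()].
#'
#' @return A `synthetic_cohort` with `params = NULL` and the intended
#'   lifetime-risk category of each participant in the `ground_truth`
#'   element.
#' @export
fixture_small <- function() {
  scheme <- default_scheme()
  lesions <- scheme$lesions$lesion_id
  g <- matrix(0L, 12, length(lesions), dimnames = list(NULL, lesions))
  # p02: severe MVM (infarction patchy + knots focal = 3)
  g[2, "placental_infarction"] <- 2L; g[2, "syncytial_knots"] <- 1L
  # p03: chorioamnionitis (maternal stage diffuse, funisitis present)
  g[3, "maternal_inflammatory_response"] <- 3L; g[3, "funisitis"] <- 1L
  # p04: MVM score 1 only (below threshold)
  g[4, "accelerated_villous_maturation"] <- 1L
  # p05: fetal vascular malperfusion
  g[5, "avascular_fibrotic_villi"] <- 2L; g[5, "thrombosis"] <- 1L
  # p06: villous maldevelopment
  g[6, "delayed_villous_maturation"] <- 2L
  # p07: chronic inflammation
  g[7, "villitis_unknown_etiology"] <- 1L
  g[7, "chronic_plasma_cell_deciduitis"] <- 1L
  # p08: maternal-fetal interface disturbance
  g[8, "intervillous_thrombi"] <- 2L
  # p09: implantation site abnormality
  g[9, "insufficient_vessel_remodeling"] <- 2L
  g[9, "fibrinoid_necrosis"] <- 1L
  # p10: every lesion maximal (all category caps bind)
  g[10, ] <- scheme$lesions$max_grade
  # p11: single focal knots
  g[11, "syncytial_knots"] <- 1L
  # p12: retroplacental hematoma
  g[12, "retroplacental_hematoma"] <- 1L

  cohort <- data.frame(
    participant_id = sprintf("p%02d", 1:12),
    maternal_age = c(30, 34, 28, 41, 33, 29, 36, 31, 27, 38, 32, 25),
    gestational_weight_gain = c(12, 15, 9, 18, 14, 11, 16, 13, 10, 20, 12, 8),
    systolic_bp_delivery = c(142, 158, 150, 147, 166, 139, 155, 149, 144, 172, 141, 138),
    diastolic_bp_delivery = c(88, 97, 92, 90, 103, 86, 95, 91, 89, 108, 87, 85),
    gestational_age_delivery = c(38.0, 34.5, 36.0, 37.2, 32.1, 38.5, 35.0, 36.8,
                                 39.0, 30.4, 38.2, 37.0),
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(g))
  # intended categories:        8     39e    50     27     39m    NA(missing)
  #                             27    39e    8      50     8      27
  cohort$total_cholesterol  <- c(4.2, 4.5, 5.0, 4.9, 4.3, NA, 4.8, 4.4, 4.1, 7.0, 4.0, 4.6)
  cohort$systolic_bp        <- c(112, 150, 118, 115, 117, 119, 110, 122, 114, 170, 111, 116)
  cohort$diastolic_bp       <- c(72, 88, 76, 74, 78, 75, 71, 79, 70, 95, 73, 85)
  cohort$antihypertensive_use <- c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                                   FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  cohort$fasting_glucose    <- c(4.6, 4.8, 5.1, 4.9, 4.7, 5.0, 4.5, 6.5, 4.4, 5.2, 4.6, 4.8)
  cohort$diabetes_diagnosis <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                                 FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  cohort$current_smoker     <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                                 FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  scores <- score_cohort(lesions_wide_to_long(cohort, scheme), scheme)
  scores <- scores[match(cohort$participant_id, scores$participant_id), ]
  cohort$mvm_score <- scores$mvm_score
  cohort$cumulative_score <- scores$cumulative_score
  cohort$mvm_severe <- scores$mvm_severe
  structure(
    list(cohort = cohort, params = NULL,
         ground_truth = list(
           intended_lifetime_risk = stats::setNames(
             c(8, 39, 50, 27, 39, NA, 27, 39, 8, 50, 8, 27),
             cohort$participant_id))),
    class = "synthetic_cohort"
  )
}
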