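#' Descriptive summary of a cohort table
#'
#' Numeric variables are screened with the Shapiro-Wilk test (same gate as
#' [compare_continuous()]): normal-looking variables report mean and SD,
#' others report median and interquartile range (linear-interpolation
#' quantiles, type 7). Logical variables report count (percent). All-missing
#' columns are reported as such, never dropped silently.
#'
#' @param cohort data.frame; the `participant_id` column is ignored.
#' @param shapiro_alpha Normality screen level, default 0.05.
#' @return data.frame with one row per variable: `variable`, `type`, `n`,
#'   `n_missing`, `summary` (display string), and unrounded `mean`, `sd`,
#'   `median`, `q1`, `q3`, `count`, `percent` where applicable.
#' @export
summarize_cohort <- function(cohort, shapiro_alpha = 0.05) {
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  vars <- setdiff(names(cohort), "participant_id")
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    out <- data.frame(variable = v, type = NA_character_,
                      n = sum(!is.na(x)), n_missing = sum(is.na(x)),
                      summary = NA_character_, mean = NA_real_, sd = NA_real_,
                      median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                      count = NA_integer_, percent = NA_real_,
                      stringsAsFactors = FALSE)
    xx <- x[!is.na(x)]
    if (!length(xx)) {
      out$type <- "all_missing"
      out$summary <- "all values missing"
      return(out)
    }
    if (is.logical(xx)) {
      out$type <- "binary"
      out$count <- sum(xx)
      out$percent <- 100 * mean(xx)
      out$summary <- sprintf("%d (%.1f%%)", out$count, out$percent)
    } else if (is.numeric(xx)) {
      normal <- if (length(unique(xx)) < 3L || length(xx) < 3L) FALSE else {
        sub <- if (length(xx) > 5000) xx[seq(1L, length(xx), length.out = 5000L)] else xx
        stats::shapiro.test(sub)$p.value > shapiro_alpha
      }
      out$mean <- mean(xx); out$sd <- stats::sd(xx)
      out$median <- stats::median(xx)
      qs <- stats::quantile(xx, c(0.25, 0.75), type = 7, names = FALSE)
      out$q1 <- qs[1]; out$q3 <- qs[2]
      if (length(unique(xx)) == 1L) {
        out$type <- "numeric_mean_sd"
        out$summary <- sprintf("%.1f ± %.1f", out$mean, 0)
      } else if (normal) {
        out$type <- "numeric_mean_sd"
        out$summary <- sprintf("%.1f ± %.1f", out$mean, out$sd)
      } else {
        out$type <- "numeric_median_iqr"
        out$summary <- sprintf("%.1f (%.2f, %.2f)", out$median, out$q1, out$q3)
      }
    } else {
      out$type <- "categorical"
      tab <- sort(table(xx), decreasing = TRUE)
      out$summary <- paste(sprintf("%s: %d", names(tab), tab), collapse = "; ")
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Lesion presence frequencies by risk group, with per-lesion Pearson p
#'
#' Builds the lesion-frequency-by-risk-group table: for each lesion of the
#' scheme present in the cohort, the count (percent) of participants with
#' the lesion present (grade >= 1) in the high- and low-risk groups and the
#' uncorrected Pearson chi-square p-value. An optional Benjamini-Hochberg
#' adjusted column can be added (not part of the primary report).
#'
#' @param cohort Cohort with wide lesion columns and `risk_group`.
#' @param scheme Scoring scheme.
#' @param adjust Add a Benjamini-Hochberg `p_adjusted` column (default
#'   FALSE).
#' @return data.frame with one row per lesion.
#' @export
lesion_frequency_table <- function(cohort, scheme, adjust = FALSE) {
  if (!"risk_group" %in% names(cohort)) {
    stop("cohort must carry a risk_group column; run assess_risk() first",
         call. = FALSE)
  }
  lesion_cols <- intersect(scheme$lesions$lesion_id, names(cohort))
  high <- cohort$risk_group == "high"
  rows <- lapply(lesion_cols, function(lid) {
    present <- !is.na(cohort[[lid]]) & cohort[[lid]] >= 1
    ok <- !is.na(cohort[[lid]]) & !is.na(high)
    tab <- contingency_2x2(sum(present & high & ok), sum(!present & high & ok),
                           sum(present & !high & ok), sum(!present & !high & ok))
    chi <- pearson_chi2(tab)
    data.frame(
      lesion_id = lid,
      n_high = sum(high & ok), present_high = sum(present & high & ok),
      pct_high = 100 * sum(present & high & ok) / max(1, sum(high & ok)),
      n_low = sum(!high & ok), present_low = sum(present & !high & ok),
      pct_low = 100 * sum(present & !high & ok) / max(1, sum(!high & ok)),
      chi2 = chi$statistic, p_value = chi$p_value,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (adjust) res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Run the full screening pipeline on a cohort
#'
#' Stages: (1) severity scoring from wide lesion columns (skipped when the
#' cohort already carries `mvm_score`/`mvm_severe`); (2) lifetime risk
#' assessment (skipped when `risk_group` is present); (3) cohort
#' descriptives; (4) lesion frequency table by risk group with per-row
#' Pearson p; (5) severe-MVM vs high-risk association (2x2, odds ratio with
#' 95% CI, chi-square); (6) the three prediction models with ROC analysis.
#' The report is a pure function of (cohort, scheme, rules, options).
#'
#' @param cohort Cohort data.frame (or a `synthetic_cohort`).
#' @param scheme Scoring scheme, default the shipped one.
#' @param rules Risk stratification rules, default the shipped ones.
#' @param mvm_threshold Severe-MVM cut-point, default 2.
#' @param missing Missing-measurement policy passed to [assess_risk()].
#' @param specs Prediction model specs, default [default_model_specs()];
#'   set `NULL` to skip the modelling stage.
#' @param out_dir Optional directory; when given, the report is written as
#'   `report.json` plus delimited text tables.
#' @return A `run_report` list: `n`, `cohort_summary`, `lesion_table`,
#'   `association`, `models`, `provenance`, and the augmented `cohort`.
#' @export
run_pipeline <- function(cohort, scheme = default_scheme(),
                         rules = default_risk_rules(), mvm_threshold = 2L,
                         missing = c("error", "impute_optimal", "exclude"),
                         specs = default_model_specs(), out_dir = NULL) {
  missing <- match.arg(missing)
  if (inherits(cohort, "synthetic_cohort")) cohort <- cohort$cohort
  if (!"participant_id" %in% names(cohort)) {
    stop("cohort must have a participant_id column", call. = FALSE)
  }

  if (!all(c("mvm_score", "mvm_severe", "cumulative_score") %in% names(cohort))) {
    scores <- score_cohort(lesions_wide_to_long(cohort, scheme), scheme,
                           mvm_threshold = mvm_threshold)
    scores <- scores[match(cohort$participant_id, scores$participant_id), ]
    cohort$mvm_score <- scores$mvm_score
    cohort$cumulative_score <- scores$cumulative_score
    cohort$mvm_severe <- scores$mvm_severe
  }
  if (!"risk_group" %in% names(cohort)) {
    cohort <- assess_risk(cohort, rules, missing = missing)
  }

  cohort_summary <- summarize_cohort(
    cohort[setdiff(names(cohort), grep("^stratum_", names(cohort), value = TRUE))]
  )
  lesion_table <- lesion_frequency_table(cohort, scheme)
  tab <- build_2x2(cohort, "mvm_severe", "risk_group",
                   na_action = if (missing == "error") "error" else "omit")
  association <- associate(tab)
  models <- if (!is.null(specs)) run_models(cohort, specs) else NULL

  report <- structure(
    list(
      n = nrow(cohort),
      cohort_summary = cohort_summary,
      lesion_table = lesion_table,
      contingency = tab,
      association = association,
      models = models,
      cohort = cohort,
      provenance = list(
        package = "plascreen",
        version = as.character(utils::packageVersion("plascreen")),
        scheme_version = scheme$version,
        rules_version = attr(rules, "version"),
        mvm_threshold = mvm_threshold,
        missing_policy = missing,
        n_participants = nrow(cohort)
      )
    ),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("plascreen run report: n =", x$n, "participants\n")
  cat("  high risk:", sum(x$cohort$risk_group == "high"),
      sprintf("(%.1f%%)\n", 100 * mean(x$cohort$risk_group == "high")))
  cat("  severe MVM vs high lifetime CVD risk: ")
  print(x$association)
  if (!is.null(x$models)) print(x$models)
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes `report.json` (full report with unrounded values), plus
#' `cohort_summary.tsv`, `lesion_table.tsv` and `scored_cohort.tsv`.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assoc <- report$association
  json <- list(
    n = report$n,
    contingency = unclass(report$contingency)[c("a", "b", "c", "d")],
    association = list(
      odds_ratio = assoc$odds_ratio, ci_low = assoc$ci_low,
      ci_high = assoc$ci_high, chi2_statistic = assoc$chi2_statistic,
      p_value = assoc$p_value,
      display = sprintf("OR %.2f (%.2f-%.2f), p = %.3f", assoc$odds_ratio,
                        assoc$ci_low, assoc$ci_high, assoc$p_value)
    ),
    models = if (!is.null(report$models)) report$models$comparison else NULL,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.table(report$cohort_summary, file.path(out_dir, "cohort_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$lesion_table, file.path(out_dir, "lesion_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$cohort, file.path(out_dir, "scored_cohort.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
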