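#' The seven lifetime cardiovascular risk factors
#' @keywords internal
.risk_factors <- c("total_cholesterol", "systolic_bp", "diastolic_bp",
                   "antihypertensive_use", "fasting_glucose",
                   "diabetes_diagnosis", "current_smoker")

.strata_levels <- c("optimal", "not_optimal", "elevated", "major")

#' Load risk-factor stratification rules
#'
#' Reads a YAML/JSON rules file mapping each of the seven postpartum risk
#' factors (total cholesterol, systolic and diastolic blood pressure,
#' anti-hypertensive use, fasting glucose, diabetes diagnosis, current
#' smoking) to a stratum in optimal / not_optimal / elevated / major.
#' Numeric factors use ordered breaks; boolean factors map `TRUE` to a named
#' stratum and `FALSE` to optimal.
#'
#' The shipped defaults are transcribed from the Framingham lifetime-risk
#' stratification literature and are fully editable; see the rules file
#' header for provenance.
#'
#' @param path Rules file path; `default_risk_rules()` loads the shipped file.
#' @return A `risk_rules` object (named list of per-factor rules).
#' @export
load_risk_rules <- function(path) {
  if (!file.exists(path)) stop("rules file does not exist: ", path, call. = FALSE)
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("failed to parse rules file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(raw$factors)) {
    stop("rules file '", path, "' is missing the 'factors' block", call. = FALSE)
  }
  rules <- raw$factors
  missing_f <- setdiff(.risk_factors, names(rules))
  if (length(missing_f)) {
    stop("rules file '", path, "' is missing factor(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  for (f in names(rules)) {
    r <- rules[[f]]
    if (is.null(r$type) || !r$type %in% c("numeric", "boolean")) {
      stop("factor '", f, "': type must be 'numeric' or 'boolean'", call. = FALSE)
    }
    if (r$type == "numeric") {
      br <- unlist(r$breaks)
      if (length(br) != 3L || is.unsorted(br, strictly = TRUE)) {
        stop("factor '", f, "': breaks must be 3 strictly increasing values",
             call. = FALSE)
      }
      rules[[f]]$breaks <- as.numeric(br)
      rules[[f]]$admissible <- if (is.null(r$admissible)) c(-Inf, Inf) else
        as.numeric(unlist(r$admissible))
    } else {
      ts <- if (is.null(r$true_stratum)) "major" else as.character(r$true_stratum)
      if (!ts %in% .strata_levels) {
        stop("factor '", f, "': true_stratum must be one of ",
             paste(.strata_levels, collapse = ", "), call. = FALSE)
      }
      rules[[f]]$true_stratum <- ts
    }
  }
  structure(rules, class = "risk_rules",
            version = if (is.null(raw$version)) "unversioned" else raw$version)
}

#' @rdname load_risk_rules
#' @export
default_risk_rules <- function() {
  load_risk_rules(.extdata("default_risk_rules.yaml"))
}

#' Stratify one risk factor measurement
#'
#' @param factor_id One of the seven factor names known to `rules`.
#' @param value Numeric measurement, or logical for boolean factors.
#' @param rules A [risk_rules][load_risk_rules] object.
#' @return One of `"optimal"`, `"not_optimal"`, `"elevated"`, `"major"`.
#' @examples
#' rules <- default_risk_rules()
#' stratify_factor("systolic_bp", 115, rules)        # "optimal"
#' stratify_factor("diabetes_diagnosis", TRUE, rules) # "major"
#' @export
stratify_factor <- function(factor_id, value, rules) {
  r <- rules[[factor_id]]
  if (is.null(r)) stop("unknown risk factor: '", factor_id, "'", call. = FALSE)
  if (length(value) != 1L || is.na(value)) {
    stop("value for factor '", factor_id, "' must be a single non-missing value",
         call. = FALSE)
  }
  if (r$type == "boolean") {
    if (!is.logical(value)) {
      stop("factor '", factor_id, "' expects a logical value", call. = FALSE)
    }
    return(if (value) r$true_stratum else "optimal")
  }
  if (!is.numeric(value)) {
    stop("factor '", factor_id, "' expects a numeric value", call. = FALSE)
  }
  if (value < r$admissible[1] || value > r$admissible[2]) {
    stop("value ", value, " outside admissible range [", r$admissible[1], ", ",
         r$admissible[2], "] for factor '", factor_id, "'", call. = FALSE)
  }
  .strata_levels[findInterval(value, r$breaks) + 1L]
}

# Vectorized counterpart of stratify_factor(); NA passes through.
.stratify_vectorized <- function(factor_id, values, rules) {
  r <- rules[[factor_id]]
  if (is.null(r)) stop("unknown risk factor: '", factor_id, "'", call. = FALSE)
  if (r$type == "boolean") {
    if (!is.logical(values)) {
      stop("factor '", factor_id, "' expects logical values", call. = FALSE)
    }
    return(ifelse(values, r$true_stratum, "optimal"))
  }
  if (!is.numeric(values)) {
    stop("factor '", factor_id, "' expects numeric values", call. = FALSE)
  }
  out_of_range <- !is.na(values) &
    (values < r$admissible[1] | values > r$admissible[2])
  if (any(out_of_range)) {
    stop("value(s) outside admissible range [", r$admissible[1], ", ",
         r$admissible[2], "] for factor '", factor_id, "': ",
         paste(utils::head(values[out_of_range], 3), collapse = ", "),
         call. = FALSE)
  }
  out <- rep(NA_character_, length(values))
  ok <- !is.na(values)
  out[ok] <- .strata_levels[findInterval(values[ok], r$breaks) + 1L]
  out
}

#' Categorical lifetime cardiovascular risk from factor strata
#'
#' Applies the lifetime-risk lookup in highest-severity-first priority order:
#' two or more major factors give 50%; exactly one major gives 39%; otherwise
#' at least one elevated gives 39%; otherwise at least one not-optimal gives
#' 27%; all optimal gives 8%.
#'
#' @param strata Named character vector assigning each of the seven risk
#'   factors a stratum (`optimal`, `not_optimal`, `elevated`, `major`).
#' @return Lifetime risk percentage: one of 8, 27, 39, 50.
#' @examples
#' strata <- setNames(rep("optimal", 7),
#'                    c("total_cholesterol", "systolic_bp", "diastolic_bp",
#'                      "antihypertensive_use", "fasting_glucose",
#'                      "diabetes_diagnosis", "current_smoker"))
#' lifetime_risk(strata)  # 8
#' @export
lifetime_risk <- function(strata) {
  missing_f <- setdiff(.risk_factors, names(strata))
  if (length(missing_f)) {
    stop("missing stratum for factor(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  strata <- unlist(strata)[.risk_factors]
  bad <- setdiff(unique(strata), .strata_levels)
  if (length(bad)) {
    stop("unknown stratum value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n_major <- sum(strata == "major")
  if (n_major >= 2L) return(50)
  if (n_major == 1L) return(39)
  if (any(strata == "elevated")) return(39)
  if (any(strata == "not_optimal")) return(27)
  8
}

#' Dichotomize the categorical lifetime risk at 39%
#'
#' @param lifetime_risk_percent One of 8, 27, 39, 50.
#' @return `"low"` (below 39%) or `"high"` (39% or above).
#' @export
dichotomize <- function(lifetime_risk_percent) {
  vapply(lifetime_risk_percent, function(p) {
    if (is.na(p) || !p %in% c(8, 27, 39, 50)) {
      stop("lifetime risk percent must be one of 8, 27, 39, 50; got ", p,
           call. = FALSE)
    }
    if (p >= 39) "high" else "low"
  }, character(1))
}

#' Assess lifetime cardiovascular risk for a cohort
#'
#' Stratifies each participant's seven risk-factor measurements, applies the
#' categorical lifetime-risk lookup, and dichotomizes at 39%. Columns must be
#' named after the factors (`total_cholesterol`, `systolic_bp`,
#' `diastolic_bp`, `antihypertensive_use`, `fasting_glucose`,
#' `diabetes_diagnosis`, `current_smoker`).
#'
#' @param cohort data.frame with `participant_id` and the seven factor
#'   columns.
#' @param rules A [risk_rules][load_risk_rules] object.
#' @param missing Policy for missing measurements: `"error"` (default; names
#'   the offending participants), `"impute_optimal"` (treat missing as
#'   optimal — flagged in `n_imputed`), or `"exclude"` (drop incomplete
#'   participants).
#' @return The cohort with appended `stratum_<factor>` columns,
#'   `lifetime_risk_percent` and `risk_group`; excluded participants (if any)
#'   are recorded in the `"excluded"` attribute.
#' @export
assess_risk <- function(cohort, rules = default_risk_rules(),
                        missing = c("error", "impute_optimal", "exclude")) {
  missing <- match.arg(missing)
  missing_cols <- setdiff(c("participant_id", .risk_factors), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  incomplete <- !stats::complete.cases(cohort[.risk_factors])
  excluded <- character(0)
  if (any(incomplete)) {
    if (missing == "error") {
      stop("missing risk-factor measurements for participant(s): ",
           paste(cohort$participant_id[incomplete], collapse = ", "),
           "; set missing='impute_optimal' or 'exclude' to override",
           call. = FALSE)
    } else if (missing == "exclude") {
      excluded <- as.character(cohort$participant_id[incomplete])
      cohort <- cohort[!incomplete, , drop = FALSE]
    }
  }
  n_imputed <- integer(nrow(cohort))
  strata_mat <- matrix(NA_character_, nrow(cohort), length(.risk_factors),
                       dimnames = list(NULL, .risk_factors))
  for (f in .risk_factors) {
    vals <- cohort[[f]]
    miss <- is.na(vals)  # only reachable under impute_optimal
    n_imputed <- n_imputed + miss
    strata_mat[, f] <- .stratify_vectorized(f, vals, rules)
    strata_mat[miss, f] <- "optimal"
  }
  # vectorized priority rule (scalar reference: lifetime_risk())
  n_major <- rowSums(strata_mat == "major")
  any_elev <- rowSums(strata_mat == "elevated") > 0
  any_noto <- rowSums(strata_mat == "not_optimal") > 0
  pct <- ifelse(n_major >= 2, 50,
         ifelse(n_major == 1 | any_elev, 39,
         ifelse(any_noto, 27, 8)))
  for (f in .risk_factors) cohort[[paste0("stratum_", f)]] <- strata_mat[, f]
  cohort$lifetime_risk_percent <- if (nrow(cohort)) pct else numeric(0)
  cohort$risk_group <- if (nrow(cohort)) ifelse(pct >= 39, "high", "low") else character(0)
  cohort$n_factors_imputed <- as.integer(n_imputed)
  attr(cohort, "excluded") <- excluded
  cohort
}
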