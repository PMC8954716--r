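#' Specify a prediction model
#'
#' @param name Model label, e.g. `"clinical"`, `"mvm"`, `"combined"`.
#' @param covariates Character vector of covariate column names; empty for an
#'   intercept-only (null) model.
#' @param outcome Outcome column name (logical or high/low risk group),
#'   default `"risk_group"`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(name, covariates = character(0), outcome = "risk_group") {
  covariates <- as.character(covariates)
  if (anyDuplicated(covariates)) {
    stop("duplicate covariate(s): ",
         paste(unique(covariates[duplicated(covariates)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, covariates = covariates, outcome = outcome),
            class = "model_spec")
}

#' The three pre-registered prediction model specifications
#'
#' (a) clinical-only: maternal age, gestational weight gain, systolic and
#' diastolic blood pressure at delivery, gestational age at delivery;
#' (b) MVM-only: the severe maternal vascular malperfusion indicator
#' (severity score 2 or more; switch to the raw `mvm_score` via
#' `mvm_covariate`); (c) combined: both sets.
#'
#' @param bp Blood pressure coding: `"both"` (systolic and diastolic as
#'   separate covariates, default), `"systolic"`, or `"map"` (mean arterial
#'   pressure, requires an `map_delivery` column).
#' @param mvm_covariate Column used by the MVM model: `"mvm_severe"`
#'   (default) or `"mvm_score"`.
#' @return Named list of three [model_spec] objects.
#' @export
default_model_specs <- function(bp = c("both", "systolic", "map"),
                                mvm_covariate = c("mvm_severe", "mvm_score")) {
  bp <- match.arg(bp)
  mvm_covariate <- match.arg(mvm_covariate)
  bp_cols <- switch(bp,
                    both = c("systolic_bp_delivery", "diastolic_bp_delivery"),
                    systolic = "systolic_bp_delivery",
                    map = "map_delivery")
  clinical <- c("maternal_age", "gestational_weight_gain", bp_cols,
                "gestational_age_delivery")
  list(
    clinical = model_spec("clinical", clinical),
    mvm      = model_spec("mvm", mvm_covariate),
    combined = model_spec("combined", c(mvm_covariate, clinical))
  )
}

#' Fit a multivariable logistic regression prediction model
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (convergence when the relative deviance change falls below 1e-8, at most
#' 100 iterations), on complete cases. Rank-deficient designs are an error
#' naming the collinear columns; (quasi-)complete separation is detected and
#' flagged, with coefficients still reported under a warning.
#'
#' @param cohort Cohort data.frame.
#' @param spec A [model_spec].
#' @return A `fitted_model`: list with `name`, `coefficients`, `converged`,
#'   `separation`, `n_used`, `linear_scores` (linear predictor per used row),
#'   `fitted_prob`, `used_rows`, and the underlying `glm` fit.
#' @export
fit_logistic <- function(cohort, spec) {
  stopifnot(inherits(spec, "model_spec"))
  missing_cols <- setdiff(c(spec$outcome, spec$covariates), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing model column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  y <- cohort[[spec$outcome]]
  if (is.character(y)) y <- y == "high"
  if (is.factor(y)) y <- as.character(y) == "high"
  if (!is.logical(y) && !all(y %in% c(0, 1, NA))) {
    stop("outcome '", spec$outcome, "' must be logical or high/low", call. = FALSE)
  }
  y <- as.numeric(y)
  X <- cohort[spec$covariates]
  for (nm in names(X)) if (is.logical(X[[nm]])) X[[nm]] <- as.numeric(X[[nm]])
  dat <- if (length(spec$covariates)) cbind(.y = y, X) else data.frame(.y = y)
  used <- stats::complete.cases(dat)
  dat <- dat[used, , drop = FALSE]
  if (!nrow(dat)) stop("no complete cases for model '", spec$name, "'", call. = FALSE)
  if (length(spec$covariates)) {
    mm <- stats::model.matrix(~ ., data = dat[spec$covariates])
    dec <- qr(mm)
    if (dec$rank < ncol(mm)) {
      drop_cols <- colnames(mm)[dec$pivot[(dec$rank + 1L):ncol(mm)]]
      stop("rank-deficient design for model '", spec$name, "'; collinear column(s): ",
           paste(drop_cols, collapse = ", "), call. = FALSE)
    }
  }
  rhs <- if (length(spec$covariates)) paste(spec$covariates, collapse = " + ") else "1"
  form <- stats::as.formula(paste(".y ~", rhs))
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- stats::coef(fit)
  separation <- sep_warning || any(abs(coefs[-1]) > 15)
  if (separation) {
    warning("possible (quasi-)complete separation in model '", spec$name,
            "'; coefficients are unreliable", call. = FALSE)
  }
  structure(
    list(name = spec$name, spec = spec,
         coefficients = coefs,
         converged = fit$converged,
         separation = separation,
         n_used = nrow(dat),
         linear_scores = unname(stats::predict(fit, type = "link")),
         fitted_prob = unname(stats::fitted(fit)),
         used_rows = which(used),
         outcome = dat$.y == 1,
         glm = fit),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("Logistic model '", x$name, "' (n = ", x$n_used, ", converged: ",
      x$converged, if (x$separation) ", SEPARATION FLAG" else "", ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

.wilson_ci <- function(k, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(centre - half, centre + half)
}

#' ROC curve analysis of a continuous score against a binary label
#'
#' The AUC is computed as pairwise concordance (the Mann-Whitney identity),
#' counting ties as 1/2; its confidence interval uses the Hanley-McNeil
#' standard error. The reported operating point maximizes Youden's J
#' (sensitivity + specificity - 1; ties broken toward higher sensitivity),
#' with Wilson score confidence intervals on sensitivity and specificity.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical labels (or high/low risk group).
#' @param conf_level Confidence level, default 0.95.
#' @return A `roc_result`: `auc`, `auc_ci_low`, `auc_ci_high`, `threshold`,
#'   `sensitivity`, `specificity` (in percent, with `*_ci_low/high`),
#'   `youden`, `n_pos`, `n_neg`, and the empirical `curve` (data.frame of
#'   threshold, fpr, tpr).
#' @export
roc_curve <- function(scores, labels, conf_level = 0.95) {
  if (is.character(labels)) labels <- labels == "high"
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  # Mann-Whitney concordance with ties counted 1/2, via midranks
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  auc_ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  # empirical ROC (classify positive when score >= threshold), built from
  # cumulative counts over the descending score order
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- which(c(s[-1] != s[-length(s)], TRUE))  # last index of each tie group
  tpr <- c(0, cumsum(l)[last] / n_pos)
  fpr <- c(0, cumsum(!l)[last] / n_neg)
  thresholds <- c(Inf, s[last])
  curve <- data.frame(threshold = thresholds, fpr = fpr, tpr = tpr)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.max(tpr[best])]  # tie-break toward higher sensitivity
  sens <- tpr[best]; spec <- 1 - fpr[best]
  sens_ci <- .wilson_ci(round(sens * n_pos), n_pos, conf_level)
  spec_ci <- .wilson_ci(round(spec * n_neg), n_neg, conf_level)
  structure(
    list(auc = auc, auc_ci_low = auc_ci[1], auc_ci_high = auc_ci[2],
         auc_se = se,
         threshold = thresholds[best], youden = j[best],
         sensitivity = 100 * sens,
         sensitivity_ci_low = 100 * sens_ci[1],
         sensitivity_ci_high = 100 * sens_ci[2],
         specificity = 100 * spec,
         specificity_ci_low = 100 * spec_ci[1],
         specificity_ci_high = 100 * spec_ci[2],
         n_pos = n_pos, n_neg = n_neg, curve = curve),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.2f (%.2f, %.2f); sensitivity %.1f%% (%.1f, %.1f); specificity %.1f%% (%.1f, %.1f)\n",
              x$auc, x$auc_ci_low, x$auc_ci_high,
              x$sensitivity, x$sensitivity_ci_low, x$sensitivity_ci_high,
              x$specificity, x$specificity_ci_low, x$specificity_ci_high))
  invisible(x)
}

#' Fit and evaluate the three pre-registered prediction models
#'
#' Fits the clinical-only, MVM-only and combined logistic models on the
#' cohort and evaluates each by in-sample (apparent) ROC AUC with a
#' Youden-optimal operating point.
#'
#' @param cohort Cohort data.frame carrying the outcome and all covariates.
#' @param specs List of [model_spec]s, default [default_model_specs()].
#' @return A `model_comparison`: list with `models` (per spec: `fit` and
#'   `roc`) and `comparison` (data.frame of AUCs and operating points).
#' @export
run_models <- function(cohort, specs = default_model_specs()) {
  models <- lapply(specs, function(sp) {
    fit <- fit_logistic(cohort, sp)
    roc <- roc_curve(fit$linear_scores, fit$outcome)
    list(fit = fit, roc = roc)
  })
  comparison <- do.call(rbind, lapply(models, function(m) {
    data.frame(model = m$fit$name, n = m$fit$n_used,
               auc = m$roc$auc,
               auc_ci_low = m$roc$auc_ci_low, auc_ci_high = m$roc$auc_ci_high,
               sensitivity = m$roc$sensitivity, specificity = m$roc$specificity,
               converged = m$fit$converged, separation = m$fit$separation,
               stringsAsFactors = FALSE)
  }))
  rownames(comparison) <- NULL
  structure(list(models = models, comparison = comparison),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Prediction model comparison (in-sample):\n")
  df <- x$comparison
  df$auc <- sprintf("%.3f (%.3f, %.3f)", df$auc, df$auc_ci_low, df$auc_ci_high)
  print(df[c("model", "n", "auc", "sensitivity", "specificity")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
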