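#' Construct a 2x2 exposure-outcome contingency table
#'
#' Cell layout: `a` = exposed with outcome, `b` = exposed without outcome,
#' `c` = unexposed with outcome, `d` = unexposed without outcome. The
#' cross-product odds ratio and the Pearson chi-square statistic are
#' invariant to transposing this layout, so tables entered in
#' outcome-by-exposure order give identical results.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A `contingency_2x2` object.
#' @examples
#' contingency_2x2(29, 9, 24, 23)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
            total = sum(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("outcome", "no outcome")))
  print(m)
  invisible(x)
}

#' Cross-classify a cohort into a 2x2 table
#'
#' @param cohort data.frame with a `participant_id` column.
#' @param exposure,outcome Names of logical columns (e.g. `mvm_severe` and
#'   high-risk screening).
#' @param na_action `"error"` (default; lists participants with missing
#'   values) or `"omit"`.
#' @return A [contingency_2x2] object.
#' @export
build_2x2 <- function(cohort, exposure, outcome, na_action = c("error", "omit")) {
  na_action <- match.arg(na_action)
  for (col in c(exposure, outcome)) {
    if (!col %in% names(cohort)) stop("column not found: '", col, "'", call. = FALSE)
  }
  e <- cohort[[exposure]]
  o <- cohort[[outcome]]
  if (is.character(o)) o <- o == "high"  # accept risk_group coding
  if (!is.logical(e) && !all(e %in% c(0, 1, NA))) {
    stop("exposure column '", exposure, "' must be logical", call. = FALSE)
  }
  if (!is.logical(o) && !all(o %in% c(0, 1, NA))) {
    stop("outcome column '", outcome, "' must be logical", call. = FALSE)
  }
  e <- as.logical(e); o <- as.logical(o)
  bad <- is.na(e) | is.na(o)
  if (any(bad)) {
    if (na_action == "error") {
      stop("missing exposure/outcome values for participant(s): ",
           paste(cohort$participant_id[bad], collapse = ", "), call. = FALSE)
    }
    e <- e[!bad]; o <- o[!bad]
  }
  contingency_2x2(sum(e & o), sum(e & !o), sum(!e & o), sum(!e & !o))
}

#' Odds ratio with 95% Woolf (logit) confidence interval
#'
#' The odds ratio is the cross-product ratio (a d)/(b c); the confidence
#' interval is computed on the log scale as
#' exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param table A [contingency_2x2].
#' @param conf_level Confidence level, default 0.95.
#' @param zero_cell Policy when a cell is zero: `"undefined"` (default;
#'   returns `NA` estimates with `undefined = TRUE`) or `"haldane"`
#'   (Haldane-Anscombe +0.5 added to every cell, flagged in the result).
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, `se_log_or`,
#'   `conf_level`, `undefined`, `adjusted`.
#' @examples
#' odds_ratio(contingency_2x2(29, 9, 24, 23))  # OR 3.09, CI (1.20, 7.92)
#' @export
odds_ratio <- function(table, conf_level = 0.95,
                       zero_cell = c("undefined", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  stopifnot(inherits(table, "contingency_2x2"))
  cells <- c(table$a, table$b, table$c, table$d)
  adjusted <- FALSE
  if (any(cells == 0L)) {
    if (zero_cell == "undefined") {
      return(list(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  se_log_or = NA_real_, conf_level = conf_level,
                  undefined = TRUE, adjusted = FALSE))
    }
    cells <- cells + 0.5
    adjusted <- TRUE
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(odds_ratio = or,
       ci_low  = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       se_log_or = se, conf_level = conf_level,
       undefined = FALSE, adjusted = adjusted)
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' Uses the closed form n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) with the
#' upper tail of the chi-square distribution on 1 degree of freedom.
#' No continuity correction by default; `correct = TRUE` applies the Yates
#' correction for sensitivity analysis.
#'
#' @inheritParams odds_ratio
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `df`, `p_value`, `undefined`.
#' @examples
#' pearson_chi2(contingency_2x2(29, 9, 24, 23))  # p = 0.017
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (n == 0L || any(margins == 0L)) {
    return(list(statistic = NA_real_, df = 1L, p_value = NA_real_,
                undefined = TRUE))
  }
  dev <- abs(a * d - b * c)
  if (correct) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / prod(margins)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       undefined = FALSE)
}

#' Combined association result for a 2x2 table
#'
#' Convenience wrapper returning the odds ratio with its confidence interval
#' together with the Pearson chi-square test, as reported for
#' exposure-outcome associations.
#'
#' @inheritParams odds_ratio
#' @inheritParams pearson_chi2
#' @return An `association_result` list.
#' @export
associate <- function(table, conf_level = 0.95, correct = FALSE,
                      zero_cell = c("undefined", "haldane")) {
  or <- odds_ratio(table, conf_level = conf_level, zero_cell = zero_cell)
  chi <- pearson_chi2(table, correct = correct)
  structure(c(or, list(chi2_statistic = chi$statistic, p_value = chi$p_value,
                       table = table)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR %.2f (%.2f-%.2f), chi-square %.2f, p = %.3f\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$chi2_statistic, x$p_value))
  invisible(x)
}

#' Compare a continuous variable between two groups
#'
#' Chooses between Student's t-test and the Mann-Whitney U test. Under
#' `method = "auto"` both samples are screened with the Shapiro-Wilk test at
#' `shapiro_alpha`; the t-test is used only when neither sample rejects
#' normality (and both have at least 3 observations), otherwise Mann-Whitney.
#' Degenerate t-tests (zero variance) fall back to Mann-Whitney with a
#' warning.
#'
#' @param x,y Numeric samples (missing values dropped).
#' @param method `"auto"`, `"t"`, or `"mann_whitney"`.
#' @param shapiro_alpha Significance level of the normality screen.
#' @return List with `p_value`, `statistic`, `method_used`, `normality_p`.
#' @export
compare_continuous <- function(x, y, method = c("auto", "t", "mann_whitney"),
                               shapiro_alpha = 0.05) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  normality_p <- c(x = NA_real_, y = NA_real_)
  if (method == "auto") {
    if (min(length(x), length(y)) < 3L) {
      warning("fewer than 3 observations in a group; falling back to Mann-Whitney")
      method <- "mann_whitney"
    } else {
      sw <- function(v) {
        if (length(unique(v)) < 2L) return(0)  # constant: certainly non-normal gate
        stats::shapiro.test(if (length(v) > 5000) v[seq(1L, length(v), length.out = 5000L)] else v)$p.value
      }
      normality_p <- c(x = sw(x), y = sw(y))
      method <- if (all(normality_p > shapiro_alpha)) "t" else "mann_whitney"
    }
  }
  if (method == "t") {
    res <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
    if (is.null(res)) {
      warning("t-test degenerate (constant data); falling back to Mann-Whitney")
      method <- "mann_whitney"
    } else {
      return(list(p_value = res$p.value, statistic = unname(res$statistic),
                  method_used = "t", normality_p = normality_p))
    }
  }
  res <- suppressWarnings(stats::wilcox.test(x, y))
  p <- res$p.value
  if (is.na(p)) p <- 1  # identical constant groups: no evidence of difference
  list(p_value = p, statistic = unname(res$statistic),
       method_used = "mann_whitney", normality_p = normality_p)
}

#' Sample size for comparing two proportions
#'
#' Normal-approximation two-sample formula with pooled variance under the
#' null: n per group = (z_(1-alpha/2) sqrt(2 p_bar q_bar) +
#' z_(power) sqrt(p1 q1 + p2 q2))^2 / (p1 - p2)^2, rounded up.
#'
#' @param p1,p2 The two proportions (0 < p < 1, p1 != p2).
#' @param alpha Two-sided significance level, default 0.05.
#' @param power Target power, default 0.80.
#' @return Integer sample size per group.
#' @examples
#' power_two_proportions(0.547, 0.281)  # 53 per group
#' @export
power_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.80) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1)) {
    stop("proportions must lie strictly between 0 and 1", call. = FALSE)
  }
  if (p1 == p2) stop("p1 and p2 must differ (sample size is infinite)", call. = FALSE)
  p_bar <- (p1 + p2) / 2
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  n <- (z_a * sqrt(2 * p_bar * (1 - p_bar)) +
          z_b * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  as.integer(ceiling(n))
}
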