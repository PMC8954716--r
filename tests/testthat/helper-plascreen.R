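# Shared helpers for the plascreen test suite.

the_scheme <- default_scheme()
the_rules <- default_risk_rules()

risk_factor_names <- c("total_cholesterol", "systolic_bp", "diastolic_bp",
                       "antihypertensive_use", "fasting_glucose",
                       "diabetes_diagnosis", "current_smoker")

# A strata map with every factor optimal, selectively overridden.
make_strata <- function(...) {
  s <- stats::setNames(rep("optimal", 7), risk_factor_names)
  over <- list(...)
  for (nm in names(over)) s[nm] <- over[[nm]]
  s
}

# Long observation table for one participant from lesion=grade pairs.
make_obs <- function(pid = "p1", ...) {
  pairs <- list(...)
  if (!length(pairs)) {
    return(data.frame(participant_id = character(0), lesion_id = character(0),
                      grade = integer(0)))
  }
  data.frame(participant_id = pid, lesion_id = names(pairs),
             grade = unlist(pairs), stringsAsFactors = FALSE, row.names = NULL)
}

# Independent trapezoidal AUC oracle over the empirical ROC curve.
trapezoid_auc <- function(scores, labels) {
  thresholds <- c(-Inf, sort(unique(scores)), Inf)
  tpr <- vapply(thresholds, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!labels] >= t), numeric(1))
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Brute-force pairwise concordance AUC oracle (ties count 1/2).
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
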