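test_that("null logistic model recovers the logit of the sample prevalence", {
  # 53 of 85 high-risk: intercept-only fit gives logit(53/85) = logit(0.624)
  y <- rep(c(TRUE, FALSE), c(53, 32))
  cohort <- data.frame(participant_id = seq_along(y), y = y)
  fit <- fit_logistic(cohort, model_spec("null", outcome = "y"))
  expect_equal(unname(fit$coefficients["(Intercept)"]), qlogis(53 / 85),
               tolerance = 1e-8)
  expect_equal(fit$n_used, 85)
})

test_that("logistic fit matches closed-form and grid-search oracles", {
  # closed form: intercept-only model via a zero-variance-free single binary
  # covariate identical split -> coefficients are logits of group rates
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 23, 22))
  x <- rep(c(1, 1, 0, 0), c(30, 10, 23, 22))
  cohort <- data.frame(participant_id = seq_along(y), x = x, y = y)
  fit <- fit_logistic(cohort, model_spec("bin", "x", outcome = "y"))
  expect_equal(unname(fit$coefficients["(Intercept)"]), qlogis(23 / 45),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["x"]), qlogis(30 / 40) - qlogis(23 / 45),
               tolerance = 1e-6)

  # grid-search maximizer of the log-likelihood on a 2-covariate n=30 fixture
  set.seed(14)
  x1 <- rnorm(30); x2 <- rnorm(30)
  yy <- runif(30) < plogis(-0.5 + 0.8 * x1 - 0.4 * x2)
  cohort2 <- data.frame(participant_id = 1:30, x1 = x1, x2 = x2, y = yy)
  fit2 <- fit_logistic(cohort2, model_spec("two", c("x1", "x2"), outcome = "y"))
  loglik <- function(b) {
    eta <- b[1] + b[2] * x1 + b[3] * x2
    sum(yy * eta - log1p(exp(eta)))
  }
  grid_fit <- optim(c(0, 0, 0), function(b) -loglik(b), method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(unname(fit2$coefficients), grid_fit$par, tolerance = 1e-3)
})

test_that("parameter recovery at n = 5000 within +/- 0.15", {
  set.seed(27)
  n <- 5000
  x <- rnorm(n)
  y <- runif(n) < plogis(-1 + 1.1 * x)
  cohort <- data.frame(participant_id = 1:n, x = x, y = y)
  fit <- fit_logistic(cohort, model_spec("sim", "x", outcome = "y"))
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - (-1)), 0.15)
  expect_lt(abs(fit$coefficients[["x"]] - 1.1), 0.15)
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("separation and rank deficiency are detected", {
  y <- rep(c(TRUE, FALSE), each = 20)
  cohort <- data.frame(participant_id = 1:40, y = y,
                       x = as.numeric(y),      # outcome identical to covariate
                       x2 = rnorm(40))
  cohort$x3 <- 2 * cohort$x2 + 1               # collinear
  expect_warning(
    fit <- fit_logistic(cohort, model_spec("sep", "x", outcome = "y" )),
    "separation"
  )
  expect_true(fit$separation)
  expect_error(
    fit_logistic(cohort, model_spec("rank", c("x2", "x3"), outcome = "y")),
    "collinear.*x3"
  )
  expect_error(
    fit_logistic(cohort, model_spec("none", "nope", outcome = "y")),
    "missing model column"
  )
})

test_that("AUC equals brute-force concordance and the trapezoidal area", {
  # frozen tiny cases (computable by hand over the 4 pairs)
  expect_equal(roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1.0)
  expect_equal(roc_curve(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 0.75)
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    auc <- roc_curve(scores, labels)$auc
    expect_equal(auc, pairwise_auc(scores, labels), tolerance = 1e-12)
    expect_equal(auc, trapezoid_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(10)
  scores <- rnorm(200)
  labels <- runif(200) < plogis(scores)
  base <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(exp(scores), labels)$auc, base, tolerance = 1e-12)
  expect_equal(roc_curve(qlogis(plogis(scores)), labels)$auc, base,
               tolerance = 1e-9)
})

test_that("label-independent scores give AUC near one half", {
  set.seed(12)
  n <- 10000
  scores <- rnorm(n)
  labels <- runif(n) < 0.5
  expect_lt(abs(roc_curve(scores, labels)$auc - 0.5), 0.02)
})

test_that("AUC and its CI agree with pROC on a fixed sample", {
  skip_if_not_installed("pROC")
  set.seed(15)
  scores <- rnorm(150)
  labels <- runif(150) < plogis(scores - 0.3)
  mine <- roc_curve(scores, labels)
  theirs <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                      direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(theirs)), tolerance = 1e-12)
})

test_that("degenerate label vectors are rejected", {
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("binary-exposure AUC equals (sensitivity + specificity) / 2", {
  fx <- generate_cohort(cohort_params(n = 400, seed = 33))$cohort
  fit <- fit_logistic(fx, model_spec("mvm", "mvm_severe"))
  roc <- roc_curve(fit$linear_scores, fit$outcome)
  e <- fx$mvm_severe; o <- fx$risk_group == "high"
  se <- sum(e & o) / sum(o); sp <- sum(!e & !o) / sum(!o)
  expect_equal(roc$auc, (se + sp) / 2, tolerance = 1e-12)
})

test_that("the three pre-registered models run and nest sensibly", {
  sc <- generate_cohort(cohort_params(n = 4000, seed = 61))
  res <- run_models(sc$cohort)
  expect_setequal(res$comparison$model, c("clinical", "mvm", "combined"))
  expect_true(all(res$comparison$converged))
  cmp <- res$comparison
  expect_gte(cmp$auc[cmp$model == "combined"], cmp$auc[cmp$model == "mvm"])
  # outcome independent of everything: all AUC near 0.5
  null_cohort <- sc$cohort
  set.seed(99)
  null_cohort$risk_group <- sample(null_cohort$risk_group)
  null_res <- run_models(null_cohort)
  expect_true(all(abs(null_res$comparison$auc - 0.5) < 0.05))
})
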