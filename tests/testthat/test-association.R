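test_that("2x2 construction cross-classifies and enforces the missing policy", {
  cohort <- data.frame(
    participant_id = sprintf("p%d", 1:6),
    exp = c(TRUE, TRUE, FALSE, FALSE, TRUE, NA),
    out = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  )
  expect_error(build_2x2(cohort, "exp", "out"), "p6")
  tab <- build_2x2(cohort, "exp", "out", na_action = "omit")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 1, 1, 1))
  # empty cohort and single-record cohort
  tab0 <- build_2x2(cohort[0, ], "exp", "out")
  expect_equal(attr(tab0, "total"), 0)
  tab1 <- build_2x2(cohort[1, ], "exp", "out")
  expect_equal(c(tab1$a, tab1$b, tab1$c, tab1$d), c(1, 0, 0, 0))
  expect_error(contingency_2x2(-1, 0, 0, 0), "non-negative")
})

test_that("odds ratio and Woolf CI reproduce the reference table values", {
  res <- odds_ratio(contingency_2x2(29, 9, 24, 23))
  expect_equal(res$odds_ratio, 29 * 23 / (9 * 24), tolerance = 1e-12)
  expect_equal(round(res$odds_ratio, 2), 3.09)
  expect_equal(round(res$ci_low, 2), 1.20)
  expect_equal(round(res$ci_high, 2), 7.92)
  # symmetric and simple cross-product tables
  expect_equal(odds_ratio(contingency_2x2(10, 10, 10, 10))$odds_ratio, 1.0)
  expect_equal(odds_ratio(contingency_2x2(5, 5, 1, 9))$odds_ratio, 9.0)
})

test_that("transposing exposure labels inverts the odds ratio", {
  set.seed(3)
  for (rep in 1:25) {
    cells <- rpois(4, 20) + 1
    or1 <- odds_ratio(do.call(contingency_2x2, as.list(cells)))$odds_ratio
    or2 <- odds_ratio(contingency_2x2(cells[2], cells[1], cells[4], cells[3]))$odds_ratio
    expect_equal(or1, 1 / or2, tolerance = 1e-12)
  }
})

test_that("zero cells follow the configured continuity policy", {
  tab <- contingency_2x2(5, 0, 3, 7)
  und <- odds_ratio(tab)
  expect_true(und$undefined)
  expect_true(is.na(und$odds_ratio))
  hal <- odds_ratio(tab, zero_cell = "haldane")
  expect_true(hal$adjusted)
  expect_equal(hal$odds_ratio, (5.5 * 7.5) / (0.5 * 3.5), tolerance = 1e-12)
})

test_that("Pearson chi-square matches the closed form and chisq.test", {
  tab <- contingency_2x2(29, 9, 24, 23)
  res <- pearson_chi2(tab)
  expect_equal(round(res$statistic, 2), 5.71)
  expect_equal(round(res$p_value, 3), 0.017)
  # independent oracle 1: base R without continuity correction
  ct <- chisq.test(matrix(c(29, 9, 24, 23), 2, byrow = TRUE), correct = FALSE)
  expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
  # independent oracle 2: generic observed-vs-expected summation
  set.seed(8)
  for (rep in 1:25) {
    cells <- rpois(4, 15) + 1
    t2 <- do.call(contingency_2x2, as.list(cells))
    m <- matrix(cells, 2, byrow = TRUE)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(pearson_chi2(t2)$statistic, sum((m - expected)^2 / expected),
                 tolerance = 1e-10)
  }
  # proportional table has statistic zero; degenerate margin is flagged
  expect_equal(pearson_chi2(contingency_2x2(10, 10, 5, 5))$statistic, 0)
  expect_true(pearson_chi2(contingency_2x2(0, 0, 5, 5))$undefined)
})

test_that("chi-square equals the squared two-proportion z statistic", {
  set.seed(21)
  for (rep in 1:25) {
    cells <- rpois(4, 25) + 1
    tab <- do.call(contingency_2x2, as.list(cells))
    n1 <- cells[1] + cells[2]; n2 <- cells[3] + cells[4]
    p1 <- cells[1] / n1; p2 <- cells[3] / n2
    p_pool <- (cells[1] + cells[3]) / (n1 + n2)
    z <- (p1 - p2) / sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
    expect_equal(pearson_chi2(tab)$statistic, z^2, tolerance = 1e-10)
  }
})

test_that("continuous comparison selects the method via the normality gate", {
  set.seed(5)
  x <- rnorm(50); y <- rnorm(50, 5)
  res <- compare_continuous(x, y)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$method_used, "t")
  # heavy-tailed samples fail the gate and fall to Mann-Whitney
  xs <- exp(rnorm(60, sd = 2)); ys <- exp(rnorm(60, sd = 2))
  expect_equal(compare_continuous(xs, ys)$method_used, "mann_whitney")
  # identical tiny samples: no evidence of difference
  expect_equal(compare_continuous(c(1, 2, 3), c(1, 2, 3),
                                  method = "mann_whitney")$p_value, 1.0)
  # constant equal groups degenerate under t: handled fallback
  expect_warning(res_const <- compare_continuous(rep(2, 5), rep(2, 5), method = "t"),
                 "falling back")
  expect_equal(res_const$method_used, "mann_whitney")
  # tiny groups under auto fall back with a warning
  expect_warning(compare_continuous(c(1, 2), c(3, 4)), "fewer than 3")
  # matches the base implementations it wraps
  expect_equal(compare_continuous(x, y, method = "t")$p_value,
               t.test(x, y)$p.value)
  expect_equal(compare_continuous(x, y, method = "mann_whitney")$p_value,
               suppressWarnings(wilcox.test(x, y)$p.value))
})

test_that("two-proportion sample size matches the pooled-variance formula", {
  # reference scenario: severe-MVM frequencies 54.7% vs 28.1%
  n <- power_two_proportions(0.547, 0.281, alpha = 0.05, power = 0.80)
  expect_equal(n, 53)
  # independent oracle: base R's power.prop.test
  expect_equal(n, as.integer(ceiling(
    power.prop.test(p1 = 0.547, p2 = 0.281, power = 0.80)$n)))
  # symmetry and monotone behaviour
  expect_equal(power_two_proportions(0.281, 0.547), n)
  expect_lt(power_two_proportions(0.1, 0.6), power_two_proportions(0.1, 0.3))
  expect_error(power_two_proportions(0.4, 0.4), "must differ")
  expect_error(power_two_proportions(0, 0.5), "strictly between")
})
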