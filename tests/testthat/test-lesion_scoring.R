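test_that("default scheme encodes the seven categories with their caps", {
  caps <- setNames(the_scheme$categories$max_score,
                   the_scheme$categories$category_id)
  expect_equal(unname(caps[c("mvm", "implantation_site", "chorioamnionitis",
                             "villous_maldevelopment", "fvm", "mfi_disturbance",
                             "chronic_inflammation")]),
               c(14L, 4L, 11L, 5L, 6L, 5L, 6L))
  expect_false(anyDuplicated(the_scheme$lesions$lesion_id) > 0)
  # every lesion resolves to a defined category
  expect_true(all(the_scheme$lesions$category_id %in%
                    the_scheme$categories$category_id))
})

test_that("malformed schemes are rejected with informative errors", {
  raw <- yaml::read_yaml(system.file("extdata", "default_scheme.yaml",
                                     package = "plascreen"))
  dangling <- raw
  dangling$lesions[[1]]$category_id <- "no_such_category"
  expect_error(plascreen:::as_scoring_scheme(dangling), "unknown category")
  dup <- raw
  dup$lesions[[2]]$lesion_id <- dup$lesions[[1]]$lesion_id
  expect_error(plascreen:::as_scoring_scheme(dup), "duplicate lesion_id")
  nofield <- raw
  nofield$lesions[[1]]$scale <- NULL
  expect_error(plascreen:::as_scoring_scheme(nofield), "missing field 'scale'")
  badscale <- raw
  badscale$lesions[[1]]$scale <- "ordinal"
  expect_error(plascreen:::as_scoring_scheme(badscale), "unknown scale")
})

test_that("grades and grade labels resolve to validated ordinals", {
  expect_identical(score_lesion("diffuse", "syncytial_knots", the_scheme), 3L)
  expect_identical(score_lesion("patchy", "placental_infarction", the_scheme), 2L)
  expect_identical(score_lesion("absent", "thrombosis", the_scheme), 0L)
  expect_identical(score_lesion("present", "villous_agglutination", the_scheme), 1L)
  expect_identical(score_lesion(2, "syncytial_knots", the_scheme), 2L)
  expect_error(score_lesion(2, "villous_agglutination", the_scheme), "out of range")
  expect_error(score_lesion("diffuse", "villous_agglutination", the_scheme),
               "unknown grade label")
  expect_error(score_lesion(1, "no_such_lesion", the_scheme), "unknown lesion")
})

test_that("category severity sums member grades and caps at max_score", {
  # two MVM lesions at grades 1 and 2: cap not binding
  obs <- make_obs(placental_infarction = 1, syncytial_knots = 2)
  expect_equal(category_severity(obs, "mvm", the_scheme), 3)
  # all MVM members maximal: cap binds at 14
  mvm <- the_scheme$lesions[the_scheme$lesions$category_id == "mvm", ]
  obs_max <- data.frame(participant_id = "p1", lesion_id = mvm$lesion_id,
                        grade = mvm$max_grade)
  expect_equal(category_severity(obs_max, "mvm", the_scheme), 14)
  # no observations
  expect_equal(category_severity(make_obs(), "mvm", the_scheme), 0)
  # observations outside the category are ignored, not an error
  expect_equal(category_severity(make_obs(funisitis = 1), "mvm", the_scheme), 0)
  # duplicated lesion observation is an error
  dup <- rbind(obs, obs[1, ])
  expect_error(category_severity(dup, "mvm", the_scheme), "duplicate observation")
})

test_that("cap saturation holds for every category", {
  for (cid in the_scheme$categories$category_id) {
    members <- the_scheme$lesions[the_scheme$lesions$category_id == cid, ]
    obs <- data.frame(participant_id = "p1", lesion_id = members$lesion_id,
                      grade = members$max_grade)
    expect_equal(category_severity(obs, cid, the_scheme),
                 the_scheme$categories$max_score[
                   the_scheme$categories$category_id == cid],
                 info = cid)
  }
})

test_that("severity profile fills categories, cumulative score and MVM flag", {
  prof0 <- severity_profile(make_obs(), the_scheme)
  expect_equal(prof0$cumulative_score, 0)
  expect_false(prof0$mvm_severe)
  expect_true(all(prof0$category_scores == 0))

  # MVM score exactly at the threshold flips the flag
  prof2 <- severity_profile(make_obs(placental_infarction = 2), the_scheme)
  expect_equal(unname(prof2$category_scores["mvm"]), 2L)
  expect_true(prof2$mvm_severe)
  prof1 <- severity_profile(make_obs(placental_infarction = 1), the_scheme)
  expect_false(prof1$mvm_severe)
  # threshold is configurable
  expect_true(severity_profile(make_obs(placental_infarction = 1), the_scheme,
                               mvm_threshold = 1)$mvm_severe)
  # cumulative = sum of category scores
  obs <- make_obs(placental_infarction = 3, funisitis = 1,
                  villitis_unknown_etiology = 2)
  prof <- severity_profile(obs, the_scheme)
  expect_equal(prof$cumulative_score, sum(prof$category_scores))
  expect_equal(prof$cumulative_score, 6)
})

test_that("scoring is monotone, idempotent and permutation invariant", {
  set.seed(42)
  lesions <- the_scheme$lesions
  for (rep in 1:20) {
    k <- sample.int(nrow(lesions), 8)
    obs <- data.frame(
      participant_id = "p1",
      lesion_id = lesions$lesion_id[k],
      grade = vapply(lesions$max_grade[k],
                     function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    )
    prof <- severity_profile(obs, the_scheme)
    # idempotence
    expect_identical(severity_profile(obs, the_scheme), prof)
    # permutation invariance
    shuffled <- obs[sample.int(nrow(obs)), ]
    expect_identical(severity_profile(shuffled, the_scheme)[c(
      "category_scores", "cumulative_score", "mvm_severe")],
      prof[c("category_scores", "cumulative_score", "mvm_severe")])
    # monotonicity: bump one below-max grade
    can_bump <- which(obs$grade < lesions$max_grade[k])
    if (length(can_bump)) {
      i <- can_bump[1]
      obs2 <- obs
      obs2$grade[i] <- obs2$grade[i] + 1L
      prof2 <- severity_profile(obs2, the_scheme)
      expect_true(all(prof2$category_scores >= prof$category_scores))
      expect_gte(prof2$cumulative_score, prof$cumulative_score)
    }
  }
})

test_that("vectorized cohort scoring agrees with per-participant profiles", {
  set.seed(101)
  lesions <- the_scheme$lesions
  obs <- do.call(rbind, lapply(1:30, function(i) {
    k <- sample.int(nrow(lesions), sample(3:27, 1))
    data.frame(
      participant_id = sprintf("q%02d", i),
      lesion_id = lesions$lesion_id[k],
      grade = vapply(lesions$max_grade[k],
                     function(m) sample(c(NA_integer_, 0:m), 1L), integer(1))
    )
  }))
  scored <- score_cohort(obs, the_scheme)
  for (pid in unique(obs$participant_id)) {
    prof <- severity_profile(obs[obs$participant_id == pid, ], the_scheme)
    row <- scored[scored$participant_id == pid, ]
    expect_equal(unlist(row[names(prof$category_scores)]),
                 prof$category_scores, info = pid)
    expect_equal(row$cumulative_score, prof$cumulative_score)
    expect_equal(row$mvm_severe, prof$mvm_severe)
    expect_equal(row$n_lesions_observed, prof$n_observed)
  }
})

test_that("cohort scoring reports completeness and handles missing grades", {
  obs <- rbind(
    make_obs("a", placental_infarction = 2, syncytial_knots = 1),
    data.frame(participant_id = "b", lesion_id = "syncytial_knots",
               grade = NA_integer_)
  )
  res <- score_cohort(obs, the_scheme)
  expect_equal(nrow(res), 2)
  a <- res[res$participant_id == "a", ]
  b <- res[res$participant_id == "b", ]
  expect_equal(a$mvm_score, 3)
  expect_true(a$mvm_severe)
  expect_equal(b$mvm_score, 0)  # missing scored 0...
  expect_equal(b$n_lesions_observed, 0)  # ...but flagged incomplete
  expect_false(b$complete)
})

test_that("wide/long converters and file readers round-trip observations", {
  fx <- fixture_small()$cohort
  long <- lesions_wide_to_long(fx, the_scheme)
  expect_setequal(unique(long$lesion_id), the_scheme$lesions$lesion_id)
  scored <- score_cohort(long, the_scheme)
  expect_equal(nrow(scored), 12)

  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(long, tmp, row.names = FALSE)
  long2 <- read_lesions_long(tmp)
  expect_equal(score_cohort(long2, the_scheme), scored)
})
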