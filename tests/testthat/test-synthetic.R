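test_that("generators are pure functions of their seed", {
  expect_identical(gen_decision_matrix(4, seed = 3),
                   gen_decision_matrix(4, seed = 3))
  expect_false(identical(gen_decision_matrix(4, seed = 3),
                         gen_decision_matrix(4, seed = 4)))
  expect_identical(gen_cohort(50, seed = 5), gen_cohort(50, seed = 5))
  expect_false(identical(gen_cohort(50, seed = 5),
                         gen_cohort(50, seed = 6)))
  # the global RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_cohort(10, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("linguistic fill draws only valid labels; crisp fill is numeric", {
  m <- gen_decision_matrix(6, fill = "linguistic_uniform", seed = 8)
  cells <- unlist(m[, -1])
  expect_true(all(cells %in% c("VL", "L", "M", "H", "VH")))

  m2 <- gen_decision_matrix(3, fill = "crisp_uniform", seed = 8)
  expect_true(all(vapply(m2[, -1], is.numeric, logical(1))))
  expect_error(gen_decision_matrix(1, seed = 1), "at least 2")
  expect_error(gen_decision_matrix(3, dominant_index = 9, seed = 1),
               "dominant_index")
})

test_that("the imaging scenario matrix carries the published accuracy values", {
  for (stratum in c("low", "high")) {
    m <- gen_paper_like_matrix(stratum)
    expect_equal(m$alternative,
                 c("US", "CT non-contrast", "CT contrast", "MRI 1.5T",
                   "MRI 3T"))
    expect_equal(m$sensitivity, c(78, 90.5, 100, 96.6, 100))
    expect_equal(m$specificity, c(83, 100, 94.8, 95.8, 98))
    # both MRI field strengths agree on every non-accuracy criterion
    mri <- m[m$alternative %in% c("MRI 1.5T", "MRI 3T"),
             !names(m) %in% c("alternative", "sensitivity", "specificity")]
    expect_equal(mri[1, ], mri[2, ], ignore_attr = TRUE)
    expect_named(m, c("alternative", imaging_criteria()$criterion))
  }
  # strata differ only in the air-score suitability column
  low <- gen_paper_like_matrix("low"); high <- gen_paper_like_matrix("high")
  differs <- vapply(names(low)[-1],
                    function(cl) !identical(low[[cl]], high[[cl]]),
                    logical(1))
  expect_equal(names(differs)[differs], "air score")
})

test_that("cohort scores concentrate on the calibrated expectations", {
  probs <- cohort_item_probs()
  # frozen hand computations of the closed-form expectation
  expect_equal(expected_air_score(probs$diseased), 6.30)
  expect_equal(expected_air_score(probs$healthy), 3.90)

  cohort <- gen_cohort(2000, seed = 31)
  scored <- air_score(cohort)
  expect_equal(mean(scored$air_score[scored$disease]), 6.30,
               tolerance = 0.05)
  expect_equal(mean(scored$air_score[!scored$disease]), 3.90,
               tolerance = 0.05)
})

test_that("degenerate cohort settings produce all-zero scores", {
  zero <- list(
    vomiting = 0, rlq_pain = 0,
    rebound = c(none = 1, low = 0, mild = 0, severe = 0),
    fever = 0,
    pnl = c(p0 = 1, p1 = 0, p2 = 0),
    wbc = c(p0 = 1, p1 = 0, p2 = 0),
    crp = c(p0 = 1, p1 = 0, p2 = 0)
  )
  cohort <- gen_cohort(100, prevalence = 0,
                       item_probs = list(diseased = zero, healthy = zero),
                       seed = 2)
  scored <- air_score(cohort)
  expect_true(all(scored$air_score == 0))
  expect_true(all(scored$air_category == "low"))
  expect_true(all(scored$air_stratum == "low"))

  expect_error(gen_cohort(0, seed = 1), "positive")
  expect_error(gen_cohort(10, prevalence = 2, seed = 1), "prevalence")
})

test_that("raising disease-conditional severities lowers the low-stratum fraction (coupled seeds)", {
  probs_lo <- cohort_item_probs()
  probs_hi <- probs_lo
  probs_hi$diseased$rebound <- c(none = 0.05, low = 0.15, mild = 0.30,
                                 severe = 0.50)
  probs_hi$diseased$crp <- c(p0 = 0.10, p1 = 0.30, p2 = 0.60)
  probs_hi$diseased$fever <- 0.80

  frac_low <- function(p) {
    cohort <- gen_cohort(1500, prevalence = 1, item_probs = p, seed = 77)
    mean(air_score(cohort)$air_score < 6)
  }
  expect_lte(frac_low(probs_hi), frac_low(probs_lo))
})

test_that("the scenario matrices drive a full report with green self-checks", {
  for (stratum in c("low", "high")) {
    report <- run_scenario(gen_paper_like_matrix(stratum),
                           scenario_config(stratum))
    expect_true(all(unlist(report$selfcheck)))
  }
})
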