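test_that("Gaussian preference function matches its closed form", {
  expect_equal(gaussian_preference(0, 1), 0)
  expect_equal(gaussian_preference(-1, 5), 0)
  expect_equal(gaussian_preference(1, 1), 1 - exp(-0.5))
  expect_equal(gaussian_preference(1, 1), 0.39347, tolerance = 1e-5)
  expect_equal(gaussian_preference(2, 2), 1 - exp(-0.5))

  d <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(gaussian_preference(d, 1.3)) > 0))
  expect_true(all(gaussian_preference(d, 1.3) < 1))

  expect_error(gaussian_preference(1, 0), "`s` must be > 0")
  expect_error(gaussian_preference(1, -2), "`s` must be > 0")
})

test_that("single-criterion pair reproduces the hand-computed index and flows", {
  m <- tibble::tibble(alternative = c("a1", "a2"), f = c(1, 0))
  res <- promethee(m, crit_tbl("f", s = 1))

  expect_equal(res$pi["a1", "a2"], 1 - exp(-0.5))
  expect_equal(res$pi["a2", "a1"], 0)
  # n = 2: flows equal the single pairwise index
  expect_equal(res$flows$phi_plus, c(1 - exp(-0.5), 0))
  expect_equal(res$flows$phi_minus, c(0, 1 - exp(-0.5)))
  expect_equal(res$flows$phi_net, c(1 - exp(-0.5), -(1 - exp(-0.5))))
  expect_equal(res$ranking, c("a1", "a2"))
})

test_that("negative differences contribute nothing to the preference index", {
  # two equally weighted criteria; differences (+s, -s): only the first
  # contributes, so pi = 0.5 * (1 - exp(-1/2))
  m <- tibble::tibble(alternative = c("a1", "a2"),
                      c1 = c(2, 1), c2 = c(1, 3))
  res <- promethee(m, crit_tbl(c("c1", "c2"), s = c(1, 2)))
  expect_equal(res$pi["a1", "a2"], 0.5 * (1 - exp(-0.5)))
  expect_equal(res$pi["a1", "a2"], 0.19674, tolerance = 1e-4)
})

test_that("identical rows give zero index, equal flows and relation I", {
  m <- tibble::tibble(alternative = c("a1", "a2", "a3"),
                      c1 = c(5, 5, 1), c2 = c("H", "H", "L"))
  res <- promethee(m, crit_tbl(c("c1", "c2")))
  expect_equal(res$pi["a1", "a2"], 0)
  expect_equal(res$flows$phi_plus[1], res$flows$phi_plus[2])
  expect_equal(res$flows$phi_minus[1], res$flows$phi_minus[2])
  expect_equal(res$flows$phi_net[1], res$flows$phi_net[2])
  rel <- res$relations
  expect_equal(rel$relation[rel$a == "a1" & rel$b == "a2"], "I")
  expect_true(all(res$flows$tied[1:2]))
})

test_that("engine matches the naive equation-by-equation oracle", {
  for (case in list(c(n = 3, k = 4), c(n = 5, k = 12))) {
    for (seed in 1:10) {
      criteria <- random_criteria(case["k"], seed * 31)
      m <- random_crisp_matrix(case["n"], criteria, seed * 37)
      res <- promethee(m, criteria)

      X <- oracle_defuzzify(m)
      w <- oracle_weights(criteria$weight_label)
      s <- oracle_auto_s(X, criteria$direction)
      ref <- naive_promethee(X, w, s, criteria$direction)

      expect_equal(unname(res$pi), unname(ref$pi), tolerance = 1e-12)
      expect_equal(res$flows$phi_plus, ref$phi_plus, tolerance = 1e-12)
      expect_equal(res$flows$phi_minus, ref$phi_minus, tolerance = 1e-12)
      expect_equal(res$flows$phi_net, ref$phi_net, tolerance = 1e-12)
    }
  }
})

test_that("flows are zero-sum and bounded on random linguistic matrices", {
  for (seed in 1:15) {
    m <- gen_decision_matrix(sample(2:7, 1), fill = "linguistic_uniform",
                             seed = seed)
    res <- promethee(m)
    expect_lt(abs(sum(res$flows$phi_net)), 1e-12)
    expect_true(all(res$pi >= 0 & res$pi <= 1))
    expect_true(all(res$flows$phi_plus >= 0 & res$flows$phi_plus <= 1))
    expect_true(all(res$flows$phi_minus >= 0 & res$flows$phi_minus <= 1))
    expect_true(all(abs(res$flows$phi_net) <= 1))
    expect_setequal(res$ranking, m$alternative)
  }
})

test_that("pairwise indices are local: a third alternative never changes pi(a, b)", {
  criteria <- crit_tbl(c("c1", "c2", "c3"),
                       directions = c("benefit", "cost", "benefit"),
                       s = c(2, 3, 1))
  set.seed(99)
  for (i in 1:10) {
    m3 <- random_crisp_matrix(3, criteria, seed = i * 11)
    m2 <- m3[1:2, ]
    res3 <- promethee(m3, criteria)
    res2 <- promethee(m2, criteria)
    expect_equal(res3$pi["a1", "a2"], res2$pi["a1", "a2"],
                 tolerance = 1e-15)
    expect_equal(res3$pi["a2", "a1"], res2$pi["a2", "a1"],
                 tolerance = 1e-15)
  }
})

test_that("a componentwise-dominant alternative attains the strictly largest net flow", {
  for (seed in 1:8) {
    idx <- (seed %% 4) + 1
    m <- gen_decision_matrix(5, fill = "linguistic_uniform",
                             dominant_index = idx, seed = seed)
    res <- promethee(m)
    expect_equal(res$ranking[1], m$alternative[idx])
    expect_true(all(res$flows$phi_net[idx] >
                      res$flows$phi_net[-idx]))
  }
})

test_that("partial-order relations follow the flow comparison rules", {
  # independent re-derivation of P/I/R from the flows
  rederive <- function(fp, fm, a, b) {
    eq <- function(x, y) abs(x - y) <= 1e-12
    if (eq(fp[a], fp[b]) && eq(fm[a], fm[b])) return("I")
    better_a <- (fp[a] > fp[b] && fm[a] <= fm[b] + 1e-12) ||
      (eq(fp[a], fp[b]) && fm[a] < fm[b])
    better_b <- (fp[b] > fp[a] && fm[b] <= fm[a] + 1e-12) ||
      (eq(fp[a], fp[b]) && fm[b] < fm[a])
    if (better_a || better_b) "P" else "R"
  }
  for (seed in 21:30) {
    criteria <- random_criteria(5, seed)
    m <- random_crisp_matrix(4, criteria, seed + 100)
    res <- promethee(m, criteria)
    fp <- setNames(res$flows$phi_plus, res$flows$alternative)
    fm <- setNames(res$flows$phi_minus, res$flows$alternative)
    for (i in seq_len(nrow(res$relations))) {
      row <- res$relations[i, ]
      expect_equal(row$relation, rederive(fp, fm, row$a, row$b))
    }
  }
})

test_that("full ties keep input order and are flagged indifferent", {
  m <- tibble::tibble(alternative = c("x", "y", "z"),
                      c1 = c(3, 3, 3), c2 = c("M", "M", "M"))
  res <- promethee(m, crit_tbl(c("c1", "c2")))
  expect_equal(res$flows$phi_net, c(0, 0, 0))
  expect_equal(res$ranking, c("x", "y", "z"))
  expect_true(all(res$flows$tied))
  expect_true(all(res$relations$relation == "I"))
})

test_that("the top choice is stable under a 10% Gaussian shape sweep", {
  for (stratum in c("low", "high")) {
    sweep <- sweep_preference_s(gen_paper_like_matrix(stratum))
    expect_true(all(sweep$stable))
  }
})
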