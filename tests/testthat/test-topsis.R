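test_that("vector normalization matches hand computations", {
  m <- tibble::tibble(alternative = c("a1", "a2"),
                      c1 = c(3, 4), c2 = c(5, 5))
  res <- topsis(m, crit_tbl(c("c1", "c2")))
  expect_equal(unname(res$normalized[, "c1"]), c(0.6, 0.8))
  # equal column: all entries 1/sqrt(m)
  expect_equal(unname(res$normalized[, "c2"]), rep(1 / sqrt(2), 2))
  # unit Euclidean norm per column
  expect_equal(unname(colSums(res$normalized^2)), c(1, 1))

  expect_error(
    topsis(tibble::tibble(alternative = c("a", "b"), z = c(0, 0)),
           crit_tbl("z")),
    "z")
})

test_that("weighting scales each normalized column by its weight", {
  m <- tibble::tibble(alternative = c("a1", "a2"),
                      c1 = c(3, 4), c2 = c(3, 4))
  res <- topsis(m, crit_tbl(c("c1", "c2"), labels = c("H", "H")))
  # equal labels -> weights 1/2 each
  expect_equal(unname(res$weights), c(0.5, 0.5))
  expect_equal(unname(res$weighted[, "c1"]), c(0.3, 0.4))
})

test_that("ideal solutions respect criterion directions", {
  m <- tibble::tibble(alternative = c("a1", "a2"),
                      c1 = c(3, 4), c2 = c(4, 3))
  res_bb <- topsis(m, crit_tbl(c("c1", "c2"), c("benefit", "benefit")))
  expect_equal(unname(res_bb$a_plus),
               unname(apply(res_bb$weighted, 2, max)))
  expect_equal(unname(res_bb$a_minus),
               unname(apply(res_bb$weighted, 2, min)))

  # flipping one direction swaps that criterion's ideal components
  res_bc <- topsis(m, crit_tbl(c("c1", "c2"), c("benefit", "cost")))
  expect_equal(res_bc$a_plus[["c2"]], res_bb$a_minus[["c2"]])
  expect_equal(res_bc$a_minus[["c2"]], res_bb$a_plus[["c2"]])
  expect_equal(res_bc$a_plus[["c1"]], res_bb$a_plus[["c1"]])
})

test_that("closeness coefficient matches its definition and bounds", {
  expect_equal(closeness_coefficient(0.0946, 0.1561),
               0.1561 / (0.1561 + 0.0946))
  expect_equal(round(closeness_coefficient(0.0946, 0.1561), 4), 0.6227)
  expect_equal(closeness_coefficient(0, 0.3), 1)
  expect_equal(closeness_coefficient(0.3, 0), 0)
  expect_error(closeness_coefficient(0, 0), "zero distance")
  expect_error(closeness_coefficient(-0.1, 0.5), "non-negative")

  # strictly decreasing in d+, increasing in d-
  expect_true(closeness_coefficient(0.2, 0.5) >
                closeness_coefficient(0.3, 0.5))
  expect_true(closeness_coefficient(0.2, 0.6) >
                closeness_coefficient(0.2, 0.5))
})

test_that("engine matches the naive equation-by-equation oracle", {
  for (seed in 1:10) {
    criteria <- random_criteria(12, seed * 13)
    m <- random_crisp_matrix(5, criteria, seed * 17)
    res <- topsis(m, criteria)

    X <- oracle_defuzzify(m)
    w <- oracle_weights(criteria$weight_label)
    ref <- naive_topsis(X, w, criteria$direction)

    expect_equal(res$scores$d_plus, ref$d_plus, tolerance = 1e-12)
    expect_equal(res$scores$d_minus, ref$d_minus, tolerance = 1e-12)
    expect_equal(res$scores$closeness, ref$closeness, tolerance = 1e-12)
    expect_true(all(res$scores$closeness >= 0 &
                      res$scores$closeness <= 1))
    expect_equal(res$scores$closeness,
                 res$scores$d_minus /
                   (res$scores$d_minus + res$scores$d_plus))
  }
})

test_that("a componentwise-dominant alternative reaches the ideal (R = 1)", {
  m <- gen_decision_matrix(5, fill = "crisp_uniform", dominant_index = 3,
                           seed = 5)
  res <- topsis(m)
  expect_equal(res$scores$d_plus[3], 0)
  expect_equal(res$scores$closeness[3], 1)
  expect_equal(res$ranking[1], m$alternative[3])
})

test_that("duplicate rows receive identical closeness and ties are flagged", {
  m <- tibble::tibble(alternative = c("a1", "a2", "a3"),
                      c1 = c("H", "H", "L"), c2 = c(4, 4, 9))
  res <- topsis(m, crit_tbl(c("c1", "c2"), c("benefit", "cost")))
  expect_equal(res$scores$closeness[1], res$scores$closeness[2])
  expect_true(all(res$scores$tied[1:2]))
  # input order preserved within the tie
  expect_lt(res$scores$rank[1], res$scores$rank[2])
})

test_that("closeness is invariant to positive rescaling of any raw column", {
  criteria <- random_criteria(6, 71)
  m <- random_crisp_matrix(4, criteria, 72)
  base <- topsis(m, criteria)$scores$closeness
  for (lambda in c(0.01, 100)) {
    for (col in criteria$criterion[c(1, 4)]) {
      m2 <- m
      m2[[col]] <- m2[[col]] * lambda
      expect_equal(topsis(m2, criteria)$scores$closeness, base,
                   tolerance = 1e-12)
    }
  }
})
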