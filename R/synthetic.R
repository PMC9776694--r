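# Run code with a temporary, seed-initialized RNG state, restoring the
# caller's state afterwards so generators are pure functions of their seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Generate a random decision matrix
#'
#' Seed-reproducible random matrices for testing and simulation, with an
#' optional dominant alternative that is componentwise at least as good as
#' every other row after direction adjustment and strictly better on the
#' first criterion.
#'
#' @param n_alternatives Number of alternatives (>= 2).
#' @param criteria Criteria tibble; defaults to [imaging_criteria()].
#' @param fill `"linguistic_uniform"` (cells drawn uniformly from the five
#'   labels), `"crisp_uniform"` (numeric cells uniform on (10, 90)) or
#'   `"paper_like"` (delegates to [gen_paper_like_matrix()]).
#' @param dominant_index Optional row index (1-based) forced to dominate.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A decision matrix tibble (see [validate_matrix()]).
#' @examples
#' gen_decision_matrix(4, seed = 1)
#' @export
gen_decision_matrix <- function(n_alternatives = 5,
                                criteria = imaging_criteria(),
                                fill = c("linguistic_uniform",
                                         "crisp_uniform", "paper_like"),
                                dominant_index = NULL,
                                seed = 1) {
  fill <- match.arg(fill)
  if (fill == "paper_like") return(gen_paper_like_matrix("low"))
  criteria <- validate_criteria(criteria)
  if (n_alternatives < 2) {
    rlang::abort("`n_alternatives` must be at least 2.")
  }
  if (!is.null(dominant_index) &&
      (dominant_index < 1 || dominant_index > n_alternatives)) {
    rlang::abort("`dominant_index` must index an alternative row.")
  }
  k <- nrow(criteria)
  labels <- linguistic_labels()

  with_seed(seed, {
    if (fill == "linguistic_uniform") {
      cells <- matrix(sample(labels, n_alternatives * k, replace = TRUE),
                      n_alternatives, k)
    } else {
      cells <- matrix(stats::runif(n_alternatives * k, 10, 90),
                      n_alternatives, k)
    }
    if (!is.null(dominant_index)) {
      benefit <- criteria$direction == "benefit"
      if (fill == "linguistic_uniform") {
        best <- ifelse(benefit, "VH", "VL")
        cells[dominant_index, ] <- best
        # strictness on the first criterion: no rival may match the best
        rivals <- setdiff(seq_len(n_alternatives), dominant_index)
        worse <- setdiff(labels, best[1])
        cells[rivals, 1] <- sample(worse, length(rivals), replace = TRUE)
      } else {
        cells[dominant_index, ] <- ifelse(benefit, 95, 5)
      }
    }
    out <- tibble::as_tibble(as.data.frame(cells,
                                           stringsAsFactors = FALSE))
    names(out) <- criteria$criterion
    dplyr::bind_cols(
      tibble::tibble(alternative = paste0("alt", seq_len(n_alternatives))),
      out
    )
  })
}

#' Default linguistic judgments for the imaging alternatives
#'
#' Expert-style linguistic fill-in for the ten criteria without published
#' crisp values, one row per (criterion, alternative) pair. The values are
#' the package defaults, not measurements: they encode the usual clinical
#' trade-offs (ultrasound is operator-dependent but radiation-free, fast
#' and cheap; CT is fast and accurate but irradiates; MRI is accurate,
#' radiation-free, but slow, costly and hard for young children). Only the
#' "air score" suitability row differs between strata: ultrasound is
#' favored for low-probability patients, cross-sectional imaging for
#' high-probability ones. Both MRI field strengths share one column, so
#' their rows differ only in sensitivity/specificity. Edit the returned
#' tibble to encode your own judgments before building a matrix.
#'
#' @param stratum `"low"` or `"high"` AIR stratum.
#' @return Tibble with columns `criterion`, `US`, `CT non-contrast`,
#'   `CT contrast`, `MRI` (labels `VL`...`VH`).
#' @export
imaging_judgments <- function(stratum = c("low", "high")) {
  stratum <- match.arg(stratum)
  fill <- tibble::tribble(
    ~criterion,             ~US,  ~`CT non-contrast`, ~`CT contrast`, ~MRI,
    "diagnostic precision", "M",  "H",                "VH",           "H",
    "time of imaging",      "L",  "L",                "M",            "VH",
    "user dependency",      "VH", "L",                "L",            "L",
    "radiation dose",       "VL", "H",                "H",            "VL",
    "comfortability",       "VH", "H",                "H",            "L",
    "air score",            "H",  "M",                "M",            "M",
    "disposition",          "H",  "H",                "H",            "M",
    "time of order",        "L",  "M",                "M",            "H",
    "result time",          "L",  "M",                "M",            "H",
    "cost",                 "L",  "M",                "H",            "VH"
  )
  if (stratum == "high") {
    fill[fill$criterion == "air score", -1] <-
      tibble::tibble(US = "M", `CT non-contrast` = "H",
                     `CT contrast` = "H", MRI = "H")
  }
  fill
}

#' Decision matrix emulating the published imaging scenario
#'
#' Builds the five-alternative (US, non-contrast CT, contrast-enhanced CT,
#' 1.5 T MRI, 3 T MRI) by twelve-criterion matrix. Sensitivity and
#' specificity are fixed to published crisp accuracy values (percent):
#' sensitivity 78, 90.5, 100, 96.6, 100 and specificity 83, 100, 94.8,
#' 95.8, 98 respectively. All other criteria take the linguistic defaults
#' of [imaging_judgments()] (overridable via `judgments`). Percent values
#' enter as crisp 0-100 numbers; vector normalization and the automatic
#' Gaussian shape parameter make the ranking invariant to the column
#' scale, so they need not be mapped onto the 0-1 linguistic range.
#'
#' @param stratum `"low"` or `"high"` AIR stratum.
#' @param judgments Optional replacement for [imaging_judgments()] output.
#' @return A decision matrix tibble with columns ordered as
#'   [imaging_criteria()].
#' @examples
#' gen_paper_like_matrix("low")
#' @export
gen_paper_like_matrix <- function(stratum = c("low", "high"),
                                  judgments = NULL) {
  stratum <- match.arg(stratum)
  if (is.null(judgments)) judgments <- imaging_judgments(stratum)
  alternatives <- c("US", "CT non-contrast", "CT contrast",
                    "MRI 1.5T", "MRI 3T")
  accuracy <- tibble::tibble(
    alternative = alternatives,
    sensitivity = c(78, 90.5, 100, 96.6, 100),
    specificity = c(83, 100, 94.8, 95.8, 98)
  )
  fill_cols <- c("US", "CT non-contrast", "CT contrast", "MRI", "MRI")
  ling <- purrr::map_dfc(seq_along(alternatives), function(i) {
    tibble::tibble(!!alternatives[i] := judgments[[fill_cols[i]]])
  })
  ling <- dplyr::bind_cols(judgments["criterion"], ling)
  long <- tidyr::pivot_longer(ling, -"criterion",
                              names_to = "alternative",
                              values_to = "value")
  wide <- tidyr::pivot_wider(long, names_from = "criterion",
                             values_from = "value")
  out <- dplyr::left_join(accuracy, wide, by = "alternative")
  crit_order <- imaging_criteria()$criterion
  validate_matrix(out[, c("alternative", crit_order)])
}

#' Default AIR item probabilities for the cohort generator
#'
#' Per-item occurrence probabilities conditional on disease status,
#' calibrated so the expected AIR score is 6.30 for appendicitis cases and
#' 3.90 for non-cases (matching the reported operated / not-operated
#' strata means). Binary items are Bernoulli probabilities; `rebound`,
#' `pnl`, `wbc`, `crp` are distributions over their ordered point levels.
#'
#' @return Named list with elements `diseased` and `healthy`, each a list
#'   of item probabilities.
#' @seealso [expected_air_score()] for the closed-form expectation.
#' @export
cohort_item_probs <- function() {
  list(
    diseased = list(
      vomiting = 0.55, rlq_pain = 0.90,
      rebound = c(none = 0.15, low = 0.30, mild = 0.35, severe = 0.20),
      fever = 0.40,
      pnl = c(p0 = 0.30, p1 = 0.45, p2 = 0.25),
      wbc = c(p0 = 0.30, p1 = 0.40, p2 = 0.30),
      crp = c(p0 = 0.35, p1 = 0.40, p2 = 0.25)
    ),
    healthy = list(
      vomiting = 0.30, rlq_pain = 0.70,
      rebound = c(none = 0.45, low = 0.35, mild = 0.15, severe = 0.05),
      fever = 0.25,
      pnl = c(p0 = 0.60, p1 = 0.30, p2 = 0.10),
      wbc = c(p0 = 0.50, p1 = 0.35, p2 = 0.15),
      crp = c(p0 = 0.45, p1 = 0.40, p2 = 0.15)
    )
  )
}

#' Expected AIR score under a set of item probabilities
#'
#' Closed-form expectation of the AIR point sum: the Bernoulli items
#' contribute their probability, the leveled items the probability-weighted
#' point values.
#'
#' @param probs One element of [cohort_item_probs()] (e.g.
#'   `cohort_item_probs()$diseased`).
#' @return The expected AIR score (numeric scalar).
#' @examples
#' expected_air_score(cohort_item_probs()$diseased)   # 6.30
#' expected_air_score(cohort_item_probs()$healthy)    # 3.90
#' @export
expected_air_score <- function(probs) {
  probs$vomiting + probs$rlq_pain +
    sum(probs$rebound * c(0, 1, 2, 3)) +
    probs$fever +
    sum(probs$pnl * c(0, 1, 2)) +
    sum(probs$wbc * c(0, 1, 2)) +
    sum(probs$crp * c(0, 1, 2))
}

# Inverse-CDF band assignment: monotone in the cumulative probabilities,
# so cohorts generated from the same seed are coupled across settings.
assign_band <- function(u, probs) {
  findInterval(u, cumsum(probs)[-length(probs)]) + 1L
}

#' Generate a synthetic patient cohort
#'
#' Draws AIR findings for `n_patients` with disease status Bernoulli at
#' `prevalence` and per-item probabilities conditional on status. Leveled
#' items are drawn by inverse CDF from one uniform per (patient, item), so
#' fixing the seed couples cohorts across probability settings; continuous
#' measurements are then drawn uniformly within the band consistent with
#' the item's point level.
#'
#' @param n_patients Number of patients (> 0).
#' @param prevalence Appendicitis prevalence in the cohort (default 0.725,
#'   the operated fraction of the emulated 51-patient series).
#' @param item_probs Conditional item probabilities, see
#'   [cohort_item_probs()].
#' @param seed Integer seed.
#' @return Tibble with `patient_id`, `disease` (logical) and the AIR
#'   findings columns accepted by [air_score()].
#' @examples
#' cohort <- gen_cohort(100, seed = 7)
#' air_score(cohort) |> dplyr::count(air_category)
#' @export
gen_cohort <- function(n_patients, prevalence = 0.725,
                       item_probs = cohort_item_probs(), seed = 1) {
  if (n_patients <= 0) rlang::abort("`n_patients` must be positive.")
  if (prevalence < 0 || prevalence > 1) {
    rlang::abort("`prevalence` must lie in [0, 1].")
  }
  ok <- function(p) all(p >= 0 & p <= 1)
  for (grp in item_probs) {
    if (!ok(unlist(grp))) rlang::abort("Item probabilities must lie in [0, 1].")
    for (nm in c("rebound", "pnl", "wbc", "crp")) {
      if (abs(sum(grp[[nm]]) - 1) > 1e-8) {
        rlang::abort(paste0("`", nm, "` level probabilities must sum to 1."))
      }
    }
  }

  with_seed(seed, {
    u_dis <- stats::runif(n_patients)
    u_item <- matrix(stats::runif(n_patients * 7), n_patients, 7)
    u_val <- matrix(stats::runif(n_patients * 4), n_patients, 4)

    disease <- u_dis < prevalence
    pick <- function(field) {
      lapply(ifelse(disease, "diseased", "healthy"),
             function(g) item_probs[[g]][[field]])
    }
    row_band <- function(col, field) {
      p <- pick(field)
      vapply(seq_len(n_patients),
             function(i) assign_band(u_item[i, col], p[[i]]), integer(1))
    }

    vomiting <- u_item[, 1] < unlist(pick("vomiting"))
    rlq_pain <- u_item[, 2] < unlist(pick("rlq_pain"))
    rebound_lvl <- row_band(3, "rebound")
    fever <- u_item[, 4] < unlist(pick("fever"))
    pnl_lvl <- row_band(5, "pnl")
    wbc_lvl <- row_band(6, "wbc")
    crp_lvl <- row_band(7, "crp")

    in_band <- function(u, lo, hi) lo + u * (hi - lo)
    temperature_c <- ifelse(fever,
                            in_band(u_val[, 1], 38.6, 40.5),
                            in_band(u_val[, 1], 36.5, 38.5))
    pnl_percent <- in_band(u_val[, 2],
                           c(40, 70, 85)[pnl_lvl],
                           c(69.9, 84.9, 98)[pnl_lvl])
    wbc_count <- in_band(u_val[, 3],
                         c(4, 10, 15)[wbc_lvl],
                         c(9.9, 14.9, 25)[wbc_lvl])
    crp <- in_band(u_val[, 4],
                   c(0, 10, 50)[crp_lvl],
                   c(9.9, 49.9, 200)[crp_lvl])

    tibble::tibble(
      patient_id = seq_len(n_patients),
      disease = disease,
      vomiting = vomiting,
      rlq_pain = rlq_pain,
      rebound = c("none", "low", "mild", "severe")[rebound_lvl],
      temperature_c = temperature_c,
      pnl_percent = pnl_percent,
      wbc_count = wbc_count,
      crp = crp
    )
  })
}
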