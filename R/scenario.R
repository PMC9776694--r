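#' Build a scenario configuration
#'
#' Bundles everything one ranking run needs: the AIR stratum, the criteria
#' table (directions, linguistic weights, optional Gaussian shape
#' overrides), the alternative set, and reporting options.
#'
#' @param stratum `"low"` or `"high"` AIR stratum.
#' @param criteria Criteria tibble; defaults to [imaging_criteria()].
#' @param alternatives Character vector of expected alternative names
#'   (>= 2); defaults to the five imaging modalities.
#' @param merge_identical Collapse alternatives with identical defuzzified
#'   rows into one report entry (default `TRUE`; the engines always run on
#'   the full set).
#' @param weight_method Yager index variant.
#' @param seed Integer seed recorded for any synthetic fill-in.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(stratum = c("low", "high"),
                            criteria = imaging_criteria(),
                            alternatives = c("US", "CT non-contrast",
                                             "CT contrast", "MRI 1.5T",
                                             "MRI 3T"),
                            merge_identical = TRUE,
                            weight_method = c("centroid", "weighted_mode"),
                            seed = 1) {
  stratum <- match.arg(stratum)
  weight_method <- match.arg(weight_method)
  criteria <- validate_criteria(criteria)
  if (length(alternatives) < 2) {
    rlang::abort("A scenario needs at least 2 alternatives.")
  }
  if (anyDuplicated(alternatives)) {
    rlang::abort("Alternative names must be unique.")
  }
  structure(
    list(stratum = stratum, criteria = criteria,
         alternatives = alternatives,
         merge_identical = isTRUE(merge_identical),
         weight_method = weight_method, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Run a full ranking scenario
#'
#' Defuzzifies the decision matrix once, runs PROMETHEE and TOPSIS on the
#' identical crisp input, compares the two rankings (Kendall tau and
#' top-choice agreement), verifies the engine invariants (zero-sum net
#' flows, closeness bounds, permutation validity), and attaches
#' provenance (config summary, matrix hash, package version).
#'
#' @param data Decision matrix whose alternatives and criteria match the
#'   configuration.
#' @param config A [scenario_config()].
#' @return A `scenario_report` list with elements `promethee`, `topsis`,
#'   `agreement`, `ranking` (merged display ranking per method),
#'   `selfcheck`, `config` and `provenance`.
#' @examples
#' report <- run_scenario(gen_paper_like_matrix("low"), scenario_config("low"))
#' report$agreement
#' @export
run_scenario <- function(data, config = scenario_config()) {
  if (!inherits(config, "scenario_config")) {
    rlang::abort("`config` must be created by scenario_config().")
  }
  data <- validate_matrix(data, config$criteria)
  extra <- setdiff(data$alternative, config$alternatives)
  missing_alt <- setdiff(config$alternatives, data$alternative)
  if (length(extra) > 0 || length(missing_alt) > 0) {
    rlang::abort(paste0(
      "Matrix alternatives do not match the configuration.",
      if (length(missing_alt) > 0)
        paste0("\n  missing: ", paste(missing_alt, collapse = ", ")),
      if (length(extra) > 0)
        paste0("\n  unexpected: ", paste(extra, collapse = ", "))
    ))
  }
  data <- data[match(config$alternatives, data$alternative), ]

  prom <- promethee(data, config$criteria,
                    weight_method = config$weight_method)
  tops <- topsis(data, config$criteria,
                 weight_method = config$weight_method)
  agreement <- compare_rankings(prom$ranking, tops$ranking)

  crisp <- defuzzify_matrix(data, config$criteria,
                            method = config$weight_method)
  groups <- identical_row_groups(crisp)
  ranking <- list(
    promethee = merge_ranking(prom$ranking, groups, config$merge_identical),
    topsis = merge_ranking(tops$ranking, groups, config$merge_identical)
  )

  selfcheck <- list(
    zero_sum_net_flow = abs(sum(prom$flows$phi_net)) <= 1e-12,
    pi_in_unit_interval = all(prom$pi >= 0 & prom$pi <= 1),
    closeness_in_unit_interval =
      all(tops$scores$closeness >= 0 & tops$scores$closeness <= 1),
    rankings_are_permutations =
      setequal(prom$ranking, data$alternative) &&
      setequal(tops$ranking, data$alternative)
  )

  structure(
    list(
      promethee = prom,
      topsis = tops,
      agreement = agreement,
      ranking = ranking,
      merged_groups = groups[lengths(groups) > 1],
      selfcheck = selfcheck,
      config = config,
      provenance = list(
        stratum = config$stratum,
        matrix_hash = rlang::hash(crisp),
        seed = config$seed,
        package_version = as.character(utils::packageVersion("airmcdm"))
      )
    ),
    class = "scenario_report"
  )
}

# Groups of alternatives whose defuzzified rows are identical.
identical_row_groups <- function(crisp) {
  key <- apply(as.matrix(crisp[, -1, drop = FALSE]), 1,
               function(r) paste(format(r, digits = 15), collapse = "|"))
  unname(split(crisp$alternative, factor(key, levels = unique(key))))
}

# Collapse identical-row alternatives into one "a/b" display entry,
# keeping the position of the best-ranked member.
merge_ranking <- function(ranking, groups, merge) {
  if (!merge) return(ranking)
  label_of <- ranking
  for (g in groups[lengths(groups) > 1]) {
    merged <- paste(g, collapse = "/")
    label_of[ranking %in% g] <- merged
  }
  unique(label_of)
}

#' Compare two rankings of the same alternatives
#'
#' Kendall rank correlation between two orderings plus a top-choice match
#' flag; used to quantify cross-method agreement.
#'
#' @param r1,r2 Character vectors: the same alternative set in two orders.
#' @return Tibble with `kendall_tau` and `top_match`.
#' @examples
#' compare_rankings(c("a", "b", "c"), c("a", "c", "b"))
#' @export
compare_rankings <- function(r1, r2) {
  if (!setequal(r1, r2) || length(r1) != length(r2)) {
    rlang::abort("Rankings must order the same alternative set.")
  }
  rank1 <- match(r1, r1)
  rank2 <- match(r1, r2)
  tibble::tibble(
    kendall_tau = unname(stats::cor(rank1, rank2, method = "kendall")),
    top_match = r1[1] == r2[1]
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Imaging scenario report -", x$config$stratum, "AIR stratum\n\n")
  cat("PROMETHEE ranking:",
      paste(x$ranking$promethee, collapse = " > "), "\n")
  cat("TOPSIS ranking:   ",
      paste(x$ranking$topsis, collapse = " > "), "\n")
  cat(sprintf("Agreement: Kendall tau = %.4f, top choice %s\n",
              x$agreement$kendall_tau,
              if (x$agreement$top_match) "matches" else "differs"))
  invisible(x)
}

#' Tidy a scenario report
#'
#' One row per alternative and method with the method's scores and ranks.
#'
#' @param x A `scenario_report`.
#' @param ... Unused.
#' @return Tibble with `alternative`, `method`, `score` (net flow or
#'   closeness), `rank`.
#' @export
tidy.scenario_report <- function(x, ...) {
  dplyr::bind_rows(
    x$promethee$flows |>
      dplyr::transmute(.data$alternative, method = "promethee",
                       score = .data$phi_net, .data$rank),
    x$topsis$scores |>
      dplyr::transmute(.data$alternative, method = "topsis",
                       score = .data$closeness, .data$rank)
  )
}

#' One-row summary of a scenario report
#'
#' @inheritParams tidy.scenario_report
#' @return Tibble with the stratum, each method's top choice, the Kendall
#'   tau between the rankings and the self-check status.
#' @export
glance.scenario_report <- function(x, ...) {
  tibble::tibble(
    stratum = x$config$stratum,
    promethee_top = x$promethee$ranking[1],
    topsis_top = x$topsis$ranking[1],
    kendall_tau = x$agreement$kendall_tau,
    top_match = x$agreement$top_match,
    selfcheck_passed = all(unlist(x$selfcheck))
  )
}

#' Plot both rankings of a scenario side by side
#'
#' @param object A `scenario_report`.
#' @param ... Unused.
#' @return A ggplot object (faceted by method).
#' @export
autoplot.scenario_report <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(alternative = tidyr::replace_na(.data$alternative, "")) |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$alternative, -.data$rank),
      y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~method, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "net flow / closeness",
                  title = paste("Imaging ranking,",
                                object$config$stratum, "AIR stratum")) +
    ggplot2::theme_minimal()
}
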