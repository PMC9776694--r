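#' Gaussian preference function
#'
#' Maps a pairwise criterion difference to a preference degree in `[0, 1]`:
#' zero for non-positive differences, `1 - exp(-d^2 / (2 s^2))` otherwise.
#' Strictly increasing in `d` for `d > 0`, approaching 1 as the difference
#' grows relative to the shape parameter `s`.
#'
#' @param d Numeric vector of criterion differences `f(a) - f(b)`.
#' @param s Gaussian shape parameter, `> 0` (scalar or recycled vector).
#' @return Numeric vector of preference degrees in `[0, 1]`.
#' @examples
#' gaussian_preference(c(-1, 0, 1), s = 1)
#' @export
gaussian_preference <- function(d, s) {
  if (any(is.na(s)) || any(s <= 0)) {
    rlang::abort("Gaussian shape parameter `s` must be > 0.")
  }
  ifelse(d <= 0, 0, 1 - exp(-d^2 / (2 * s^2)))
}

# Direction-adjust a defuzzified numeric matrix: negate cost columns so a
# larger adjusted value is always better.
adjust_directions <- function(X, directions) {
  stopifnot(ncol(X) == length(directions))
  cost <- directions == "cost"
  X[, cost] <- -X[, cost, drop = FALSE]
  X
}

# Per-criterion Gaussian shape parameters: configured value when given,
# otherwise the population standard deviation of the (defuzzified,
# direction-adjusted) column. Zero-spread columns keep s = 0 and are
# skipped by the preference index (no discrimination, no preference).
resolve_preference_s <- function(X, preference_s = NULL) {
  auto <- apply(X, 2, function(col) sqrt(mean((col - mean(col))^2)))
  if (is.null(preference_s)) return(auto)
  s <- ifelse(is.na(preference_s), auto, preference_s)
  as.numeric(s)
}

# Pairwise preference-index matrix pi[a, b] = sum_k w_k p_k(x_ak - x_bk)
# over a direction-adjusted numeric matrix X.
preference_index_matrix <- function(X, weights, s) {
  n <- nrow(X)
  k_use <- which(s > 0)
  pi_mat <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      d <- X[a, k_use] - X[b, k_use]
      pi_mat[a, b] <- sum(weights[k_use] *
                            gaussian_preference(d, s[k_use]))
    }
  }
  pi_mat
}

# Leaving (phi+) and entering (phi-) flows from a preference-index matrix.
outranking_flows <- function(pi_mat) {
  n <- nrow(pi_mat)
  if (n < 2) rlang::abort("Flows need at least 2 alternatives.")
  list(
    phi_plus  = rowSums(pi_mat) / (n - 1),
    phi_minus = colSums(pi_mat) / (n - 1)
  )
}

# Pairwise partial-order labels from the two flows: P when one alternative
# is at least as good on both flows and strictly better on one, I when both
# flows agree, R when the flows conflict (incomparable).
flow_relations <- function(phi_plus, phi_minus, alternatives,
                           tol = 1e-12) {
  pairs <- utils::combn(seq_along(alternatives), 2)
  cmp <- function(x, y) {
    if (abs(x - y) <= tol) 0 else sign(x - y)
  }
  rel <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    cp <- cmp(phi_plus[a], phi_plus[b])
    cm <- cmp(phi_minus[a], phi_minus[b])
    rel[j] <-
      if (cp == 0 && cm == 0) "I"
      else if ((cp > 0 && cm <= 0) || (cp == 0 && cm < 0)) "P"
      else if ((cp < 0 && cm >= 0) || (cp == 0 && cm > 0)) "P'"
      else "R"
  }
  tibble::tibble(
    a = alternatives[pairs[1, ]],
    b = alternatives[pairs[2, ]],
    relation = ifelse(rel == "P'", "P", rel),
    preferred = dplyr::case_when(
      rel == "P"  ~ alternatives[pairs[1, ]],
      rel == "P'" ~ alternatives[pairs[2, ]],
      TRUE ~ NA_character_
    )
  )
}

#' PROMETHEE I/II outranking analysis
#'
#' Runs the full outranking computation on a (possibly linguistic) decision
#' matrix: defuzzification, direction adjustment, pairwise Gaussian
#' preference indices, leaving/entering flows (PROMETHEE I partial order)
#' and the net-flow total order (PROMETHEE II).
#'
#' Criterion weights come from the linguistic importance labels in
#' `criteria`, defuzzified and normalized to sum to 1, so every preference
#' index lies in `[0, 1]`. Cost criteria enter with the sign of the
#' pairwise difference flipped. The Gaussian shape parameter defaults per
#' criterion to the population standard deviation of the defuzzified
#' column, which makes the analysis invariant to positive rescaling of any
#' criterion; set `preference_s` in `criteria` to override.
#'
#' @param data Decision matrix (see [validate_matrix()]).
#' @param criteria Criteria tibble with `criterion`, `direction`,
#'   `weight_label` and optional `preference_s`; defaults to
#'   [imaging_criteria()] when the matrix columns match it.
#' @param weight_method Yager index variant for defuzzification.
#' @param s_factor Positive scalar multiplying every resolved Gaussian
#'   shape parameter; used by [sweep_preference_s()] for stability checks.
#' @return An object of class `promethee_result`: a list with `flows`
#'   (tibble: alternative, phi_plus, phi_minus, phi_net, rank, tied),
#'   `pi` (preference-index matrix), `relations` (pairwise P/I/R tibble),
#'   `ranking` (alternatives by descending net flow), `weights`, and the
#'   resolved `preference_s`.
#' @examples
#' m <- gen_paper_like_matrix("low")
#' res <- promethee(m)
#' tidy(res)
#' @export
promethee <- function(data, criteria = NULL,
                      weight_method = c("centroid", "weighted_mode"),
                      s_factor = 1) {
  weight_method <- match.arg(weight_method)
  if (is.null(criteria)) criteria <- imaging_criteria()
  criteria <- validate_criteria(criteria)
  if (!is.numeric(s_factor) || length(s_factor) != 1 || s_factor <= 0) {
    rlang::abort("`s_factor` must be a positive scalar.")
  }

  crisp <- defuzzify_matrix(data, criteria, method = weight_method)
  X <- as.matrix(crisp[, -1, drop = FALSE])
  rownames(X) <- crisp$alternative
  X <- adjust_directions(X, criteria$direction)

  weights <- fuzzy_weights(criteria$weight_label, method = weight_method)
  s <- resolve_preference_s(X, criteria$preference_s) * s_factor

  pi_mat <- preference_index_matrix(X, weights, s)
  flows <- outranking_flows(pi_mat)
  phi_net <- flows$phi_plus - flows$phi_minus

  ord <- order(-phi_net)  # stable: ties keep input order
  rank_of <- integer(length(ord)); rank_of[ord] <- seq_along(ord)
  tied <- vapply(seq_along(phi_net), function(i) {
    any(abs(phi_net[-i] - phi_net[i]) <= 1e-12)
  }, logical(1))

  flows_tbl <- tibble::tibble(
    alternative = crisp$alternative,
    phi_plus = unname(flows$phi_plus),
    phi_minus = unname(flows$phi_minus),
    phi_net = unname(phi_net),
    rank = rank_of,
    tied = tied
  )

  structure(
    list(
      flows = flows_tbl,
      pi = pi_mat,
      relations = flow_relations(flows$phi_plus, flows$phi_minus,
                                 crisp$alternative),
      ranking = crisp$alternative[ord],
      weights = stats::setNames(weights, criteria$criterion),
      preference_s = stats::setNames(s, criteria$criterion),
      weight_method = weight_method
    ),
    class = "promethee_result"
  )
}

#' Stability of the top choice under Gaussian shape perturbation
#'
#' Re-runs the PROMETHEE ranking with every automatic Gaussian shape
#' parameter multiplied by each factor and reports the winner, flagging
#' whether the top choice is unchanged across the sweep.
#'
#' @inheritParams promethee
#' @param factors Positive multipliers for the shape parameters
#'   (default a ±10% band around the automatic value).
#' @return Tibble with columns `s_factor`, `top`, `stable`.
#' @export
sweep_preference_s <- function(data, criteria = NULL,
                               factors = c(0.9, 1, 1.1)) {
  res <- purrr::map_chr(factors, function(f) {
    promethee(data, criteria, s_factor = f)$ranking[1]
  })
  tibble::tibble(s_factor = factors, top = res,
                 stable = res == res[factors == 1][1])
}

#' @export
print.promethee_result <- function(x, ...) {
  cat("PROMETHEE outranking analysis\n")
  cat("Ranking (by net flow):", paste(x$ranking, collapse = " > "), "\n\n")
  print(round_half_even(x$flows, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the flows of a PROMETHEE result
#'
#' @param x A `promethee_result`.
#' @param ... Unused.
#' @return Tibble with one row per alternative: `alternative`, `phi_plus`,
#'   `phi_minus`, `phi_net`, `rank`, `tied`.
#' @export
tidy.promethee_result <- function(x, ...) x$flows

#' One-row summary of a PROMETHEE result
#'
#' @inheritParams tidy.promethee_result
#' @return Tibble with `n_alternatives`, `n_criteria`, `top`,
#'   `phi_net_top`, `sum_phi_net`, `n_tied`.
#' @export
glance.promethee_result <- function(x, ...) {
  tibble::tibble(
    n_alternatives = nrow(x$flows),
    n_criteria = length(x$weights),
    top = x$ranking[1],
    phi_net_top = max(x$flows$phi_net),
    sum_phi_net = sum(x$flows$phi_net),
    n_tied = sum(x$flows$tied)
  )
}

#' Plot PROMETHEE flows
#'
#' Bar chart of the net flow per alternative, ordered by rank, with the
#' leaving/entering flows overplotted as points.
#'
#' @param object A `promethee_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.promethee_result <- function(object, ...) {
  flows <- object$flows |>
    dplyr::mutate(alternative = stats::reorder(.data$alternative,
                                               -.data$rank))
  ggplot2::ggplot(flows, ggplot2::aes(x = .data$alternative)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$phi_net), fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$phi_plus), shape = 24) +
    ggplot2::geom_point(ggplot2::aes(y = .data$phi_minus), shape = 25) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "outranking flow",
                  title = "PROMETHEE net flows",
                  subtitle = "triangles: leaving (up) / entering (down) flows") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
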