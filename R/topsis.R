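#' TOPSIS closeness-coefficient analysis
#'
#' Ranks the alternatives of a (possibly linguistic) decision matrix by
#' relative closeness to the ideal solution: the defuzzified matrix is
#' column-wise vector-normalized (each criterion column divided by its
#' Euclidean norm), weighted by the normalized criterion weights, compared
#' against the positive ideal `A+` (columnwise best: max for benefit
#' criteria, min for cost) and the negative ideal `A-` (the reverse), and
#' each alternative is scored by
#' `R_i = d_i^- / (d_i^- + d_i^+)` where `d_i^+`/`d_i^-` are Euclidean
#' distances to `A+`/`A-`. Larger `R_i` is better; ties keep input order
#' and are flagged rather than broken.
#'
#' @inheritParams promethee
#' @return An object of class `topsis_result`: a list with `scores`
#'   (tibble: alternative, d_plus, d_minus, closeness, rank, tied),
#'   `normalized` and `weighted` matrices, `a_plus`, `a_minus`,
#'   `ranking`, and `weights`.
#' @examples
#' m <- gen_paper_like_matrix("low")
#' res <- topsis(m)
#' tidy(res)
#' @export
topsis <- function(data, criteria = NULL,
                   weight_method = c("centroid", "weighted_mode")) {
  weight_method <- match.arg(weight_method)
  if (is.null(criteria)) criteria <- imaging_criteria()
  criteria <- validate_criteria(criteria)

  crisp <- defuzzify_matrix(data, criteria, method = weight_method)
  X <- as.matrix(crisp[, -1, drop = FALSE])
  rownames(X) <- crisp$alternative

  weights <- fuzzy_weights(criteria$weight_label, method = weight_method)
  N <- normalize_columns(X)
  V <- sweep(N, 2, weights, `*`)

  benefit <- criteria$direction == "benefit"
  a_plus <- ifelse(benefit, apply(V, 2, max), apply(V, 2, min))
  a_minus <- ifelse(benefit, apply(V, 2, min), apply(V, 2, max))

  d_plus <- sqrt(rowSums(sweep(V, 2, a_plus)^2))
  d_minus <- sqrt(rowSums(sweep(V, 2, a_minus)^2))
  closeness <- closeness_coefficient(d_plus, d_minus)

  ord <- order(-closeness)  # stable: ties keep input order
  rank_of <- integer(length(ord)); rank_of[ord] <- seq_along(ord)
  tied <- vapply(seq_along(closeness), function(i) {
    any(abs(closeness[-i] - closeness[i]) <= 1e-12)
  }, logical(1))

  structure(
    list(
      scores = tibble::tibble(
        alternative = crisp$alternative,
        d_plus = unname(d_plus),
        d_minus = unname(d_minus),
        closeness = unname(closeness),
        rank = rank_of,
        tied = tied
      ),
      normalized = N,
      weighted = V,
      a_plus = stats::setNames(a_plus, criteria$criterion),
      a_minus = stats::setNames(a_minus, criteria$criterion),
      ranking = crisp$alternative[ord],
      weights = stats::setNames(weights, criteria$criterion),
      weight_method = weight_method
    ),
    class = "topsis_result"
  )
}

# Vector normalization: each column divided by its Euclidean norm.
normalize_columns <- function(X) {
  norms <- sqrt(colSums(X^2))
  zero <- norms == 0
  if (any(zero)) {
    rlang::abort(paste0(
      "Criterion column(s) entirely zero cannot be vector-normalized: ",
      paste(colnames(X)[zero], collapse = ", "), "."
    ))
  }
  sweep(X, 2, norms, `/`)
}

#' Relative closeness to the positive ideal
#'
#' `R = d_minus / (d_minus + d_plus)`, the TOPSIS closeness coefficient:
#' 1 for an alternative coinciding with the positive ideal, 0 for one
#' coinciding with the negative ideal.
#'
#' @param d_plus,d_minus Non-negative Euclidean distances to the positive
#'   and negative ideal solutions.
#' @return Numeric vector of closeness coefficients in `[0, 1]`.
#' @examples
#' closeness_coefficient(0.0946, 0.1561)  # 0.6227 at 4 decimals
#' @export
closeness_coefficient <- function(d_plus, d_minus) {
  if (any(d_plus < 0) || any(d_minus < 0)) {
    rlang::abort("Distances must be non-negative.")
  }
  denom <- d_plus + d_minus
  if (any(denom == 0)) {
    rlang::abort(paste0(
      "Alternative(s) at zero distance from both ideals (degenerate ",
      "matrix); closeness is undefined for index: ",
      paste(which(denom == 0), collapse = ", "), "."
    ))
  }
  d_minus / denom
}

#' @export
print.topsis_result <- function(x, ...) {
  cat("TOPSIS closeness analysis\n")
  cat("Ranking (by closeness):", paste(x$ranking, collapse = " > "), "\n\n")
  print(round_half_even(x$scores, 4))
  invisible(x)
}

#' Tidy the scores of a TOPSIS result
#'
#' @param x A `topsis_result`.
#' @param ... Unused.
#' @return Tibble with one row per alternative: `alternative`, `d_plus`,
#'   `d_minus`, `closeness`, `rank`, `tied`.
#' @export
tidy.topsis_result <- function(x, ...) x$scores

#' One-row summary of a TOPSIS result
#'
#' @inheritParams tidy.topsis_result
#' @return Tibble with `n_alternatives`, `n_criteria`, `top`,
#'   `closeness_top`, `n_tied`.
#' @export
glance.topsis_result <- function(x, ...) {
  tibble::tibble(
    n_alternatives = nrow(x$scores),
    n_criteria = length(x$weights),
    top = x$ranking[1],
    closeness_top = max(x$scores$closeness),
    n_tied = sum(x$scores$tied)
  )
}

#' Plot TOPSIS closeness coefficients
#'
#' @param object A `topsis_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topsis_result <- function(object, ...) {
  scores <- object$scores |>
    dplyr::mutate(alternative = stats::reorder(.data$alternative,
                                               -.data$rank))
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$alternative,
                               y = .data$closeness)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "closeness coefficient R",
                  title = "TOPSIS relative closeness to the ideal") +
    ggplot2::theme_minimal()
}
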