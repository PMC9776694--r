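#' Appendicitis Inflammatory Response (AIR) score
#'
#' Scores each patient row on the seven AIR items and attaches the per-item
#' points, the 0-12 total, the probability category, and the binary stratum
#' used by the imaging scenarios.
#'
#' Point scheme: vomiting 1; right-lower-quadrant pain 1; rebound tenderness
#' low/mild/severe 1/2/3; body temperature > 38.5 C 1; polymorphonuclear
#' fraction 70-84.99% 1 or >= 85% 2; white cell count 10.0-14.9 (x10^9/L) 1
#' or >= 15.0 2; CRP 10-49 (g/L) 1 or >= 50 2. The printed bands leave small
#' gaps (84-85%, 14.9-15.0, 49-50); these are closed with half-open bands
#' `[70, 85)`, `[10, 15)`, `[10, 50)`, which changes no printed category.
#' Totals 0-4 are low probability, 5-8 mild, 9-12 high. The scenario
#' stratum is `low` for scores below 6 and `high` for 6 and above.
#'
#' @param data A data frame with one row per patient and columns
#'   `vomiting` (logical or 0/1), `rlq_pain` (logical or 0/1), `rebound`
#'   (one of `"none"`, `"low"`, `"mild"`, `"severe"`), `temperature_c`
#'   (degrees Celsius, 30-45), `pnl_percent` (0-100), `wbc_count`
#'   (x10^9/L, >= 0), `crp` (g/L, >= 0). Extra columns pass through.
#' @return The input as a tibble with appended integer point columns
#'   (`pts_vomiting`, `pts_rlq_pain`, `pts_rebound`, `pts_temperature`,
#'   `pts_pnl`, `pts_wbc`, `pts_crp`), `air_score`, `air_category`
#'   (`low`/`mild`/`high`) and `air_stratum` (`low`/`high`).
#' @examples
#' pts <- tibble::tibble(
#'   vomiting = c(TRUE, FALSE), rlq_pain = c(TRUE, FALSE),
#'   rebound = c("severe", "none"), temperature_c = c(39.1, 37.0),
#'   pnl_percent = c(88, 60), wbc_count = c(16, 8), crp = c(60, 4)
#' )
#' air_score(pts)
#' @export
air_score <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("vomiting", "rlq_pain", "rebound", "temperature_c",
              "pnl_percent", "wbc_count", "crp")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Missing cohort column(s): ",
                        paste(missing_cols, collapse = ", "), "."))
  }

  rebound <- tolower(as.character(data$rebound))
  check_air_inputs(data, rebound)

  data |>
    dplyr::mutate(
      pts_vomiting = as.integer(as.logical(.data$vomiting)),
      pts_rlq_pain = as.integer(as.logical(.data$rlq_pain)),
      pts_rebound = unname(c(none = 0L, low = 1L, mild = 2L,
                             severe = 3L)[rebound]),
      pts_temperature = as.integer(.data$temperature_c > 38.5),
      pts_pnl = dplyr::case_when(
        .data$pnl_percent >= 85 ~ 2L,
        .data$pnl_percent >= 70 ~ 1L,
        TRUE ~ 0L
      ),
      pts_wbc = dplyr::case_when(
        .data$wbc_count >= 15 ~ 2L,
        .data$wbc_count >= 10 ~ 1L,
        TRUE ~ 0L
      ),
      pts_crp = dplyr::case_when(
        .data$crp >= 50 ~ 2L,
        .data$crp >= 10 ~ 1L,
        TRUE ~ 0L
      ),
      air_score = .data$pts_vomiting + .data$pts_rlq_pain +
        .data$pts_rebound + .data$pts_temperature + .data$pts_pnl +
        .data$pts_wbc + .data$pts_crp,
      air_category = air_category(.data$air_score),
      air_stratum = air_stratum(.data$air_score)
    )
}

check_air_inputs <- function(data, rebound) {
  bad_reb <- !rebound %in% c("none", "low", "mild", "severe")
  if (any(bad_reb)) {
    rlang::abort(paste0(
      "Invalid `rebound` value(s) in row(s) ",
      paste(which(bad_reb), collapse = ", "),
      ": must be one of none, low, mild, severe."
    ))
  }
  range_check <- function(x, lo, hi, name) {
    bad <- is.na(x) | x < lo | x > hi
    if (any(bad)) {
      rlang::abort(sprintf(
        "`%s` out of range [%g, %g] in row(s) %s.",
        name, lo, hi, paste(which(bad), collapse = ", ")
      ))
    }
  }
  range_check(data$temperature_c, 30, 45, "temperature_c")
  range_check(data$pnl_percent, 0, 100, "pnl_percent")
  range_check(data$wbc_count, 0, Inf, "wbc_count")
  range_check(data$crp, 0, Inf, "crp")
  invisible(TRUE)
}

#' Map an AIR score to its probability category
#'
#' @param score Integer vector of AIR scores in 0-12.
#' @return Factor with levels `low` (0-4), `mild` (5-8), `high` (9-12).
#' @examples
#' air_category(c(4, 5, 9))
#' @export
air_category <- function(score) {
  if (any(is.na(score) | score < 0 | score > 12 | score != round(score))) {
    rlang::abort("AIR scores must be integers in [0, 12].")
  }
  cut(score, breaks = c(-0.5, 4.5, 8.5, 12.5),
      labels = c("low", "mild", "high"))
}

#' Binary AIR stratum for the imaging scenarios
#'
#' The imaging scenarios split patients at a score of 6: `low` below 6,
#' `high` at 6 and above (the boundary value itself is assigned to `high`;
#' see the methods vignette).
#'
#' @inheritParams air_category
#' @return Factor with levels `low`, `high`.
#' @examples
#' air_stratum(c(5, 6, 7))
#' @export
air_stratum <- function(score) {
  if (any(is.na(score) | score < 0 | score > 12)) {
    rlang::abort("AIR scores must lie in [0, 12].")
  }
  factor(ifelse(score < 6, "low", "high"), levels = c("low", "high"))
}
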