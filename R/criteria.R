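#' Default imaging-criteria configuration
#'
#' The twelve criteria on which the imaging modalities are judged, with
#' their linguistic importance labels and optimization directions:
#' specificity, diagnostic precision, time of imaging, user dependency,
#' radiation dose and comfortability are weighted VH; sensitivity, air
#' score and disposition H; time of order, result time and cost M.
#'
#' Directions are the package defaults (benefit = larger is better):
#' accuracy measures, comfortability, air-score suitability and
#' disposition are benefits; times, cost, user dependency and radiation
#' dose are costs. Both the labels and the directions are plain tibble
#' columns, so they can be edited before running an analysis.
#'
#' @param weight_method Yager index used when the weights are defuzzified
#'   downstream; stored as an attribute for provenance only.
#' @return A tibble with columns `criterion`, `direction` (`benefit` or
#'   `cost`), `weight_label` and `preference_s` (`NA` = automatic Gaussian
#'   shape parameter).
#' @examples
#' imaging_criteria()
#' @export
imaging_criteria <- function(weight_method = c("centroid", "weighted_mode")) {
  weight_method <- match.arg(weight_method)
  out <- tibble::tibble(
    criterion = c(
      "specificity", "diagnostic precision", "time of imaging",
      "user dependency", "radiation dose", "comfortability",
      "sensitivity", "air score", "disposition",
      "time of order", "result time", "cost"
    ),
    direction = c(
      "benefit", "benefit", "cost",
      "cost", "cost", "benefit",
      "benefit", "benefit", "benefit",
      "cost", "cost", "cost"
    ),
    weight_label = c(rep("VH", 6), rep("H", 3), rep("M", 3)),
    preference_s = NA_real_
  )
  attr(out, "weight_method") <- weight_method
  out
}

# Aliases accepted for criterion names in configuration files; the prose
# descriptions of the criteria differ slightly from the canonical table.
criterion_aliases <- function() {
  c(
    "imaging time"        = "time of imaging",
    "duration of the examination" = "time of imaging",
    "easy applicability"  = "comfortability",
    "fee"                 = "cost",
    "treatment cost"      = "cost",
    "request duration"    = "time of order",
    "request time"        = "time of order",
    "time to result"      = "result time",
    "radiation exposure"  = "radiation dose",
    "radiation exposure level" = "radiation dose"
  )
}

canonicalize_criterion <- function(name) {
  name <- tolower(trimws(name))
  ali <- criterion_aliases()
  ifelse(name %in% names(ali), unname(ali[name]), name)
}

validate_criteria <- function(criteria) {
  criteria <- tibble::as_tibble(criteria)
  needed <- c("criterion", "direction", "weight_label")
  missing_cols <- setdiff(needed, names(criteria))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Criteria table lacks column(s): ",
                        paste(missing_cols, collapse = ", "), "."))
  }
  if (!"preference_s" %in% names(criteria)) criteria$preference_s <- NA_real_
  criteria$criterion <- canonicalize_criterion(criteria$criterion)
  if (anyDuplicated(criteria$criterion)) {
    rlang::abort("Criteria names must be unique.")
  }
  bad_dir <- setdiff(unique(criteria$direction), c("benefit", "cost"))
  if (length(bad_dir) > 0) {
    rlang::abort(paste0(
      "Invalid criterion direction(s): ", paste(bad_dir, collapse = ", "),
      ". Use \"benefit\" or \"cost\"."
    ))
  }
  bad_s <- !is.na(criteria$preference_s) & criteria$preference_s <= 0
  if (any(bad_s)) {
    rlang::abort(paste0(
      "`preference_s` must be positive (or NA for automatic) for: ",
      paste(criteria$criterion[bad_s], collapse = ", "), "."
    ))
  }
  # validates the labels
  defuzzify_label(criteria$weight_label)
  criteria
}
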