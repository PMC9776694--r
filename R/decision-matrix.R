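#' Validate a decision matrix
#'
#' A decision matrix is a tibble whose first column, `alternative`, names
#' the options being ranked; every other column is a criterion whose cells
#' are either crisp numbers or linguistic labels (`VL`...`VH`). Cells may
#' mix the two styles within a column.
#'
#' @param data Data frame with an `alternative` column and one column per
#'   criterion.
#' @param criteria Optional criteria tibble (see [imaging_criteria()]);
#'   when supplied, matrix columns must match `criteria$criterion` exactly
#'   (order included).
#' @return The validated tibble (invisibly unchanged).
#' @export
validate_matrix <- function(data, criteria = NULL) {
  data <- tibble::as_tibble(data)
  if (!"alternative" %in% names(data)) {
    rlang::abort("A decision matrix needs an `alternative` column.")
  }
  if (names(data)[1] != "alternative") {
    data <- dplyr::relocate(data, "alternative")
  }
  if (nrow(data) < 2) {
    rlang::abort("A decision matrix needs at least 2 alternatives.")
  }
  if (ncol(data) < 2) {
    rlang::abort("A decision matrix needs at least 1 criterion column.")
  }
  if (anyDuplicated(data$alternative)) {
    dup <- unique(data$alternative[duplicated(data$alternative)])
    rlang::abort(paste0("Duplicate alternative name(s): ",
                        paste(dup, collapse = ", "), "."))
  }
  for (col in setdiff(names(data), "alternative")) {
    cells <- data[[col]]
    for (i in seq_along(cells)) {
      parsed <- parse_cell(cells[i])
      if (is.na(parsed)) {
        rlang::abort(paste0(
          "Invalid cell at alternative \"", data$alternative[i],
          "\", criterion \"", col, "\": \"", as.character(cells[i]),
          "\". Cells must be numeric or one of ",
          paste(linguistic_labels(), collapse = ", "), "."
        ))
      }
    }
  }
  if (!is.null(criteria)) {
    criteria <- validate_criteria(criteria)
    mat_crit <- canonicalize_criterion(setdiff(names(data), "alternative"))
    if (!identical(mat_crit, criteria$criterion)) {
      rlang::abort(paste0(
        "Matrix criteria do not match the configuration.\n",
        "  matrix: ", paste(mat_crit, collapse = ", "), "\n",
        "  config: ", paste(criteria$criterion, collapse = ", ")
      ))
    }
  }
  data
}

# One cell -> defuzzified crisp value, or NA if unparseable. Crisp cells
# are degenerate TFNs (x, x, x), so a single defuzzification path serves
# the whole matrix.
parse_cell <- function(cell, method = "centroid") {
  if (is.numeric(cell)) return(as.numeric(cell))
  chr <- toupper(trimws(as.character(cell)))
  if (length(chr) != 1 || is.na(chr) || chr == "") return(NA_real_)
  num <- suppressWarnings(as.numeric(chr))
  if (!is.na(num)) return(num)
  if (chr %in% linguistic_labels()) {
    return(defuzzify_label(chr, method = method))
  }
  NA_real_
}

#' Defuzzify a decision matrix to crisp values
#'
#' Linguistic cells are mapped through the five-level TFN scale and the
#' Yager index; crisp cells pass through unchanged (they are degenerate
#' TFNs). The result feeds both ranking engines identically.
#'
#' @inheritParams validate_matrix
#' @inheritParams yager_index
#' @return A tibble with `alternative` plus numeric criterion columns.
#' @examples
#' m <- tibble::tibble(alternative = c("a", "b"),
#'                     sensitivity = c(90, "H"), cost = c("M", "L"))
#' defuzzify_matrix(m)
#' @export
defuzzify_matrix <- function(data, criteria = NULL,
                             method = c("centroid", "weighted_mode")) {
  method <- match.arg(method)
  data <- validate_matrix(data, criteria)
  crit_cols <- setdiff(names(data), "alternative")
  data |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(crit_cols),
      function(col) purrr::map_dbl(col, parse_cell, method = method)
    ))
}
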