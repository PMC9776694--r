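#' Read a decision matrix from CSV
#'
#' Expects a header row of criterion names with the first column named
#' `alternative`; cells are crisp numbers or linguistic labels
#' (case-insensitive on input, canonical uppercase in memory). The file
#' round-trips with [write_matrix_csv()].
#'
#' @param path CSV file path.
#' @return A validated decision matrix tibble.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Matrix file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"alternative" %in% names(raw)) names(raw)[1] <- "alternative"
  out <- validate_matrix(raw)
  crit_cols <- setdiff(names(out), "alternative")
  out |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(crit_cols),
      function(col) {
        num <- suppressWarnings(as.numeric(col))
        if (all(!is.na(num))) num else {
          ifelse(is.na(num), toupper(trimws(col)), col)
        }
      }
    ))
}

#' Write a decision matrix to CSV
#'
#' @param data Decision matrix tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(data, path) {
  data <- validate_matrix(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a patient cohort from CSV
#'
#' Columns: `vomiting`, `rlq_pain` (logical or 0/1), `rebound`,
#' `temperature_c`, `pnl_percent`, `wbc_count`, `crp`; extra columns pass
#' through.
#'
#' @param path CSV file path.
#' @return A tibble ready for [air_score()].
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Cohort file not found: ", path))
  }
  readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
}

#' Score a cohort CSV and write the result
#'
#' Reads the cohort, appends the per-item points, the AIR score, the
#' probability category and the binary stratum, and writes the scored
#' table.
#'
#' @param in_path Input cohort CSV.
#' @param out_path Output CSV.
#' @return The scored tibble, invisibly.
#' @export
score_cohort_csv <- function(in_path, out_path) {
  scored <- air_score(read_cohort_csv(in_path))
  readr::write_csv(scored, out_path, progress = FALSE)
  invisible(scored)
}

#' Read a scenario configuration from JSON or YAML
#'
#' Missing fields fall back to the package defaults ([imaging_criteria()],
#' the five imaging alternatives), so an empty configuration file yields
#' the default scenario. Criteria entries may override any of
#' `direction`, `weight_label`, `preference_s` per criterion name (prose
#' aliases accepted).
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Config file not found: ", path))
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    rlang::abort("Config must be a .json, .yaml or .yml file.")
  }
  if (is.null(cfg)) cfg <- list()
  known <- c("stratum", "criteria", "alternatives", "merge_identical",
             "weight_method", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown config field(s): ",
                        paste(unknown, collapse = ", "), "."))
  }

  criteria <- imaging_criteria()
  if (!is.null(cfg$criteria)) {
    for (entry in cfg$criteria) {
      if (is.null(entry$criterion)) {
        rlang::abort("Each criteria entry needs a `criterion` name.")
      }
      nm <- canonicalize_criterion(entry$criterion)
      idx <- match(nm, criteria$criterion)
      if (is.na(idx)) {
        criteria <- dplyr::bind_rows(criteria, tibble::tibble(
          criterion = nm,
          direction = entry$direction %||% "benefit",
          weight_label = toupper(entry$weight_label %||% "M"),
          preference_s = as.numeric(entry$preference_s %||% NA_real_)
        ))
      } else {
        if (!is.null(entry$direction)) criteria$direction[idx] <- entry$direction
        if (!is.null(entry$weight_label)) {
          criteria$weight_label[idx] <- toupper(entry$weight_label)
        }
        if (!is.null(entry$preference_s)) {
          criteria$preference_s[idx] <- as.numeric(entry$preference_s)
        }
      }
    }
  }

  scenario_config(
    stratum = cfg$stratum %||% "low",
    criteria = criteria,
    alternatives = unlist(cfg$alternatives) %||%
      c("US", "CT non-contrast", "CT contrast", "MRI 1.5T", "MRI 3T"),
    merge_identical = cfg$merge_identical %||% TRUE,
    weight_method = cfg$weight_method %||% "centroid",
    seed = cfg$seed %||% 1
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Serializable representation of a scenario report (stable field order,
# full precision; deterministic for fixed inputs and seed).
report_as_list <- function(report) {
  stopifnot(inherits(report, "scenario_report"))
  cfg <- report$config
  list(
    scenario = cfg$stratum,
    criteria = lapply(seq_len(nrow(cfg$criteria)), function(i) {
      list(
        name = cfg$criteria$criterion[i],
        direction = cfg$criteria$direction[i],
        weight_label = cfg$criteria$weight_label[i],
        weight = unname(report$promethee$weights[i])
      )
    }),
    promethee = list(
      phi_plus = as.list(stats::setNames(report$promethee$flows$phi_plus,
                                         report$promethee$flows$alternative)),
      phi_minus = as.list(stats::setNames(report$promethee$flows$phi_minus,
                                          report$promethee$flows$alternative)),
      phi_net = as.list(stats::setNames(report$promethee$flows$phi_net,
                                        report$promethee$flows$alternative)),
      ranking = report$ranking$promethee,
      relations = lapply(seq_len(nrow(report$promethee$relations)),
                         function(i) as.list(report$promethee$relations[i, ]))
    ),
    topsis = list(
      d_plus = as.list(stats::setNames(report$topsis$scores$d_plus,
                                       report$topsis$scores$alternative)),
      d_minus = as.list(stats::setNames(report$topsis$scores$d_minus,
                                        report$topsis$scores$alternative)),
      closeness = as.list(stats::setNames(report$topsis$scores$closeness,
                                          report$topsis$scores$alternative)),
      ranking = report$ranking$topsis
    ),
    agreement = list(
      kendall_tau = report$agreement$kendall_tau,
      top_match = report$agreement$top_match
    ),
    selfcheck = report$selfcheck,
    provenance = report$provenance
  )
}

#' Write a scenario report to JSON (and optionally a text table)
#'
#' The JSON carries full-precision numbers and is byte-identical across
#' reruns with the same inputs and seed. With `text = TRUE` a plain-text
#' companion (`<path>.txt`) mirrors the familiar ranking tables —
#' `Rank | Alternative | phi_net` for PROMETHEE and
#' `Rank | Alternative | d+ | d- | R` for TOPSIS — with values rounded
#' half-to-even to 4 decimals.
#'
#' @param report A `scenario_report`.
#' @param path Output JSON path.
#' @param text Also write the text tables (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, text = FALSE) {
  obj <- report_as_list(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (text) {
    writeLines(report_text_tables(report), paste0(path, ".txt"))
  }
  invisible(path)
}

report_text_tables <- function(report) {
  prom <- report$promethee$flows |>
    dplyr::arrange(.data$rank) |>
    round_half_even(4)
  tops <- report$topsis$scores |>
    dplyr::arrange(.data$rank) |>
    round_half_even(4)
  c(
    sprintf("PROMETHEE ranking (%s AIR stratum)", report$config$stratum),
    "Rank | Alternative | phi_net",
    sprintf("%4d | %-15s | %7.4f", prom$rank, prom$alternative,
            prom$phi_net),
    "",
    sprintf("TOPSIS ranking (%s AIR stratum)", report$config$stratum),
    "Rank | Alternative | d+ | d- | R",
    sprintf("%4d | %-15s | %6.4f | %6.4f | %6.4f", tops$rank,
            tops$alternative, tops$d_plus, tops$d_minus, tops$closeness)
  )
}

#' Read a scenario report back from JSON
#'
#' @param path JSON path written by [write_report()].
#' @return The parsed report list (not a `scenario_report` object).
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
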