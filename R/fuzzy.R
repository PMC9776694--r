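#' The five-level linguistic fuzzy scale
#'
#' Triangular fuzzy numbers (TFNs) attached to the five linguistic labels
#' used for expert judgments: VL (very low), L (low), M (medium), H (high)
#' and VH (very high). Each TFN `(left, mode, right)` has membership 0
#' outside `[left, right]`, 1 at `mode`, and is linear in between.
#'
#' @return A tibble with columns `label`, `left`, `mode`, `right`.
#' @examples
#' linguistic_scale()
#' @export
linguistic_scale <- function() {
  tibble::tibble(
    label = c("VL", "L", "M", "H", "VH"),
    left  = c(0.00, 0.00, 0.25, 0.50, 0.75),
    mode  = c(0.00, 0.25, 0.50, 0.75, 1.00),
    right = c(0.25, 0.50, 0.75, 1.00, 1.00)
  )
}

linguistic_labels <- function() c("VL", "L", "M", "H", "VH")

#' Convert linguistic labels to triangular fuzzy numbers
#'
#' @param label Character vector of linguistic labels (`VL`, `L`, `M`, `H`,
#'   `VH`); case-insensitive.
#' @return A tibble with one row per input label and columns `label`,
#'   `left`, `mode`, `right`.
#' @examples
#' linguistic_to_tfn(c("VH", "M"))
#' @export
linguistic_to_tfn <- function(label) {
  lab <- toupper(trimws(as.character(label)))
  bad <- setdiff(unique(lab), linguistic_labels())
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "Unknown linguistic label(s): ", paste(bad, collapse = ", "),
      ". Valid labels are: ", paste(linguistic_labels(), collapse = ", "), "."
    ))
  }
  scale <- linguistic_scale()
  scale[match(lab, scale$label), ]
}

#' Defuzzify triangular fuzzy numbers with a Yager ranking index
#'
#' Collapses TFNs to crisp representatives. The default `"centroid"` index
#' is the centroid of the triangular membership function,
#' `(left + mode + right) / 3`; `"weighted_mode"` is the mode-weighted
#' variant `(left + 2 mode + right) / 4`, exposed for sensitivity checks.
#' Both are translation-equivariant and reduce to the crisp value on
#' degenerate TFNs `(x, x, x)`.
#'
#' @param left,mode,right Numeric vectors (recycled) with
#'   `left <= mode <= right`.
#' @param method `"centroid"` (default) or `"weighted_mode"`.
#' @return Numeric vector of crisp values, each within `[left, right]`.
#' @examples
#' yager_index(0.75, 1, 1)           # 0.91667
#' yager_index(0.25, 0.5, 0.75)      # symmetric: equals the mode
#' @export
yager_index <- function(left, mode, right,
                        method = c("centroid", "weighted_mode")) {
  method <- match.arg(method)
  n <- max(length(left), length(mode), length(right))
  left  <- rep_len(as.numeric(left), n)
  mode  <- rep_len(as.numeric(mode), n)
  right <- rep_len(as.numeric(right), n)
  if (any(is.na(left) | is.na(mode) | is.na(right))) {
    rlang::abort("TFN components must be non-missing numbers.")
  }
  if (any(left > mode | mode > right)) {
    rlang::abort("Invalid TFN: require left <= mode <= right.")
  }
  switch(method,
    centroid      = (left + mode + right) / 3,
    weighted_mode = (left + 2 * mode + right) / 4
  )
}

#' Defuzzify a linguistic label vector to a crisp value per label
#'
#' @param label Character vector of linguistic labels.
#' @inheritParams yager_index
#' @return Numeric vector of defuzzified values.
#' @examples
#' defuzzify_label(c("VL", "L", "M", "H", "VH"))
#' @export
defuzzify_label <- function(label, method = c("centroid", "weighted_mode")) {
  method <- match.arg(method)
  tfn <- linguistic_to_tfn(label)
  yager_index(tfn$left, tfn$mode, tfn$right, method = method)
}

#' Crisp, normalized criterion weights from linguistic importance labels
#'
#' Maps each label to its TFN, defuzzifies with a Yager index, and
#' normalizes the resulting vector to sum to 1 (required so that both the
#' PROMETHEE preference index and the TOPSIS weighted matrix use a proper
#' weight vector).
#'
#' @param weight_label Character vector of linguistic importance labels,
#'   one per criterion.
#' @inheritParams yager_index
#' @return Numeric weight vector, componentwise `>= 0`, summing to 1.
#' @examples
#' fuzzy_weights(c("VH", "VL"))
#' fuzzy_weights(c("H", "H", "H"))
#' @export
fuzzy_weights <- function(weight_label,
                          method = c("centroid", "weighted_mode")) {
  method <- match.arg(method)
  if (length(weight_label) == 0) {
    rlang::abort("At least one weight label is required.")
  }
  w <- defuzzify_label(weight_label, method = method)
  total <- sum(w)
  if (total <= 0) {
    rlang::abort("Weight labels defuzzify to a zero total; cannot normalize.")
  }
  w / total
}
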