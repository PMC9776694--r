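# Display rounding: half-to-even at `digits` decimals on every numeric
# column (base round() implements IEC 60559 banker's rounding).
round_half_even <- function(df, digits = 4) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  function(x) round(x, digits)))
}

#' @importFrom rlang .data :=
NULL

#' @keywords internal
"_PACKAGE"
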