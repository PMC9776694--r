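# All combinations of AIR item severity levels, one row each, with
# representative measurement values for every band.
air_lattice <- function() {
  tidyr::expand_grid(
    vomiting = c(FALSE, TRUE),
    rlq_pain = c(FALSE, TRUE),
    rebound = c("none", "low", "mild", "severe"),
    temp_lvl = 0:1, pnl_lvl = 0:2, wbc_lvl = 0:2, crp_lvl = 0:2
  ) |>
    dplyr::mutate(
      temperature_c = c(37.0, 39.0)[temp_lvl + 1],
      pnl_percent = c(60, 75, 90)[pnl_lvl + 1],
      wbc_count = c(8, 12, 16)[wbc_lvl + 1],
      crp = c(5, 30, 60)[crp_lvl + 1]
    )
}
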