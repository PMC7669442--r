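# Benchmark summary statistics of the free-living ring/watch validation
# study that the simulator defaults are calibrated to. Raw per-night data
# were never deposited, so derived statistics (limits of agreement, t
# statistics, coverage percentages) are recomputed from these printed
# summaries rather than from raw inputs.

#' Benchmark agreement summaries for the ring and watch
#'
#' Per device and parameter: the number of matched nights, the mean
#' (reference-minus-device) difference, and the SD of the differences, plus
#' the satisfactory-range counts where reported. These are the same values
#' that parameterise the default [sim_config()] (with the bias sign flipped
#' to device-minus-truth).
#'
#' @return A list of tibbles: `agreement` (device, parameter, n, bias,
#'   sd_diff, n_within, loa printed by the benchmark study), and
#'   `gender_tst` (per-gender mean/sd/n of ring TST differences).
#' @export
reference_summaries <- function() {
  agreement <- tibble(
    device = rep(c("ring", "watch"), each = 4),
    parameter = rep(c("tst", "se", "waso", "sol"), 2),
    n = c(rep(266L, 4), rep(134L, 4)),
    bias = c(-15.27, 1.34, 17.41, -11.93,
             -22.51, -4.44, 31.27, -12.81),
    sd_diff = c(39.68, 5.91, 28.24, 14.92,
                73.24, 7.88, 35.15, 14.65),
    n_within = c(173L, 175L, 186L, NA_integer_,
                 52L, 57L, 61L, NA_integer_)
  )
  gender_tst <- tibble(
    group = c("F", "M"),
    mean = c(-12.98, -17.84),
    sd = c(37.94, 41.39),
    n = c(141L, 125L)
  )
  list(agreement = agreement, gender_tst = gender_tst)
}
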