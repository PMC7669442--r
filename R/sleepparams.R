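# Nonstaging sleep parameters per night, unified across devices.
#
# NightParams rows carry: subject, night (noon-to-noon frame), device
# ("actigraphy" / "ring" / "watch"), tib, tst, waso, sol (minutes; sol may be
# NA), se (percent), and for actigraphy a sol_low_confidence flag (actigraphy
# onset latency is known to be unreliable and is segregated in reporting).

night_params_row <- function(subject, night, device, tib, tst, waso, se,
                             sol = NA_real_, sol_low_confidence = FALSE) {
  tibble(subject = subject, night = night, device = device,
         tib = tib, tst = tst, waso = waso, se = se, sol = sol,
         sol_low_confidence = sol_low_confidence)
}

#' Compute actigraphy sleep parameters for one sleep period
#'
#' Sleep onset is the first epoch of the first run of at least `onset_run`
#' consecutive SLEEP epochs inside the period; the final wake is the end of
#' the last SLEEP epoch. Then TST is the SLEEP minutes and WASO the WAKE
#' minutes inside `[onset, final wake]`, TIB is the period length, SE is
#' `100 * TST / TIB`, and SOL is `onset - period start`. The minute
#' accounting `SOL + TST + WASO + terminal wake = TIB` holds exactly.
#'
#' Actigraphy onset latency is computed but flagged `sol_low_confidence` so
#' that reporting can segregate it.
#'
#' @param period One row of [detect_sleep_periods()] output.
#' @param labels Scored epochs ([cole_kripke_score()]) covering the period.
#' @param onset_run Consecutive SLEEP epochs defining onset (default 5).
#' @return A one-row NightParams tibble, or `NULL` (with a warning) when the
#'   period contains no qualifying sleep onset.
#' @export
actigraphy_night_params <- function(period, labels, onset_run = 5) {
  stopifnot(nrow(period) == 1)
  ep <- as.numeric(labels$time[2]) - as.numeric(labels$time[1])
  in_period <- labels$time >= period$start & labels$time < period$end
  st <- labels$state[in_period]
  n <- length(st)
  if (n == 0 || !any(st == "SLEEP")) {
    warning("period on night ", period$night, " has no sleep epochs; dropped",
            call. = FALSE)
    return(NULL)
  }
  r <- rle(st == "SLEEP")
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  ok <- which(r$values & r$lengths >= onset_run)
  if (length(ok) == 0) {
    warning("period on night ", period$night, " has no run of ", onset_run,
            " consecutive sleep epochs; dropped", call. = FALSE)
    return(NULL)
  }
  onset_i <- run_start[ok[1]]
  final_i <- max(which(st == "SLEEP"))
  window <- st[onset_i:final_i]
  tst <- sum(window == "SLEEP") * ep / 60
  waso <- sum(window == "WAKE") * ep / 60
  tib <- n * ep / 60
  night_params_row(
    subject = period$subject, night = period$night, device = "actigraphy",
    tib = tib, tst = tst, waso = waso, se = 100 * tst / tib,
    sol = (onset_i - 1L) * ep / 60, sol_low_confidence = TRUE
  )
}

#' Run the full actigraphy pipeline over a study's epoch counts
#'
#' Per subject: Cole-Kripke scoring, Troiano nonwear detection, sleep-period
#' detection, log-based cleaning, and per-night parameter extraction. When a
#' night holds several periods the longest is kept as the main sleep period
#' (shorter ones are typically naps removed by the daytime rule anyway).
#'
#' @param counts Epoch counts for any number of subjects (`subject`, `time`,
#'   `count`).
#' @param logs Daily logs (see [clean_sleep_periods()]).
#' @param study_window Length-2 `Date` vector of first/last night; defaults
#'   to the range of nights present in `counts`.
#' @param weights A [ck_weights()] object.
#' @param onset_run,min_zero_run,spike_tolerance,spike_ceiling,merge_gap
#'   Tuning parameters passed through to the stage functions.
#' @return A NightParams tibble (device `"actigraphy"`).
#' @export
actigraphy_nights <- function(counts, logs = NULL, study_window = NULL,
                              weights = ck_weights(), onset_run = 5,
                              min_zero_run = 60, spike_tolerance = 2,
                              spike_ceiling = 100, merge_gap = 60) {
  if (is.null(study_window)) {
    study_window <- range(night_date(counts$time))
  }
  if (is.null(logs)) {
    logs <- list(reports = tibble(subject = unique(counts$subject),
                                  date = study_window[1]),
                 removals = tibble(subject = character(),
                                   start = as.POSIXct(character(), tz = "UTC"),
                                   end = as.POSIXct(character(), tz = "UTC")))
  }
  out <- lapply(split(counts, counts$subject), function(series) {
    series <- series[order(series$time), , drop = FALSE]
    labels <- cole_kripke_score(series, weights)
    bouts <- detect_nonwear(series, min_zero_run, spike_tolerance,
                            spike_ceiling)
    periods <- detect_sleep_periods(labels, bouts, merge_gap = merge_gap)
    periods <- clean_sleep_periods(periods, logs, study_window)
    if (nrow(periods) == 0) return(NULL)
    # keep the longest period per night as the main sleep period
    periods <- dplyr::slice_max(dplyr::group_by(periods, .data$night),
                                .data$n_epochs, n = 1, with_ties = FALSE)
    periods <- dplyr::ungroup(periods)
    rows <- lapply(seq_len(nrow(periods)), function(k) {
      actigraphy_night_params(periods[k, ], labels, onset_run)
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}
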