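# Actigraphy baseline: epoch scoring, wear-time detection, sleep-period
# detection and log-based cleaning.

#' Cole-Kripke scoring weights (1-minute epochs)
#'
#' The canonical 1-minute-epoch coefficients as used by the ActiLife
#' implementation: the epoch score is
#' `scale * sum(weights * counts[t-4 .. t+2] / count_divisor)` and the epoch
#' is scored SLEEP when the score is below `threshold`. `count_divisor`
#' rescales modern wrist-counts to the scale of the device on which the
#' algorithm was derived. Alternative coefficient sets can be injected by
#' constructing a different object.
#'
#' @param scale Scale factor applied to the weighted sum.
#' @param weights Seven window weights for epochs `t-4` to `t+2`
#'   (non-negative).
#' @param threshold Decision threshold; score below it means SLEEP.
#' @param count_divisor Divisor applied to raw counts before weighting.
#' @return An object of class `ck_weights`.
#' @export
#' @examples
#' w <- ck_weights()
#' w$weights
ck_weights <- function(scale = 0.001,
                       weights = c(106, 54, 58, 76, 230, 74, 67),
                       threshold = 1,
                       count_divisor = 100) {
  if (length(weights) != 7 || any(weights < 0)) {
    stop("`weights` must be 7 non-negative values (epochs t-4 .. t+2)",
         call. = FALSE)
  }
  check_scalar(threshold, "threshold", function(v) v > 0)
  check_scalar(scale, "scale", function(v) v > 0)
  check_scalar(count_divisor, "count_divisor", function(v) v > 0)
  structure(list(scale = scale, weights = as.numeric(weights),
                 threshold = threshold, count_divisor = count_divisor),
            class = "ck_weights")
}

check_epoch_series <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("subject", "time", "count") %in% names(series)))
  if (length(unique(series$subject)) > 1) {
    stop("epoch series must contain a single subject", call. = FALSE)
  }
  if (any(series$count < 0)) stop("counts must be non-negative", call. = FALSE)
  dt <- diff(as.numeric(series$time))
  if (length(dt) > 0 && (any(dt <= 0) || length(unique(dt)) > 1)) {
    stop("timestamps must be strictly increasing and uniformly spaced",
         call. = FALSE)
  }
  invisible(series)
}

#' Score actigraphy epochs as sleep or wake (Cole-Kripke)
#'
#' Applies the seven-epoch weighted moving sum to the count series; epochs
#' whose score falls below the threshold are labelled `SLEEP`, the rest
#' `WAKE`. Window positions that fall outside the recording are treated as
#' zero counts, so the output has exactly one label per input epoch.
#'
#' @param series Epoch series tibble (`subject`, `time`, `count`) for one
#'   subject, 60-s spacing, gap-free.
#' @param weights A [ck_weights()] object.
#' @return The input tibble with `score` and `state` (`"SLEEP"`/`"WAKE"`)
#'   columns appended.
#' @export
cole_kripke_score <- function(series, weights = ck_weights()) {
  check_epoch_series(series)
  stopifnot(inherits(weights, "ck_weights"))
  n <- nrow(series)
  if (n < 7) {
    stop("series has ", n, " epochs; at least 7 are required for the ",
         "7-epoch scoring window", call. = FALSE)
  }
  x <- series$count / weights$count_divisor
  xp <- c(rep(0, 4), x, rep(0, 2))
  # row i of embed(xp, 7) is xp[i+6], ..., xp[i]; reversing the weight
  # vector aligns weight w[k] with count x[t - 5 + k], i.e. epochs t-4..t+2
  score <- as.numeric(embed(xp, 7) %*% rev(weights$weights)) * weights$scale
  out <- series
  out$score <- score
  out$state <- ifelse(score < weights$threshold, "SLEEP", "WAKE")
  out
}

#' Detect nonwear bouts (Troiano wear-time validation)
#'
#' Marks maximal runs of zero counts of at least `min_zero_run` minutes as
#' NONWEAR. Following the Troiano rule, a run may be bridged by interruptions
#' of up to `spike_tolerance` consecutive epochs whose counts stay below
#' `spike_ceiling`; a count at or above the ceiling, or a longer
#' interruption, terminates the run. Runs start and end on zero-count epochs.
#' The remainder of the series is WEAR; the returned bouts partition it.
#'
#' @param series Epoch series tibble for one subject.
#' @param min_zero_run Minimum nonwear run length in minutes (default 60).
#' @param spike_tolerance Maximum consecutive interruption epochs bridged
#'   inside a run (default 2).
#' @param spike_ceiling Counts at or above this value always terminate a run
#'   (default 100).
#' @return A tibble of bouts: `subject`, `start`, `end` (POSIXct; `end` is
#'   the end of the last epoch), `kind` (`"WEAR"`/`"NONWEAR"`), `n_epochs`,
#'   `n_nonzero` (nonzero epochs inside the bout), sorted and
#'   non-overlapping.
#' @export
detect_nonwear <- function(series, min_zero_run = 60, spike_tolerance = 2,
                           spike_ceiling = 100) {
  check_epoch_series(series)
  n <- nrow(series)
  ep <- if (n > 1) as.numeric(series$time[2]) - as.numeric(series$time[1]) else 60
  counts <- series$count
  r <- rle(counts > 0)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  ends <- cumsum(r$lengths)
  # zero runs, possibly bridged across short, small-count nonzero runs
  nonwear <- logical(n)
  i <- 1L
  while (i <= length(r$values)) {
    if (!r$values[i]) { # a zero run: try to extend across tolerable spikes
      run_start <- starts[i]
      run_end <- ends[i]
      j <- i
      while (j + 2L <= length(r$values) &&
             r$values[j + 1L] &&
             r$lengths[j + 1L] <= spike_tolerance &&
             all(counts[starts[j + 1L]:ends[j + 1L]] < spike_ceiling)) {
        j <- j + 2L
        run_end <- ends[j]
      }
      if ((run_end - run_start + 1L) * ep / 60 >= min_zero_run) {
        nonwear[run_start:run_end] <- TRUE
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  rr <- rle(nonwear)
  b_start <- cumsum(c(1L, rr$lengths[-length(rr$lengths)]))
  b_end <- cumsum(rr$lengths)
  tibble(
    subject = series$subject[1],
    start = series$time[b_start],
    end = series$time[b_end] + ep,
    kind = ifelse(rr$values, "NONWEAR", "WEAR"),
    n_epochs = rr$lengths,
    n_nonzero = vapply(seq_along(rr$lengths), function(k) {
      sum(counts[b_start[k]:b_end[k]] > 0)
    }, integer(1))
  )
}

#' Detect candidate sleep periods from labels and nonwear bouts
#'
#' Implements the auto-detection rule of the actigraphy baseline: nonwear
#' bouts are candidate sleep time, after discarding bouts longer than a day
#' and bouts that are not almost all zeros (`max_nonzero` = 5 or more nonzero
#' epochs). Candidates separated by no more than `merge_gap` minutes (brief
#' in-bed wake) are merged into one period, and each period is extended
#' across adjacent contiguously SLEEP-labelled epochs. Periods are assigned
#' to the noon-to-noon night containing their midpoint.
#'
#' @param labels Output of [cole_kripke_score()] (one subject).
#' @param bouts Output of [detect_nonwear()] on the same series.
#' @param max_span_hours Candidates longer than this are discarded
#'   (default 24, the "greater than a day" rule).
#' @param max_nonzero Candidates with at least this many nonzero epochs are
#'   discarded (default 5).
#' @param merge_gap Maximum gap in minutes between candidates merged into a
#'   single period (default 60).
#' @return A tibble of sleep periods: `subject`, `night`, `start`, `end`,
#'   `n_epochs`. May have zero rows.
#' @export
detect_sleep_periods <- function(labels, bouts, max_span_hours = 24,
                                 max_nonzero = 5, merge_gap = 60) {
  stopifnot(all(c("time", "state") %in% names(labels)),
            all(c("start", "end", "kind") %in% names(bouts)))
  empty <- tibble(subject = character(), night = as.Date(character()),
                  start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  n_epochs = integer())
  cand <- bouts[bouts$kind == "NONWEAR", , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  span_h <- as.numeric(difftime(cand$end, cand$start, units = "hours"))
  cand <- cand[span_h <= max_span_hours & cand$n_nonzero < max_nonzero, ,
               drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(cand$start), , drop = FALSE]
  # merge candidates separated by short gaps (in-bed wake)
  gap_min <- c(Inf, as.numeric(difftime(cand$start[-1],
                                        cand$end[-nrow(cand)],
                                        units = "mins")))
  grp <- cumsum(gap_min > merge_gap)
  merged <- dplyr::summarise(
    dplyr::group_by(tibble(grp = grp, start = cand$start, end = cand$end), grp),
    start = min(.data$start), end = max(.data$end), .groups = "drop"
  )
  ep <- as.numeric(labels$time[2]) - as.numeric(labels$time[1])
  t0 <- as.numeric(labels$time[1])
  n <- nrow(labels)
  rows <- vector("list", nrow(merged))
  for (k in seq_len(nrow(merged))) {
    i0 <- as.integer((as.numeric(merged$start[k]) - t0) / ep) + 1L
    i1 <- as.integer((as.numeric(merged$end[k]) - t0) / ep) # end is exclusive
    while (i0 > 1L && labels$state[i0 - 1L] == "SLEEP") i0 <- i0 - 1L
    while (i1 < n && labels$state[i1 + 1L] == "SLEEP") i1 <- i1 + 1L
    start <- labels$time[i0]
    end <- labels$time[i1] + ep
    mid <- start + as.numeric(difftime(end, start, units = "secs")) / 2
    rows[[k]] <- tibble(
      subject = labels$subject[1],
      night = night_date(mid),
      start = start, end = end, n_epochs = i1 - i0 + 1L
    )
  }
  dplyr::bind_rows(rows)
}

#' Clean detected sleep periods against self-report logs
#'
#' Deletes periods that do not represent true night sleep: periods
#' overlapping a logged device-removal interval (`NONWEAR_LOGGED`), periods
#' lying fully inside the daytime window (`DAYTIME`, default 10:00-20:00
#' local clock), and periods whose night falls outside the study window
#' (`OUT_OF_WINDOW`). Subjects with no log coverage keep their periods and a
#' warning is emitted. Applying the cleaning twice equals applying it once.
#'
#' @param periods Sleep periods ([detect_sleep_periods()]), any subjects.
#' @param logs A list with `reports` (tibble `subject`, `date`, ...) and
#'   `removals` (tibble `subject`, `start`, `end`); see [render_logs()].
#' @param study_window A length-2 `Date` vector: first and last night of the
#'   measurement week.
#' @param daytime Numeric length-2: local clock hours bounding the daytime
#'   deletion window (default `c(10, 20)`).
#' @return The retained periods, with a `deletions` attribute: a tibble of
#'   deleted periods carrying a `reason` column.
#' @export
clean_sleep_periods <- function(periods, logs, study_window,
                                daytime = c(10, 20)) {
  stopifnot(length(study_window) == 2)
  study_window <- as.Date(study_window)
  attr(periods, "deletions") <- NULL # re-cleaning starts fresh
  if (nrow(periods) == 0) {
    attr(periods, "deletions") <- dplyr::mutate(periods, reason = character())
    return(periods)
  }
  logged <- unique(c(logs$reports$subject, logs$removals$subject))
  unlogged <- setdiff(unique(periods$subject), logged)
  if (length(unlogged) > 0) {
    warning("no daily log for subject(s) ", paste(unlogged, collapse = ", "),
            "; their periods are retained unchecked", call. = FALSE)
  }
  hr <- function(t) {
    as.numeric(format(t, "%H", tz = "UTC")) +
      as.numeric(format(t, "%M", tz = "UTC")) / 60
  }
  reason <- rep(NA_character_, nrow(periods))
  out_win <- periods$night < study_window[1] | periods$night > study_window[2]
  reason[out_win] <- "OUT_OF_WINDOW"
  same_day <- as.Date(periods$start, tz = "UTC") == as.Date(periods$end - 1,
                                                            tz = "UTC")
  day_only <- same_day & hr(periods$start) >= daytime[1] &
    hr(periods$end) <= daytime[2]
  reason[is.na(reason) & day_only] <- "DAYTIME"
  if (nrow(logs$removals) > 0) {
    for (i in seq_len(nrow(periods))) {
      if (!is.na(reason[i])) next
      rem <- logs$removals[logs$removals$subject == periods$subject[i], ]
      if (nrow(rem) == 0) next
      overlap <- rem$start < periods$end[i] & rem$end > periods$start[i]
      if (any(overlap)) reason[i] <- "NONWEAR_LOGGED"
    }
  }
  kept <- periods[is.na(reason), , drop = FALSE]
  deleted <- periods[!is.na(reason), , drop = FALSE]
  deleted$reason <- reason[!is.na(reason)]
  attr(kept, "deletions") <- deleted
  kept
}
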