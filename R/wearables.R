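# Ring summary ingestion and watch event reconstruction/validation.

#' Parse per-night ring summary records into NightParams
#'
#' Converts the ring's per-night summary (seconds) to minutes: TST =
#' duration/60, WASO = awake/60, SOL = latency/60, TIB = bedtime span/60, SE
#' = the reported efficiency percentage. Records with missing fields,
#' negative values, or `duration + awake` exceeding the bedtime span are
#' rejected with a diagnostic and the night is skipped.
#'
#' @param records Tibble of ring night records (see [render_ring()] for the
#'   field layout).
#' @return A NightParams tibble (device `"ring"`), with a `rejected`
#'   attribute listing skipped records and the reason.
#' @export
parse_ring <- function(records) {
  req <- c("subject", "bedtime_start", "bedtime_end", "duration_s",
           "awake_s", "onset_latency_s", "efficiency_pct")
  records <- as_tibble(records)
  missing_cols <- setdiff(req, names(records))
  for (mc in missing_cols) records[[mc]] <- NA
  reasons <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    vals <- c(rec$duration_s, rec$awake_s, rec$onset_latency_s,
              rec$efficiency_pct)
    if (is.na(rec$bedtime_start) || is.na(rec$bedtime_end)) {
      reasons[i] <- "MISSING_BEDTIME"
    } else if (anyNA(vals)) {
      reasons[i] <- "MISSING_FIELD"
    } else if (any(vals < 0) || rec$efficiency_pct > 100) {
      reasons[i] <- "OUT_OF_RANGE"
    } else if (rec$duration_s + rec$awake_s >
               as.numeric(difftime(rec$bedtime_end, rec$bedtime_start,
                                   units = "secs")) + 1) {
      reasons[i] <- "INCONSISTENT_SPAN"
    }
  }
  bad <- !is.na(reasons)
  if (any(bad)) {
    warning(sum(bad), " ring record(s) rejected (",
            paste(unique(reasons[bad]), collapse = ", "), ")", call. = FALSE)
  }
  ok <- records[!bad, , drop = FALSE]
  out <- night_params_row(
    subject = ok$subject,
    night = night_date(ok$bedtime_start),
    device = "ring",
    tib = as.numeric(difftime(ok$bedtime_end, ok$bedtime_start,
                              units = "mins")),
    tst = ok$duration_s / 60,
    waso = ok$awake_s / 60,
    se = ok$efficiency_pct,
    sol = ok$onset_latency_s / 60
  )
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reasons[bad]
  attr(out, "rejected") <- rejected
  out
}

#' Extract candidate sleep events from watch status changes
#'
#' Normalises the status-change stream (time order, collapse of repeated
#' states) and pairs each SLEEP transition with the next WAKE transition. A
#' trailing SLEEP transition with no terminating WAKE yields an open event
#' (`end = NA`), flagged for discard downstream. An empty stream yields an
#' empty candidate list (the "missed sleep event" case).
#'
#' @param events Tibble with `time` (POSIXct) and `state`
#'   (`"SLEEP"`/`"WAKE"`).
#' @return A tibble of candidate events: `start`, `end`, `open`.
#' @export
extract_watch_events <- function(events) {
  empty <- tibble(start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  open = logical())
  if (is.null(events) || nrow(events) == 0) return(empty)
  stopifnot(all(events$state %in% c("SLEEP", "WAKE")))
  events <- events[order(events$time), , drop = FALSE]
  keep <- c(TRUE, events$state[-1] != events$state[-nrow(events)])
  events <- events[keep, , drop = FALSE]
  out <- list()
  i <- 1L
  while (i <= nrow(events)) {
    if (events$state[i] == "SLEEP") {
      if (i + 1L <= nrow(events)) {
        out[[length(out) + 1L]] <- tibble(start = events$time[i],
                                          end = events$time[i + 1L],
                                          open = FALSE)
        i <- i + 2L
      } else {
        out[[length(out) + 1L]] <- tibble(start = events$time[i],
                                          end = as.POSIXct(NA, tz = "UTC"),
                                          open = TRUE)
        i <- i + 1L
      }
    } else {
      i <- i + 1L # leading WAKE transition carries no event
    }
  }
  if (length(out) == 0) empty else dplyr::bind_rows(out)
}

# nearest stream sample to `t` within `tol_s` seconds; NA if none
nearest_value <- function(times, values, t, tol_s = 300) {
  if (length(times) == 0) return(NA)
  d <- abs(as.numeric(times) - as.numeric(t))
  i <- which.min(d)
  if (d[i] <= tol_s) values[i] else NA
}

#' Validate a candidate sleep event against PPG, movement, and steps
#'
#' The decision cascade, in order: (1) valid heart rate in the 30-s PPG
#' windows at both event boundaries validates via PPG; (2) otherwise,
#' boundary hand-movement magnitude below `movement_threshold` validates via
#' MOVEMENT (the watch was worn but the PPG was unusable); (3) step records
#' with positive counts strictly inside the event contradict sleep, so the
#' event is trimmed to its largest step-free span (CORRECTED) or discarded
#' when no step-free span remains. Open events and events with no usable
#' boundary signal are discarded. Every outcome is a status, never an error.
#'
#' @param event One row of [extract_watch_events()].
#' @param streams A watch night stream list (`ppg`, `movement`, `steps`
#'   tibbles; see [render_watch()]).
#' @param movement_threshold Normalized magnitude below which the wrist is
#'   considered worn-and-still (default 0.05).
#' @param min_corrected_span Minimum step-free span, in minutes, that a
#'   trimmed event must retain to survive as CORRECTED (default 30); below
#'   it the event is discarded as steps-during-sleep.
#' @return A one-row tibble: `start`, `end`, `path`
#'   (`"PPG"`/`"MOVEMENT"`/`"STEP_CORRECTED"`/`NA`), `status`
#'   (`"VALID"`/`"CORRECTED"`/`"DISCARDED"`), `reason`.
#' @export
validate_event <- function(event, streams, movement_threshold = 0.05,
                           min_corrected_span = 30) {
  res <- function(start, end, path, status, reason = NA_character_) {
    tibble(start = start, end = end, path = path, status = status,
           reason = reason)
  }
  if (isTRUE(event$open) || is.na(event$end)) {
    return(res(event$start, event$end, NA_character_, "DISCARDED",
               "OPEN_EVENT"))
  }
  ppg_at <- function(t) {
    nearest_value(streams$ppg$time, streams$ppg$has_valid_heart_rate, t)
  }
  move_at <- function(t) {
    nearest_value(streams$movement$time, streams$movement$magnitude, t)
  }
  ppg_ok <- isTRUE(ppg_at(event$start)) && isTRUE(ppg_at(event$end))
  path <- NA_character_
  if (ppg_ok) {
    path <- "PPG"
  } else {
    mv <- c(move_at(event$start), move_at(event$end))
    if (!anyNA(mv) && all(mv < movement_threshold)) path <- "MOVEMENT"
  }
  if (is.na(path)) {
    return(res(event$start, event$end, NA_character_, "DISCARDED",
               "NO_SIGNAL_MATCH"))
  }
  steps <- streams$steps
  inside <- steps$time > event$start & steps$time < event$end & steps$steps > 0
  if (!any(inside)) {
    return(res(event$start, event$end, path, "VALID"))
  }
  # trim to the largest step-free span between interior step records
  cuts <- sort(steps$time[inside])
  edges <- c(event$start, cuts, event$end)
  spans <- diff(as.numeric(edges))
  best <- which.max(spans)
  if (spans[best] < min_corrected_span * 60) {
    return(res(event$start, event$end, NA_character_, "DISCARDED",
               "STEPS_DURING_SLEEP"))
  }
  res(edges[best], edges[best + 1L], "STEP_CORRECTED", "CORRECTED")
}

#' Watch sleep onset latency from step records
#'
#' The watch does not report onset latency; it is derived as the time from
#' the last positive step record strictly before the validated sleep start
#' (within the night frame) to the sleep start, in minutes. With no prior
#' step in the frame the latency is missing and the night is excluded from
#' SOL analyses.
#'
#' @param event A VALID or CORRECTED validated event (one row).
#' @param steps Step records tibble (`time`, `steps`).
#' @param frame Night frame list (see [night_frame()]); bounds the search.
#' @return Latency in minutes (`>= 0`), or `NA_real_`.
#' @export
watch_sol <- function(event, steps, frame = NULL) {
  prior <- steps$time <= event$start & steps$steps > 0
  if (!is.null(frame)) prior <- prior & steps$time >= frame$start
  if (!any(prior)) return(NA_real_)
  as.numeric(difftime(event$start, max(steps$time[prior]), units = "mins"))
}

#' Nightly watch parameters from validated sleep events
#'
#' TIB spans the first validated event start to the last validated event
#' end; TST is the summed event durations; WASO is `TIB - TST` (gaps between
#' events); SE is `100 * TST / TIB`. SOL comes from [watch_sol()] on the
#' first event. Nights with no VALID or CORRECTED event yield `NULL` - the
#' night is absent from the analysis, mirroring the removal of technically
#' invalid watch nights.
#'
#' @param validated Tibble of validated events ([validate_event()] rows).
#' @param streams The night's stream list (for steps; may be `NULL` to skip
#'   SOL).
#' @param subject,night Identifiers for the output row.
#' @return A one-row NightParams tibble (device `"watch"`), or `NULL`.
#' @export
watch_night_params <- function(validated, streams = NULL, subject, night) {
  ok <- validated[validated$status %in% c("VALID", "CORRECTED"), ,
                  drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  tib <- as.numeric(difftime(max(ok$end), min(ok$start), units = "mins"))
  tst <- sum(as.numeric(difftime(ok$end, ok$start, units = "mins")))
  sol <- if (!is.null(streams)) {
    watch_sol(ok[which.min(ok$start), ], streams$steps, night_frame(night))
  } else {
    NA_real_
  }
  night_params_row(subject = subject, night = night, device = "watch",
                   tib = tib, tst = tst, waso = tib - tst,
                   se = 100 * tst / tib, sol = sol)
}

#' Process all watch nights of a study
#'
#' Runs event extraction, the validation cascade, and nightly parameter
#' computation over a list of watch night streams. Discard accounting (every
#' candidate is VALID, CORRECTED, or DISCARDED) is returned as an attribute.
#'
#' @param watch List of watch night streams ([render_watch()]).
#' @param movement_threshold Passed to [validate_event()].
#' @return A NightParams tibble (device `"watch"`); nights whose events were
#'   all discarded are absent. Attribute `accounting` tabulates candidate
#'   outcomes.
#' @export
watch_nights <- function(watch, movement_threshold = 0.05) {
  rows <- list()
  acct <- list()
  for (st in watch) {
    cand <- extract_watch_events(st$events)
    if (nrow(cand) == 0) {
      acct[[length(acct) + 1L]] <- tibble(subject = st$subject,
                                          night = st$night,
                                          n_candidates = 0L, n_valid = 0L,
                                          n_corrected = 0L, n_discarded = 0L)
      next
    }
    val <- dplyr::bind_rows(lapply(seq_len(nrow(cand)), function(i) {
      validate_event(cand[i, ], st, movement_threshold)
    }))
    acct[[length(acct) + 1L]] <- tibble(
      subject = st$subject, night = st$night,
      n_candidates = nrow(cand),
      n_valid = sum(val$status == "VALID"),
      n_corrected = sum(val$status == "CORRECTED"),
      n_discarded = sum(val$status == "DISCARDED")
    )
    np <- watch_night_params(val, st, st$subject, st$night)
    if (!is.null(np)) rows[[length(rows) + 1L]] <- np
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "accounting") <- dplyr::bind_rows(acct)
  out
}
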