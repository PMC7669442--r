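# Plain-text interchange: epoch counts and night parameters as TSV, ring
# summaries as JSON, watch streams as line-delimited JSON, simulation
# configuration as YAML. All timestamps are written as ISO-8601 UTC.

iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
parse_iso <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ",
                                    tz = "UTC")

#' Write / read actigraphy epoch counts as tab-separated text
#'
#' Columns: `subject`, `time` (ISO-8601, UTC), `count`.
#'
#' @param counts Epoch counts tibble.
#' @param path File path.
#' @return `read_epoch_counts()` returns the counts tibble.
#' @export
write_epoch_counts <- function(counts, path) {
  out <- tibble(subject = counts$subject, time = iso8601(counts$time),
                count = counts$count)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_epoch_counts
#' @export
read_epoch_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    subject = readr::col_character(), time = readr::col_character(),
    count = readr::col_integer()
  ))
  tibble(subject = df$subject, time = parse_iso(df$time), count = df$count)
}

#' Write / read ring night records as JSON
#'
#' One JSON object per night with the device's native field names
#' (`bedtime_start`, `bedtime_end`, `duration_s`, `awake_s`,
#' `onset_latency_s`, `efficiency_pct`, `awakenings`).
#'
#' @param records Ring records tibble ([render_ring()]).
#' @param path File path.
#' @return `read_ring_json()` returns the records tibble.
#' @export
write_ring_json <- function(records, path) {
  out <- records
  out$bedtime_start <- iso8601(out$bedtime_start)
  out$bedtime_end <- iso8601(out$bedtime_end)
  out$night <- as.character(out$night)
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ring_json
#' @export
read_ring_json <- function(path) {
  df <- as_tibble(jsonlite::fromJSON(path))
  df$bedtime_start <- parse_iso(df$bedtime_start)
  df$bedtime_end <- parse_iso(df$bedtime_end)
  df$night <- as.Date(df$night)
  df
}

#' Write / read watch streams as line-delimited JSON
#'
#' Each line is one record: `{"subject", "night", "record"
#' ("event"/"ppg"/"movement"/"steps"), "time", ...payload}`. Reading
#' reconstructs the per-night stream lists.
#'
#' @param watch List of watch night streams ([render_watch()]).
#' @param path File path.
#' @return `read_watch_ndjson()` returns the stream list.
#' @export
write_watch_ndjson <- function(watch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(x) writeLines(jsonlite::toJSON(x, auto_unbox = TRUE), con)
  for (st in watch) {
    base <- list(subject = st$subject, night = as.character(st$night))
    for (i in seq_len(nrow(st$events))) {
      emit(c(base, list(record = "event", time = iso8601(st$events$time[i]),
                        state = st$events$state[i])))
    }
    for (i in seq_len(nrow(st$ppg))) {
      emit(c(base, list(record = "ppg", time = iso8601(st$ppg$time[i]),
                        span_s = st$ppg$span_s[i],
                        has_valid_heart_rate =
                          st$ppg$has_valid_heart_rate[i])))
    }
    for (i in seq_len(nrow(st$movement))) {
      emit(c(base, list(record = "movement",
                        time = iso8601(st$movement$time[i]),
                        magnitude = st$movement$magnitude[i])))
    }
    for (i in seq_len(nrow(st$steps))) {
      emit(c(base, list(record = "steps", time = iso8601(st$steps$time[i]),
                        steps = st$steps$steps[i])))
    }
  }
  invisible(path)
}

#' @rdname write_watch_ndjson
#' @export
read_watch_ndjson <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  key <- vapply(recs, function(r) paste(r$subject, r$night), character(1))
  lapply(split(recs, factor(key, levels = unique(key))), function(rs) {
    pick <- function(kind) rs[vapply(rs, function(r) r$record == kind,
                                     logical(1))]
    tb <- function(kind, fields) {
      rr <- pick(kind)
      cols <- lapply(fields, function(f) {
        vapply(rr, function(r) r[[f]], if (f %in% c("state")) character(1)
               else if (f == "has_valid_heart_rate") logical(1)
               else if (f == "time") character(1) else numeric(1))
      })
      names(cols) <- fields
      out <- as_tibble(cols)
      if ("time" %in% fields) out$time <- parse_iso(out$time)
      out
    }
    list(subject = rs[[1]]$subject, night = as.Date(rs[[1]]$night),
         events = tb("event", c("time", "state")),
         ppg = tb("ppg", c("time", "span_s", "has_valid_heart_rate")),
         movement = tb("movement", c("time", "magnitude")),
         steps = tb("steps", c("time", "steps")))
  })
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `read_sim_config()` returns the validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out$start_date <- as.character(out$start_date)
  for (nm in c("ring_bias", "ring_noise_sd", "watch_bias",
               "watch_noise_sd")) {
    out[[nm]] <- as.list(out[[nm]]) # keep names through YAML maps
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("ring_bias", "ring_noise_sd", "watch_bias", "watch_noise_sd")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}
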