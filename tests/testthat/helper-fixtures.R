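# Fixture builders shared across test files. Everything is generated in code;
# no data files are read.

t_origin <- as.POSIXct("2019-07-01 12:00:00", tz = "UTC")

make_series <- function(counts, start = t_origin, subject = "T1") {
  tibble::tibble(subject = subject,
                 time = start + 60 * (seq_along(counts) - 1),
                 count = as.integer(counts))
}

# Independent brute-force recomputation of the Cole-Kripke score: a per-epoch
# loop over the 7-epoch window, out-of-range neighbours counted as zero.
ck_naive <- function(counts, w = ck_weights()) {
  x <- counts / w$count_divisor
  n <- length(x)
  vapply(seq_len(n), function(t) {
    s <- 0
    for (k in -4:2) {
      i <- t + k
      if (i >= 1 && i <= n) s <- s + w$weights[k + 5] * x[i]
    }
    s * w$scale
  }, numeric(1))
}

# Label tibble straight from a state vector (for sleep-parameter tests).
make_labels <- function(states, start = t_origin, subject = "T1") {
  tibble::tibble(subject = subject,
                 time = start + 60 * (seq_along(states) - 1),
                 state = states)
}

one_period <- function(labels, subject = "T1") {
  ep <- as.numeric(labels$time[2]) - as.numeric(labels$time[1])
  tibble::tibble(subject = subject,
                 night = night_date(labels$time[1]),
                 start = labels$time[1],
                 end = labels$time[nrow(labels)] + ep,
                 n_epochs = nrow(labels))
}

# A minimal watch night stream with configurable boundary signals.
make_stream <- function(events, ppg_valid = TRUE, movement_mag = 0.01,
                        step_times = NULL, subject = "T1",
                        night = as.Date("2019-07-01")) {
  ev <- tibble::tibble(time = events$time, state = events$state)
  bt <- ev$time
  list(
    subject = subject, night = night,
    events = ev,
    ppg = tibble::tibble(time = bt, span_s = 30L,
                         has_valid_heart_rate = ppg_valid),
    movement = tibble::tibble(time = bt,
                              magnitude = rep_len(movement_mag, length(bt))),
    steps = if (is.null(step_times)) {
      tibble::tibble(time = as.POSIXct(character(), tz = "UTC"),
                     steps = integer())
    } else {
      tibble::tibble(time = step_times, steps = 100L)
    }
  )
}

utc <- function(s) as.POSIXct(s, tz = "UTC")

# Small night-parameter table for agreement tests.
make_np <- function(subject, night, device, tst, waso = 30, se = 90,
                    sol = 10, tib = tst + waso + sol) {
  tibble::tibble(subject = subject, night = as.Date(night), device = device,
                 tib = tib, tst = tst, waso = waso, se = se, sol = sol,
                 sol_low_confidence = FALSE)
}
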