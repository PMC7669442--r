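# Synthetic multi-device sleep study generator.
#
# The generator produces a latent "truth" sleep architecture per subject-night
# and renders it through three imperfect observation channels: an actigraphy
# count series (scored downstream by the Cole-Kripke / Troiano pipeline), a
# per-night ring summary record, and event-level watch streams. Device error
# is injected at the parameter level so that the reference-minus-device
# differences have exactly the configured mean (bias) and SD (noise).

#' Simulation configuration for a synthetic multi-device sleep study
#'
#' Defaults emulate the free-living validation study the package reproduces:
#' 45 subjects (23 women, 22 men) monitored for 7 nights, population total
#' sleep time 419.04 (SD 78.31) min, WASO 43.57 (SD 27.28) min, sleep onset
#' latency 0.91 (SD 1.37) min, and device biases/noise equal to the benchmark
#' reference-minus-device difference summaries (see [reference_summaries()]).
#' 11.6% of watch nights are rendered technically invalid and are expected to
#' be discarded by the validation cascade.
#'
#' Sign convention: `ring_bias`/`watch_bias` are *device-minus-truth* offsets,
#' so a reported reference-minus-device bias of -15.27 min corresponds to
#' `ring_bias["tst"] = +15.27`.
#'
#' @param n_subjects,nights_per_subject Study size.
#' @param tst_mean,tst_sd,waso_mean,waso_sd,sol_mean,sol_sd Population
#'   moments (minutes) of the latent per-night parameters; draws are
#'   truncated at zero.
#' @param ring_bias,ring_noise_sd,watch_bias,watch_noise_sd Named numeric
#'   vectors with elements `tst`, `waso`, `se`, `sol`: additive
#'   device-minus-truth offsets and the SD of the per-night
#'   reference-minus-device differences (minutes; `se` in percent points).
#' @param watch_invalid_night_rate Probability that a watch night is rendered
#'   with a corrupted (unterminated) event stream and is discarded
#'   downstream.
#' @param watch_ppg_invalid_rate Probability that a valid watch night carries
#'   unusable boundary PPG windows, exercising the movement fallback of the
#'   validation cascade.
#' @param epoch_length Actigraphy epoch length in seconds (fixed 60).
#' @param wake_count_rate,sleep_count_rate Expected activity counts per epoch
#'   while awake (in or out of bed) and asleep. Sleep must be near-zero for
#'   the nonwear-run-based sleep-period detection to operate (see the methods
#'   vignette).
#' @param bedtime_hour,bedtime_sd Clock hour of bedtime (mean, decimal hours)
#'   and its SD in minutes.
#' @param prop_female Proportion of female subjects (default 23/45).
#' @param start_date First night of the study.
#' @param rng_seed Integer root seed; per-subject child seeds are derived
#'   deterministically from it so subject-level output is reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 45L,
                       nights_per_subject = 7L,
                       tst_mean = 419.04, tst_sd = 78.31,
                       waso_mean = 43.57, waso_sd = 27.28,
                       sol_mean = 0.91, sol_sd = 1.37,
                       ring_bias = c(tst = 15.27, waso = -17.41,
                                     se = -1.34, sol = 11.93),
                       ring_noise_sd = c(tst = 39.68, waso = 28.24,
                                         se = 5.91, sol = 14.92),
                       watch_bias = c(tst = 22.51, waso = -31.27,
                                      se = 4.44, sol = 12.81),
                       watch_noise_sd = c(tst = 73.24, waso = 35.15,
                                          se = 7.88, sol = 14.65),
                       watch_invalid_night_rate = 21 / 181,
                       watch_ppg_invalid_rate = 0.1,
                       epoch_length = 60L,
                       wake_count_rate = 300,
                       sleep_count_rate = 0.001,
                       bedtime_hour = 23, bedtime_sd = 45,
                       prop_female = 23 / 45,
                       start_date = as.Date("2019-07-01"),
                       rng_seed = NULL) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    nights_per_subject = as.integer(nights_per_subject),
    tst_mean = tst_mean, tst_sd = tst_sd,
    waso_mean = waso_mean, waso_sd = waso_sd,
    sol_mean = sol_mean, sol_sd = sol_sd,
    ring_bias = ring_bias, ring_noise_sd = ring_noise_sd,
    watch_bias = watch_bias, watch_noise_sd = watch_noise_sd,
    watch_invalid_night_rate = watch_invalid_night_rate,
    watch_ppg_invalid_rate = watch_ppg_invalid_rate,
    epoch_length = as.integer(epoch_length),
    wake_count_rate = wake_count_rate,
    sleep_count_rate = sleep_count_rate,
    bedtime_hour = bedtime_hour, bedtime_sd = bedtime_sd,
    prop_female = prop_female,
    start_date = as.Date(start_date),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_scalar(cfg$n_subjects, "n_subjects", function(v) v >= 1)
  check_scalar(cfg$nights_per_subject, "nights_per_subject", function(v) v >= 1)
  for (nm in c("tst_sd", "waso_sd", "sol_sd", "wake_count_rate",
               "sleep_count_rate", "bedtime_sd")) {
    check_scalar(cfg[[nm]], nm, function(v) v >= 0)
  }
  for (nm in c("tst_mean", "waso_mean", "sol_mean")) {
    check_scalar(cfg[[nm]], nm, function(v) v >= 0)
  }
  for (nm in c("watch_invalid_night_rate", "watch_ppg_invalid_rate",
               "prop_female")) {
    check_scalar(cfg[[nm]], nm, function(v) v >= 0 && v <= 1)
  }
  if (cfg$epoch_length != 60L) {
    stop("epoch_length is fixed at 60 seconds", call. = FALSE)
  }
  for (nm in c("ring_bias", "ring_noise_sd", "watch_bias", "watch_noise_sd")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || !all(c("tst", "waso", "se", "sol") %in% names(v))) {
      stop(sprintf("`%s` must be a named vector with tst, waso, se, sol", nm),
           call. = FALSE)
    }
    if (grepl("noise", nm) && any(v < 0)) {
      stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
    }
  }
  mean_tib <- cfg$tst_mean + cfg$waso_mean + cfg$sol_mean
  if (mean_tib >= 1320) {
    stop("infeasible config: mean TST + WASO + SOL (", round(mean_tib),
         " min) does not fit within a 24-h night window", call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic per-subject child seeds (one column per rendering stage:
# truth, actigraphy, ring, watch) derived from the root seed so that
# subject-level output is reproducible regardless of iteration order.
subject_seeds <- function(config) {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  matrix(sample.int(2147480000L, config$n_subjects * 4L),
         ncol = 4L,
         dimnames = list(NULL, c("truth", "actigraphy", "ring", "watch")))
}

subject_ids <- function(config) {
  sprintf("S%02d", seq_len(config$n_subjects))
}

#' Simulate latent ground-truth sleep architecture
#'
#' Draws per-night total sleep time, wake after sleep onset (realised as 1-4
#' uniform-length wake bouts), and sleep onset latency from truncated normals
#' and anchors them to a bedtime inside each noon-to-noon night frame. By
#' construction `tib = tst + waso + sol` exactly (integer minutes) and the
#' final sleep segment ends at `bed_end`.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per subject-night: `subject`, `night`,
#'   `gender`, `bed_start`, `onset`, `bed_end`, `tst`, `waso`, `sol`, `tib`
#'   (minutes), `n_bouts`, and a `bouts` list-column of wake intervals
#'   (`start`/`end` POSIXct), sorted and non-overlapping within
#'   `[onset, bed_end]`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- subject_seeds(config)
  ids <- subject_ids(config)
  n_f <- round(config$n_subjects * config$prop_female)
  genders <- rep("M", config$n_subjects)
  if (n_f > 0) genders[seq_len(n_f)] <- "F"
  out <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(seeds[i, "truth"])
    out[[i]] <- simulate_truth_subject(ids[i], genders[i], config)
  }
  dplyr::bind_rows(out)
}

simulate_truth_subject <- function(id, gender, config) {
  nn <- config$nights_per_subject
  nights <- config$start_date + seq_len(nn) - 1L
  tst <- round(rtnorm(nn, config$tst_mean, config$tst_sd, lower = 20))
  waso <- round(rtnorm(nn, config$waso_mean, config$waso_sd,
                       lower = 0, upper = 180))
  sol <- round(rtnorm(nn, config$sol_mean, config$sol_sd,
                      lower = 0, upper = 120))
  bt <- round(rnorm(nn, (config$bedtime_hour - 12) * 60, config$bedtime_sd))
  bt <- clamp(bt, 6 * 60, 14 * 60) # bedtime between 18:00 and 02:00
  rows <- vector("list", nn)
  for (j in seq_len(nn)) {
    frame <- night_frame(nights[j])
    tib <- tst[j] + waso[j] + sol[j]
    bed_start <- frame$start + bt[j] * 60
    # keep the night inside its frame with a 30-min morning margin
    latest <- frame$end - (tib + 30) * 60
    if (bed_start > latest) bed_start <- latest
    onset <- bed_start + sol[j] * 60
    bed_end <- bed_start + tib * 60
    bouts <- make_wake_bouts(tst[j], waso[j], onset)
    rows[[j]] <- tibble(
      subject = id, night = nights[j], gender = gender,
      bed_start = bed_start, onset = onset, bed_end = bed_end,
      tst = tst[j], waso = waso[j], sol = sol[j], tib = tib,
      n_bouts = nrow(bouts), bouts = list(bouts)
    )
  }
  dplyr::bind_rows(rows)
}

# Realise total WASO as 1-4 uniform-length wake bouts between sleep segments.
# Each bout is 3-45 min (single epochs are not resolvable by the 7-epoch
# scoring window) and each sleep segment is at least 60 min (when tst
# allows), so segments are resolvable by the 60-min nonwear rule.
make_wake_bouts <- function(tst, waso, onset) {
  empty <- tibble(start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"))
  if (waso < 1) return(empty)
  k_min <- max(1L, as.integer(ceiling(waso / 45)))
  k_cap <- max(1L, min(4L, as.integer(floor(tst / 60)) - 1L,
                       as.integer(waso %/% 3)))
  if (k_cap < k_min) k_cap <- k_min
  k <- if (k_cap <= k_min) k_min else sample(k_min:k_cap, 1L)
  min_seg <- min(60L, tst %/% (k + 1L))
  bout_len <- rep(waso %/% k, k)
  bout_len[1] <- bout_len[1] + waso %% k
  extra <- tst - min_seg * (k + 1L)
  w <- runif(k + 1L)
  seg <- min_seg + floor(extra * w / sum(w))
  seg[k + 1L] <- tst - sum(seg[-(k + 1L)])
  starts <- onset + cumsum(seg[seq_len(k)]) * 60 +
    c(0, cumsum(bout_len[-k]))[seq_len(k)] * 60
  tibble(start = starts, end = starts + bout_len * 60)
}

#' Render an actigraphy epoch-count series from ground truth
#'
#' Produces a gap-free 60-s epoch series spanning the subject's full noon-to-
#' noon study window. Counts are Poisson draws at `wake_count_rate` while
#' awake (daytime, sleep onset latency, and wake bouts) and at
#' `sleep_count_rate` while asleep; epochs inside `nonwear` intervals are
#' forced to zero.
#'
#' @param truth Ground-truth rows ([simulate_truth()]) for a single subject.
#' @param config A [sim_config()].
#' @param seed Optional integer seed for reproducible rendering.
#' @param nonwear Optional tibble of `start`/`end` POSIXct intervals during
#'   which the device was not worn.
#' @return A tibble `subject`, `time` (epoch start, POSIXct UTC), `count`.
#' @export
render_actigraphy <- function(truth, config, seed = NULL, nonwear = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(unique(truth$subject)) != 1) {
    stop("`truth` must contain exactly one subject", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ep <- config$epoch_length
  t0 <- night_frame(min(truth$night))$start
  t1 <- night_frame(max(truth$night))$end
  times <- seq(t0, t1 - ep, by = ep)
  n <- length(times)
  idx <- function(from, to) {
    # epochs whose [time, time + ep) lies inside [from, to)
    lo <- as.numeric(difftime(from, t0, units = "secs")) / ep
    hi <- as.numeric(difftime(to, t0, units = "secs")) / ep
    lo <- max(ceiling(lo), 0) + 1L
    hi <- min(floor(hi), n)
    if (lo > hi) integer() else seq.int(lo, hi)
  }
  asleep <- rep(FALSE, n)
  for (j in seq_len(nrow(truth))) {
    asleep[idx(truth$onset[j], truth$bed_end[j])] <- TRUE
    b <- truth$bouts[[j]]
    if (nrow(b) > 0) {
      for (m in seq_len(nrow(b))) asleep[idx(b$start[m], b$end[m])] <- FALSE
    }
  }
  lambda <- ifelse(asleep, config$sleep_count_rate, config$wake_count_rate)
  counts <- rpois(n, lambda)
  if (!is.null(nonwear) && nrow(nonwear) > 0) {
    for (m in seq_len(nrow(nonwear))) {
      counts[idx(nonwear$start[m], nonwear$end[m])] <- 0L
    }
  }
  tibble(subject = truth$subject[1], time = times, count = as.integer(counts))
}

# Calibrate the gamma-distributed WASO detection fraction f (device WASO =
# truth WASO * f) so that the reference-minus-device difference W * (1 - f)
# has mean -bias and SD noise_sd at the population level. Truth moments come
# from the truncated-normal closed form.
waso_ratio_params <- function(config, bias, noise_sd) {
  mom <- tnorm_moments(config$waso_mean, config$waso_sd, lower = 0)
  mW <- mom$mean
  vW <- mom$var
  if (mW <= 0) return(list(mean = 1, var = 0))
  mu_f <- max((mW + bias) / mW, 1e-6)
  vf <- (noise_sd^2 - vW * (1 - mu_f)^2) / (vW + mW^2)
  list(mean = mu_f, var = max(vf, 0))
}

#' Render per-night ring summary records from ground truth
#'
#' The ring reports each night as a summary record (bedtime start/end, sleep
#' duration, awake total, onset latency, efficiency). Total sleep time is
#' perturbed additively (Gaussian), WASO multiplicatively through a
#' gamma-distributed detection fraction, onset latency by a gamma draw with
#' mean `truth + bias`, and the efficiency field additively with clamping to
#' \[0, 100\]; all calibrated so the reference-minus-device differences have
#' the configured bias and noise SD (see the methods vignette).
#'
#' @inheritParams render_actigraphy
#' @param truth Ground-truth rows for any number of subjects.
#' @return A tibble of ring night records: `subject`, `night`,
#'   `bedtime_start`, `bedtime_end`, `duration_s`, `awake_s`,
#'   `onset_latency_s`, `efficiency_pct`, `awakenings`.
#' @export
render_ring <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  bias <- config$ring_bias
  noise <- config$ring_noise_sd
  fpar <- waso_ratio_params(config, bias[["waso"]], noise[["waso"]])
  # cap the detection fraction: a device cannot plausibly report many times
  # the true wake (tail probability ~1e-3, negligible moment distortion)
  f <- pmin(rgamma_mv(n, fpar$mean, fpar$var), 4)
  tst_dev <- pmax(truth$tst + bias[["tst"]] + rnorm(n, 0, noise[["tst"]]), 1)
  waso_dev <- truth$waso * f
  sol_dev <- rgamma_mv(n, truth$sol + bias[["sol"]], noise[["sol"]]^2)
  se_truth <- 100 * truth$tst / truth$tib
  se_dev <- clamp(se_truth + bias[["se"]] + rnorm(n, 0, noise[["se"]]), 0, 100)
  duration_s <- round(tst_dev * 60)
  awake_s <- round(waso_dev * 60)
  latency_s <- round(sol_dev * 60)
  tibble(
    subject = truth$subject, night = truth$night,
    bedtime_start = truth$bed_start,
    bedtime_end = truth$bed_start + duration_s + awake_s + latency_s,
    duration_s = duration_s, awake_s = awake_s, onset_latency_s = latency_s,
    efficiency_pct = se_dev, awakenings = truth$n_bouts
  )
}

#' Render watch streams (status events, PPG windows, movement, steps)
#'
#' Each valid night becomes an alternating SLEEP/WAKE status-event walk whose
#' summed sleep duration and internal wake carry the configured watch bias and
#' noise, 30-s PPG validity windows at every event boundary (invalid with
#' probability `watch_ppg_invalid_rate`, which routes validation through the
#' movement fallback), low movement magnitudes at the boundaries, and step
#' records whose last pre-sleep step encodes the watch sleep onset latency.
#' With probability `watch_invalid_night_rate` the night is corrupted: a lone
#' unterminated SLEEP event with no usable boundary data, which the
#' downstream cascade must discard.
#'
#' @inheritParams render_ring
#' @return A list of per-night streams; each element is a list with
#'   `subject`, `night`, `valid_render`, and tibbles `events` (`time`,
#'   `state`), `ppg` (`time`, `span_s`, `has_valid_heart_rate`), `movement`
#'   (`time`, `magnitude`), `steps` (`time`, `steps`).
#' @export
render_watch <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  bias <- config$watch_bias
  noise <- config$watch_noise_sd
  fpar <- waso_ratio_params(config, bias[["waso"]], noise[["waso"]])
  lapply(seq_len(nrow(truth)), function(j) {
    render_watch_night(truth[j, ], config, bias, noise, fpar)
  })
}

render_watch_night <- function(tr, config, bias, noise, fpar) {
  frame <- night_frame(tr$night)
  invalid <- runif(1) < config$watch_invalid_night_rate
  tst_dev <- max(round(tr$tst + bias[["tst"]] + rnorm(1, 0, noise[["tst"]])), 10)
  waso_dev <- round(tr$waso * pmin(rgamma_mv(1, fpar$mean, fpar$var), 4))
  sol_dev <- round(rgamma_mv(1, tr$sol + bias[["sol"]], noise[["sol"]]^2))
  tib_dev <- tst_dev + waso_dev
  # centre the watch night on the truth sleep midpoint, clamped to the frame
  mid <- tr$onset + (tr$tst + tr$waso) * 30
  start <- mid - round(tib_dev / 2) * 60
  start <- clamp(start, frame$start + 120 * 60, frame$end - (tib_dev + 10) * 60)
  start <- as.POSIXct(round(as.numeric(start) / 60) * 60,
                      origin = "1970-01-01", tz = "UTC")
  last_step <- start - sol_dev * 60
  day_end <- min(last_step - 60, start - 3600)
  steps_daytime <- if (day_end > frame$start + 3600) {
    seq(frame$start + 3600, day_end, by = 3600)
  } else {
    as.POSIXct(character(), tz = "UTC")
  }
  steps <- tibble(
    time = as.POSIXct(c(steps_daytime, last_step), tz = "UTC"),
    steps = sample(20:200, length(steps_daytime) + 1L, replace = TRUE)
  )
  if (invalid) {
    return(list(
      subject = tr$subject, night = tr$night, valid_render = FALSE,
      events = tibble(time = start, state = "SLEEP"),
      ppg = tibble(time = as.POSIXct(character(), tz = "UTC"),
                   span_s = integer(), has_valid_heart_rate = logical()),
      movement = tibble(time = as.POSIXct(character(), tz = "UTC"),
                        magnitude = numeric()),
      steps = steps
    ))
  }
  n_gaps <- if (waso_dev < 2) 0L else sample(1:2, 1L)
  if (n_gaps == 0L) {
    seg <- tst_dev
    gap <- integer()
  } else {
    gap <- rep(waso_dev %/% n_gaps, n_gaps)
    gap[1] <- gap[1] + waso_dev %% n_gaps
    w <- runif(n_gaps + 1L)
    min_seg <- min(5L, tst_dev %/% (n_gaps + 1L))
    extra <- tst_dev - min_seg * (n_gaps + 1L)
    seg <- min_seg + floor(extra * w / sum(w))
    seg[n_gaps + 1L] <- tst_dev - sum(seg[-(n_gaps + 1L)])
  }
  times <- start
  state <- "SLEEP"
  cur <- start
  for (m in seq_along(seg)) {
    cur <- cur + seg[m] * 60
    times <- c(times, cur)
    state <- c(state, "WAKE")
    if (m <= length(gap)) {
      cur <- cur + gap[m] * 60
      times <- c(times, cur)
      state <- c(state, "SLEEP")
    }
  }
  events <- tibble(time = as.POSIXct(times, tz = "UTC"), state = state)
  ppg_valid <- runif(1) >= config$watch_ppg_invalid_rate
  ppg <- tibble(time = events$time, span_s = 30L,
                has_valid_heart_rate = ppg_valid)
  movement <- tibble(time = events$time,
                     magnitude = runif(nrow(events), 0, 0.02))
  steps <- dplyr::bind_rows(
    steps,
    tibble(time = max(events$time) + 600, steps = sample(20:200, 1L))
  )
  list(subject = tr$subject, night = tr$night, valid_render = TRUE,
       events = events, ppg = ppg, movement = movement, steps = steps)
}

#' Render self-report daily logs from ground truth
#'
#' Reported bedtimes and wake times are the truth rounded to 5 minutes with a
#' few minutes of recall noise; no naps or removal intervals are generated by
#' default (tests construct those directly).
#'
#' @inheritParams render_ring
#' @return A list with tibbles `reports` (`subject`, `date`, `bedtime`,
#'   `wake_time`) and `removals` (`subject`, `start`, `end`; empty).
#' @export
render_logs <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  jitter <- function(t) {
    t + round(rnorm(n, 0, 5)) * 60
  }
  reports <- tibble(
    subject = truth$subject, date = truth$night,
    bedtime = jitter(truth$bed_start), wake_time = jitter(truth$bed_end)
  )
  removals <- tibble(subject = character(),
                     start = as.POSIXct(character(), tz = "UTC"),
                     end = as.POSIXct(character(), tz = "UTC"))
  list(reports = reports, removals = removals)
}

#' Simulate a complete synthetic multi-device sleep study
#'
#' Orchestrates [simulate_truth()] and the per-device renderers with
#' deterministic per-subject child seeds, so that identical configs (and
#' seeds) yield bit-identical studies.
#'
#' @param config A [sim_config()].
#' @return A list of class `sleep_study`: `config`, `truth`, `counts`
#'   (actigraphy epochs, all subjects), `ring` (night records), `watch`
#'   (list of night streams), `logs`, and `subjects` (id, gender).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- subject_seeds(config)
  truth <- simulate_truth(config)
  ids <- subject_ids(config)
  counts <- vector("list", config$n_subjects)
  ring <- vector("list", config$n_subjects)
  watch <- list()
  for (i in seq_len(config$n_subjects)) {
    tr <- truth[truth$subject == ids[i], ]
    counts[[i]] <- render_actigraphy(tr, config, seed = seeds[i, "actigraphy"])
    ring[[i]] <- render_ring(tr, config, seed = seeds[i, "ring"])
    watch <- c(watch, render_watch(tr, config, seed = seeds[i, "watch"]))
  }
  logs <- render_logs(truth, config,
                      seed = if (is.null(config$rng_seed)) NULL
                             else config$rng_seed + 1L)
  structure(list(
    config = config,
    truth = truth,
    counts = dplyr::bind_rows(counts),
    ring = dplyr::bind_rows(ring),
    watch = watch,
    logs = logs,
    subjects = dplyr::distinct(truth[, c("subject", "gender")])
  ), class = "sleep_study")
}

#' @export
print.sleep_study <- function(x, ...) {
  cat("<sleep_study>\n")
  cat("  subjects:       ", x$config$n_subjects, "\n")
  cat("  nights/subject: ", x$config$nights_per_subject, "\n")
  cat("  epoch counts:   ", nrow(x$counts), "epochs\n")
  cat("  ring records:   ", nrow(x$ring), "\n")
  cat("  watch nights:   ", length(x$watch), "\n")
  invisible(x)
}
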