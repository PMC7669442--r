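ring_record <- function(duration_s, awake_s, latency_s = 0,
                        efficiency = 95,
                        start = utc("2019-07-01 23:00:00"),
                        end = start + duration_s + awake_s + latency_s,
                        subject = "T1") {
  tibble::tibble(subject = subject, night = night_date(start),
                 bedtime_start = start, bedtime_end = end,
                 duration_s = duration_s, awake_s = awake_s,
                 onset_latency_s = latency_s, efficiency_pct = efficiency,
                 awakenings = 1L)
}

test_that("ring unit conversion: seconds in, minutes out", {
  r1 <- parse_ring(ring_record(28800, 0, efficiency = 100))
  expect_equal(r1$tst, 480)
  expect_equal(r1$waso, 0)
  expect_equal(r1$se, 100)
  expect_equal(r1$tib, 480)
  r2 <- parse_ring(ring_record(25200, 1800, 600))
  expect_equal(r2$tst, 420)
  expect_equal(r2$waso, 30)
  expect_equal(r2$sol, 10)
  expect_equal(r2$device, "ring")
})

test_that("malformed ring records are rejected with a diagnostic", {
  rec <- ring_record(25200, 1800, 600)
  rec$bedtime_end <- utc(NA)
  expect_warning(out <- parse_ring(rec), "rejected")
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "rejected")$reason, "MISSING_BEDTIME")
  neg <- ring_record(25200, -5, 600)
  expect_warning(out2 <- parse_ring(neg), "rejected")
  expect_equal(attr(out2, "rejected")$reason, "OUT_OF_RANGE")
  # duration + awake exceeding the bedtime span is inconsistent
  bad <- ring_record(25200, 1800, 600)
  bad$bedtime_end <- bad$bedtime_start + 3600
  expect_warning(out3 <- parse_ring(bad), "rejected")
  expect_equal(attr(out3, "rejected")$reason, "INCONSISTENT_SPAN")
})

test_that("status-change pairing extracts candidate events", {
  ev <- tibble::tibble(time = utc(c("2019-07-01 23:00:00",
                                    "2019-07-02 07:00:00")),
                       state = c("SLEEP", "WAKE"))
  cand <- extract_watch_events(ev)
  expect_equal(nrow(cand), 1L)
  expect_false(cand$open)
  expect_equal(as.numeric(difftime(cand$end, cand$start, units = "mins")), 480)

  open <- extract_watch_events(tibble::tibble(
    time = utc("2019-07-01 23:00:00"), state = "SLEEP"))
  expect_true(open$open)

  frag <- extract_watch_events(tibble::tibble(
    time = utc(c("2019-07-01 23:00:00", "2019-07-02 01:00:00",
                 "2019-07-02 01:30:00", "2019-07-02 07:00:00")),
    state = c("SLEEP", "WAKE", "SLEEP", "WAKE")))
  expect_equal(nrow(frag), 2L)
  expect_false(any(frag$open))

  expect_equal(nrow(extract_watch_events(NULL)), 0L)
})

test_that("the validation cascade follows PPG, movement, steps in order", {
  ev <- tibble::tibble(time = utc(c("2019-07-01 23:00:00",
                                    "2019-07-02 07:00:00")),
                       state = c("SLEEP", "WAKE"))
  cand <- extract_watch_events(ev)
  # (1) valid boundary PPG
  v1 <- validate_event(cand, make_stream(ev, ppg_valid = TRUE))
  expect_equal(v1$status, "VALID")
  expect_equal(v1$path, "PPG")
  # (2) invalid PPG, still wrist: movement fallback
  v2 <- validate_event(cand, make_stream(ev, ppg_valid = FALSE,
                                         movement_mag = 0))
  expect_equal(v2$status, "VALID")
  expect_equal(v2$path, "MOVEMENT")
  # invalid PPG and high movement: nothing corroborates the event
  v3 <- validate_event(cand, make_stream(ev, ppg_valid = FALSE,
                                         movement_mag = 0.5))
  expect_equal(v3$status, "DISCARDED")
  expect_equal(v3$reason, "NO_SIGNAL_MATCH")
  # (3) steps all through the night contradict sleep
  dense <- seq(utc("2019-07-01 23:10:00"), utc("2019-07-02 06:50:00"),
               by = 600)
  v4 <- validate_event(cand, make_stream(ev, step_times = dense))
  expect_equal(v4$status, "DISCARDED")
  expect_equal(v4$reason, "STEPS_DURING_SLEEP")
  # a single interior step trims the event to the larger step-free span
  v5 <- validate_event(cand, make_stream(ev,
                                         step_times = utc("2019-07-02 01:00:00")))
  expect_equal(v5$status, "CORRECTED")
  expect_equal(v5$path, "STEP_CORRECTED")
  expect_equal(v5$start, utc("2019-07-02 01:00:00"))
  expect_equal(v5$end, cand$end)
  # open events are always discarded
  vo <- validate_event(tibble::tibble(start = utc("2019-07-01 23:00:00"),
                                      end = utc(NA), open = TRUE),
                       make_stream(ev))
  expect_equal(vo$status, "DISCARDED")
  expect_equal(vo$reason, "OPEN_EVENT")
})

test_that("watch onset latency comes from the last prior step", {
  ev <- tibble::tibble(start = utc("2019-07-01 23:30:00"),
                       end = utc("2019-07-02 07:00:00"), open = FALSE)
  steps <- tibble::tibble(time = utc(c("2019-07-01 20:00:00",
                                       "2019-07-01 23:12:00")),
                          steps = c(120L, 40L))
  expect_equal(watch_sol(ev, steps), 18)
  boundary <- tibble::tibble(time = utc("2019-07-01 23:30:00"), steps = 10L)
  expect_equal(watch_sol(ev, boundary), 0)
  frame <- night_frame(as.Date("2019-07-01"))
  none <- tibble::tibble(time = utc("2019-07-01 10:00:00"), steps = 10L)
  expect_true(is.na(watch_sol(ev, none, frame)))
})

test_that("watch night parameters conserve TIB = TST + WASO", {
  val1 <- tibble::tibble(start = utc("2019-07-01 23:00:00"),
                         end = utc("2019-07-02 07:00:00"),
                         path = "PPG", status = "VALID", reason = NA)
  np1 <- watch_night_params(val1, NULL, "T1", as.Date("2019-07-01"))
  expect_equal(np1$tst, 480)
  expect_equal(np1$waso, 0)
  expect_equal(np1$se, 100)
  val2 <- tibble::tibble(
    start = utc(c("2019-07-01 23:00:00", "2019-07-02 01:30:00")),
    end = utc(c("2019-07-02 01:00:00", "2019-07-02 07:00:00")),
    path = "PPG", status = c("VALID", "VALID"), reason = NA
  )
  np2 <- watch_night_params(val2, NULL, "T1", as.Date("2019-07-01"))
  expect_equal(np2$tib, 480)
  expect_equal(np2$tst, 450)
  expect_equal(np2$waso, 30)
  expect_equal(np2$se, 93.75)
  discarded <- dplyr::mutate(val2, status = "DISCARDED")
  expect_null(watch_night_params(discarded, NULL, "T1",
                                 as.Date("2019-07-01")))
})

test_that("discard accounting balances over a rendered study", {
  cfg <- sim_config(n_subjects = 4, nights_per_subject = 4,
                    watch_invalid_night_rate = 0.3, rng_seed = 16)
  tr <- simulate_truth(cfg)
  w <- render_watch(tr, cfg, seed = 17)
  np <- watch_nights(w)
  acct <- attr(np, "accounting")
  expect_equal(acct$n_candidates,
               acct$n_valid + acct$n_corrected + acct$n_discarded)
  # every night with at least one usable event yields parameters
  expect_equal(nrow(np), sum(acct$n_valid + acct$n_corrected > 0))
  expect_true(all(abs(np$tst + np$waso - np$tib) < 1e-9))
  expect_equal(np$se, 100 * np$tst / np$tib)
})

test_that("bias-free watch nights recover truth within a minute", {
  zero <- c(tst = 0, waso = 0, se = 0, sol = 0)
  cfg <- sim_config(n_subjects = 3, nights_per_subject = 3,
                    watch_bias = zero, watch_noise_sd = zero,
                    watch_invalid_night_rate = 0, watch_ppg_invalid_rate = 0,
                    rng_seed = 18)
  tr <- simulate_truth(cfg)
  np <- watch_nights(render_watch(tr, cfg, seed = 19))
  m <- dplyr::inner_join(np, tr, by = c("subject", "night"),
                         suffix = c("_est", "_tru"))
  expect_equal(nrow(m), nrow(tr))
  expect_true(all(abs(m$tst_est - m$tst_tru) <= 1))
  expect_true(all(abs(m$waso_est - m$waso_tru) <= 1))
  expect_true(all(abs(m$sol_est - m$sol_tru) <= 1))
})
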