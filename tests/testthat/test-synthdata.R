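test_that("config validation rejects impossible study designs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(tst_mean = 1300, waso_mean = 100), "infeasible")
  expect_error(sim_config(tst_sd = -1), "tst_sd")
  expect_error(sim_config(watch_invalid_night_rate = 1.5),
               "watch_invalid_night_rate")
  expect_error(sim_config(epoch_length = 30), "60 seconds")
  expect_error(sim_config(ring_bias = c(tst = 1)), "ring_bias")
})

test_that("degenerate variance yields identical true parameters every night", {
  cfg <- sim_config(n_subjects = 3, nights_per_subject = 4,
                    tst_sd = 0, waso_sd = 0, sol_sd = 0,
                    tst_mean = 400, waso_mean = 40, sol_mean = 5,
                    rng_seed = 1)
  tr <- simulate_truth(cfg)
  expect_equal(unique(tr$tst), 400)
  expect_equal(unique(tr$waso), 40)
  expect_equal(unique(tr$sol), 5)
})

test_that("a one-subject one-night config yields exactly one truth row", {
  cfg <- sim_config(n_subjects = 1, nights_per_subject = 1, rng_seed = 2)
  tr <- simulate_truth(cfg)
  expect_equal(nrow(tr), 1L)
})

test_that("night accounting is exact: tib = tst + waso + sol", {
  cfg <- sim_config(n_subjects = 8, nights_per_subject = 5, rng_seed = 3)
  tr <- simulate_truth(cfg)
  expect_equal(tr$tib, tr$tst + tr$waso + tr$sol)
  expect_true(all(tr$onset == tr$bed_start + tr$sol * 60))
  expect_true(all(tr$bed_end == tr$bed_start + tr$tib * 60))
})

test_that("wake bouts are sorted, non-overlapping, inside the sleep span", {
  cfg <- sim_config(n_subjects = 10, nights_per_subject = 4, rng_seed = 4)
  tr <- simulate_truth(cfg)
  for (j in seq_len(nrow(tr))) {
    b <- tr$bouts[[j]]
    if (nrow(b) == 0) next
    expect_true(all(b$start >= tr$onset[j]))
    expect_true(all(b$end <= tr$bed_end[j]))
    expect_true(all(b$end > b$start))
    if (nrow(b) > 1) {
      expect_true(all(diff(as.numeric(b$start)) > 0))
      expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
    bout_total <- sum(as.numeric(difftime(b$end, b$start, units = "mins")))
    expect_equal(bout_total, tr$waso[j])
  }
})

test_that("identical config and seed reproduce the study bit for bit", {
  cfg <- sim_config(n_subjects = 3, nights_per_subject = 3, rng_seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$ring, s2$ring)
  expect_identical(s1$watch, s2$watch)
})

test_that("zero sleep count rate puts zero counts in every sleep epoch", {
  cfg <- sim_config(n_subjects = 1, nights_per_subject = 2,
                    sleep_count_rate = 0, rng_seed = 5)
  tr <- simulate_truth(cfg)
  ser <- render_actigraphy(tr, cfg, seed = 99)
  asleep <- rep(FALSE, nrow(ser))
  for (j in seq_len(nrow(tr))) {
    inside <- ser$time >= tr$onset[j] & ser$time < tr$bed_end[j]
    b <- tr$bouts[[j]]
    in_bout <- rep(FALSE, nrow(ser))
    for (m in seq_len(nrow(b))) {
      in_bout <- in_bout | (ser$time >= b$start[m] & ser$time < b$end[m])
    }
    asleep <- asleep | (inside & !in_bout)
  }
  expect_true(all(ser$count[asleep] == 0))
  expect_true(any(ser$count[!asleep] > 0))
})

test_that("rendering is reproducible and respects forced nonwear", {
  cfg <- sim_config(n_subjects = 1, nights_per_subject = 1, rng_seed = 6)
  tr <- simulate_truth(cfg)
  a1 <- render_actigraphy(tr, cfg, seed = 7)
  a2 <- render_actigraphy(tr, cfg, seed = 7)
  expect_identical(a1, a2)
  nw <- tibble::tibble(start = utc("2019-07-01 14:00:00"),
                      end = utc("2019-07-01 16:00:00"))
  a3 <- render_actigraphy(tr, cfg, seed = 7, nonwear = nw)
  masked <- a3$time >= nw$start & a3$time < nw$end
  expect_true(all(a3$count[masked] == 0))
})

test_that("bias-free noise-free ring records equal the truth exactly", {
  zero <- c(tst = 0, waso = 0, se = 0, sol = 0)
  cfg <- sim_config(n_subjects = 2, nights_per_subject = 3,
                    ring_bias = zero, ring_noise_sd = zero, rng_seed = 8)
  tr <- simulate_truth(cfg)
  r <- render_ring(tr, cfg, seed = 9)
  expect_equal(r$duration_s / 60, tr$tst)
  expect_equal(r$awake_s / 60, tr$waso)
  expect_equal(r$onset_latency_s / 60, tr$sol)
  expect_equal(r$efficiency_pct, 100 * tr$tst / tr$tib)
  expect_equal(r$bedtime_start, tr$bed_start)
})

test_that("ring records respect the summary-record internal invariant", {
  cfg <- sim_config(n_subjects = 5, nights_per_subject = 4, rng_seed = 10)
  tr <- simulate_truth(cfg)
  r <- render_ring(tr, cfg, seed = 11)
  span <- as.numeric(difftime(r$bedtime_end, r$bedtime_start, units = "secs"))
  expect_true(all(r$duration_s + r$awake_s <= span))
  expect_true(all(r$efficiency_pct >= 0 & r$efficiency_pct <= 100))
})

test_that("an always-invalid watch produces no analysable nights", {
  cfg <- sim_config(n_subjects = 2, nights_per_subject = 3,
                    watch_invalid_night_rate = 1, rng_seed = 12)
  tr <- simulate_truth(cfg)
  w <- render_watch(tr, cfg, seed = 13)
  np <- watch_nights(w)
  expect_equal(nrow(np), 0L)
  acct <- attr(np, "accounting")
  expect_true(all(acct$n_valid == 0 & acct$n_corrected == 0))
})

test_that("sample mean of true TST sits near the configured population mean", {
  cfg <- sim_config(rng_seed = 20)
  tr <- simulate_truth(cfg)
  se3 <- 3 * cfg$tst_sd / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$tst) - 419.04), se3)
})
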