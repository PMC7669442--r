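test_that("all-zero counts score zero and label every epoch SLEEP", {
  s <- cole_kripke_score(make_series(rep(0, 20)))
  expect_equal(s$score, rep(0, 20))
  expect_equal(unique(s$state), "SLEEP")
  expect_equal(nrow(s), 20L)
})

test_that("a single count spike wakes only the epoch scoring above threshold", {
  counts <- c(0, 0, 0, 0, 500, 0, 0, 0, 0)
  s <- cole_kripke_score(make_series(counts))
  expect_equal(s$score, ck_naive(counts))
  expect_equal(s$state, c(rep("SLEEP", 4), "WAKE", rep("SLEEP", 4)))
})

test_that("saturating counts label every epoch WAKE", {
  s <- cole_kripke_score(make_series(rep(1e5, 12)))
  expect_equal(unique(s$state), "WAKE")
})

test_that("scoring matches the brute-force oracle on random series", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(7:400, 1)
    counts <- rpois(n, sample(c(0.05, 3, 50, 300), 1))
    s <- cole_kripke_score(make_series(counts))
    expect_equal(s$score, ck_naive(counts))
  }
})

test_that("short series and malformed weights are rejected", {
  expect_error(cole_kripke_score(make_series(rep(0, 6))), "at least 7")
  expect_error(ck_weights(weights = 1:6), "7 non-negative")
  expect_error(ck_weights(threshold = 0), "threshold")
})

test_that("raising every count never converts WAKE to SLEEP", {
  set.seed(7)
  for (i in 1:10) {
    counts <- rpois(60, 40)
    before <- cole_kripke_score(make_series(counts))$state
    after <- cole_kripke_score(make_series(counts + 25))$state
    expect_false(any(before == "WAKE" & after == "SLEEP"))
  }
})

test_that("continuous activity yields a single WEAR bout spanning the series", {
  b <- detect_nonwear(make_series(rep(200, 100)))
  expect_equal(nrow(b), 1L)
  expect_equal(b$kind, "WEAR")
  expect_equal(b$n_epochs, 100L)
})

test_that("a 90-min zero run is one NONWEAR bout; 59 min is not", {
  counts <- c(rep(200, 30), rep(0, 90), rep(200, 30))
  b <- detect_nonwear(make_series(counts))
  nw <- b[b$kind == "NONWEAR", ]
  expect_equal(nrow(nw), 1L)
  expect_equal(nw$n_epochs, 90L)
  expect_equal(as.numeric(difftime(nw$end, nw$start, units = "mins")), 90)
  b59 <- detect_nonwear(make_series(c(rep(200, 30), rep(0, 59), rep(200, 30))))
  expect_equal(sum(b59$kind == "NONWEAR"), 0L)
})

test_that("bouts partition the series without gaps or overlap", {
  set.seed(3)
  counts <- c(rpois(80, 150), rep(0, 70), rpois(30, 150), rep(0, 65))
  b <- detect_nonwear(make_series(counts))
  expect_equal(sum(b$n_epochs), length(counts))
  expect_true(all(b$start[-1] == b$end[-nrow(b)]))
})

test_that("small spikes are bridged per the consecutive-interruption rule", {
  zeros <- function(n) rep(0, n)
  # two tolerable epochs inside: still one nonwear run
  counts <- c(200, zeros(40), 50, 50, zeros(40), 200)
  b <- detect_nonwear(make_series(counts))
  nw <- b[b$kind == "NONWEAR", ]
  expect_equal(nrow(nw), 1L)
  expect_equal(nw$n_epochs, 82L)
  expect_equal(nw$n_nonzero, 2L)
  # three consecutive interruptions break the run (each half < 60 min)
  counts3 <- c(200, zeros(40), 50, 50, 50, zeros(40), 200)
  b3 <- detect_nonwear(make_series(counts3))
  expect_equal(sum(b3$kind == "NONWEAR"), 0L)
  # a count at the ceiling always breaks the run
  countsc <- c(200, zeros(40), 100, zeros(40), 200)
  bc <- detect_nonwear(make_series(countsc))
  expect_equal(sum(bc$kind == "NONWEAR"), 0L)
})

test_that("candidate spans longer than a day are excluded", {
  counts <- c(rep(200, 20), rep(0, 25 * 60), rep(200, 20))
  ser <- make_series(counts)
  lab <- cole_kripke_score(ser)
  per <- detect_sleep_periods(lab, detect_nonwear(ser))
  expect_equal(nrow(per), 0L)
})

test_that("the almost-all-zeros rule excludes at 5 nonzeros, retains at 4", {
  build <- function(n_spikes) {
    z <- rep(0, 90)
    z[seq(10, by = 12, length.out = n_spikes)] <- 1 # isolated, bridgeable
    c(rep(200, 20), z, rep(200, 20))
  }
  ser5 <- make_series(build(5))
  per5 <- detect_sleep_periods(cole_kripke_score(ser5), detect_nonwear(ser5))
  expect_equal(nrow(per5), 0L)
  ser4 <- make_series(build(4))
  per4 <- detect_sleep_periods(cole_kripke_score(ser4), detect_nonwear(ser4))
  expect_equal(nrow(per4), 1L)
})

test_that("a detected period overlaps the true bed interval by >= 90%", {
  cfg <- sim_config(n_subjects = 1, nights_per_subject = 1, rng_seed = 14)
  tr <- simulate_truth(cfg)
  ser <- render_actigraphy(tr, cfg, seed = 15)
  per <- detect_sleep_periods(cole_kripke_score(ser), detect_nonwear(ser))
  expect_equal(nrow(per), 1L)
  ov <- as.numeric(difftime(min(per$end, tr$bed_end),
                            max(per$start, tr$bed_start), units = "mins"))
  un <- as.numeric(difftime(max(per$end, tr$bed_end),
                            min(per$start, tr$bed_start), units = "mins"))
  expect_gt(ov / un, 0.9)
  expect_equal(per$night, tr$night)
})

test_that("cleaning deletes out-of-window, daytime, and logged-removal periods", {
  periods <- tibble::tibble(
    subject = "T1",
    night = as.Date(c("2019-06-20", "2019-07-02", "2019-07-03", "2019-07-04")),
    start = utc(c("2019-06-20 23:00:00", "2019-07-02 13:00:00",
                  "2019-07-03 23:00:00", "2019-07-04 23:30:00")),
    end = utc(c("2019-06-21 07:00:00", "2019-07-02 15:00:00",
                "2019-07-04 07:00:00", "2019-07-05 06:30:00")),
    n_epochs = c(480L, 120L, 480L, 420L)
  )
  logs <- list(
    reports = tibble::tibble(subject = "T1", date = as.Date("2019-07-01")),
    removals = tibble::tibble(subject = "T1",
                              start = utc("2019-07-04 02:00:00"),
                              end = utc("2019-07-04 04:00:00"))
  )
  win <- as.Date(c("2019-07-01", "2019-07-07"))
  kept <- clean_sleep_periods(periods, logs, win)
  del <- attr(kept, "deletions")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$night, as.Date("2019-07-04"))
  expect_setequal(del$reason, c("OUT_OF_WINDOW", "DAYTIME", "NONWEAR_LOGGED"))
  expect_equal(del$reason[del$night == as.Date("2019-07-02")], "DAYTIME")
})

test_that("cleaning is idempotent and warns on missing logs", {
  periods <- tibble::tibble(
    subject = c("T1", "T2"),
    night = as.Date(c("2019-07-02", "2019-07-02")),
    start = utc(c("2019-07-02 23:00:00", "2019-07-02 22:00:00")),
    end = utc(c("2019-07-03 07:00:00", "2019-07-03 06:00:00")),
    n_epochs = c(480L, 480L)
  )
  logs <- list(reports = tibble::tibble(subject = "T1",
                                        date = as.Date("2019-07-01")),
               removals = tibble::tibble(subject = character(),
                                         start = utc(character()),
                                         end = utc(character())))
  win <- as.Date(c("2019-07-01", "2019-07-07"))
  expect_warning(kept <- clean_sleep_periods(periods, logs, win), "T2")
  suppressWarnings({
    twice <- clean_sleep_periods(kept, logs, win)
  })
  expect_equal(tibble::as_tibble(twice), tibble::as_tibble(kept),
               ignore_attr = TRUE)
  expect_equal(nrow(attr(twice, "deletions")), 0L)
  expect_equal(nrow(kept), 2L) # unlogged subject retained
})
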