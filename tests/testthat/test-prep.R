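test_that("low-pass filter has unit DC gain, passband fidelity and stopband rejection", {
  sr <- 200
  t <- seq(0, 10, by = 1 / sr)

  expect_equal(lowpass_filter(rep(3.7, 500), sr), rep(3.7, 500),
               tolerance = 1e-8)

  gain_at <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- lowpass_filter(x, sr)
    mid <- seq(length(t) %/% 4, 3 * length(t) %/% 4)
    sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  }
  expect_gt(gain_at(1), 0.99)      # < 1% attenuation at 1 Hz
  expect_lt(gain_at(40), 0.01)     # > 99% attenuation at 40 Hz

  # zero lag: cross-correlation of a 1 Hz sine peaks at zero shift
  x <- sin(2 * pi * 1 * t)
  y <- lowpass_filter(x, sr)
  cc <- stats::ccf(y, x, lag.max = 5, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
})

test_that("filtering is linear", {
  set.seed(3)
  sr <- 200
  a <- stats::rnorm(800)
  b <- stats::rnorm(800)
  expect_equal(lowpass_filter(a + b, sr),
               lowpass_filter(a, sr) + lowpass_filter(b, sr),
               tolerance = 1e-10)
})

test_that("cutoff at or above Nyquist is rejected", {
  expect_error(lowpass_filter(stats::rnorm(100), 200, cutoff = 100),
               "Nyquist", class = "strideworks_param_error")
  # the dual-pass correction raises the design cutoff; reject that too
  expect_error(lowpass_filter(stats::rnorm(100), 200, cutoff = 85),
               class = "strideworks_param_error")
})

test_that("detected events match generator ground truth within one frame", {
  cfg <- sim_config(n_neutral = 1, n_tilted = 1, trial_duration = 120,
                    batch_length = 120, gap_length = 0, seed = 31)
  p <- generate_participant(cfg, "neutral", seed = 31)
  pr <- quiet_prep(p$recording)
  tf <- p$truth$events$right$foot_strikes
  tt <- p$truth$events$right$toe_offs
  infw <- function(x) x[x > 11 & x < 109]
  err_fs <- vapply(infw(tf), function(v)
    min(abs(pr$events$foot_strikes$right - v)), 0)
  err_to <- vapply(infw(tt), function(v)
    min(abs(pr$events$toe_offs$right - v)), 0)
  expect_lt(max(err_fs), 1 / cfg$sample_rate)
  expect_lt(max(err_to), 1 / cfg$sample_rate)
})

test_that("a flat foot trajectory yields an insufficient-data error", {
  expect_error(detect_events(rep(0.1, 5000), 200),
               class = "strideworks_insufficient_data_error")
})

test_that("no events are reported inside recording gaps", {
  cfg <- sim_config(n_neutral = 1, n_tilted = 1, trial_duration = 120,
                    batch_length = 50, gap_length = 20, seed = 12)
  p <- generate_participant(cfg, "neutral", seed = 12)
  rec <- filter_recording(p$recording)
  ev <- detect_events(rec$channels$foot_vertical, rec$sample_rate,
                      windows = rec$batch_windows)
  all_ev <- c(ev$foot_strikes$right, ev$toe_offs$right)
  expect_false(any(all_ev >= 50 & all_ev < 70))
  expect_false(any(all_ev >= 120))
})

test_that("trimming flags the mounting margins and is idempotent", {
  cfg <- clean_config(duration = 600)
  p <- generate_participant(cfg, "neutral", seed = 1)
  r1 <- trim_trial(p$recording, margin = 10)
  expect_equal(r1$usable_windows, cbind(10, 590), ignore_attr = TRUE)
  r2 <- trim_trial(r1, margin = 10)
  expect_equal(r2$usable_windows, r1$usable_windows)

  short <- toy_recording(list(foot_vertical = rep(0, 15 * 200)))
  expect_error(trim_trial(short, margin = 10),
               class = "strideworks_insufficient_data_error")
})

test_that("slicing registers 201 points starting at the foot-strike value", {
  cfg <- clean_config(duration = 60)
  p <- generate_participant(cfg, "neutral", seed = 2)
  pr <- quiet_prep(p$recording)
  s <- pr$strides[[5]]
  expect_identical(nrow(s$registered), 201L)
  # first registered sample equals the channel value at the foot-strike time
  v_at_fs <- stats::approx(pr$recording$time, pr$recording$channels$hip,
                           xout = s$start_time)$y
  expect_equal(unname(s$registered[1, "hip"]), v_at_fs, tolerance = 1e-9)
  # number of strides equals usable consecutive right-FS pairs
  fs <- pr$events$foot_strikes$right
  usable_pairs <- sum(vapply(seq_len(length(fs) - 1), function(i)
    fs[i] >= 10 && fs[i + 1] <= 50, TRUE))
  expect_identical(length(pr$strides), usable_pairs)
})

test_that("linear ramps are registered exactly (linear interpolation)", {
  sr <- 200
  n <- 30 * sr
  t <- (0:(n - 1)) / sr
  ramp <- 2 + 0.5 * t
  cfg <- clean_config(duration = 30)
  p <- generate_participant(cfg, "neutral", seed = 3)
  rec <- p$recording
  rec$channels$hip <- ramp
  pr <- suppressWarnings(suppressMessages({
    r <- filter_recording(rec)
    r$channels$hip <- ramp          # bypass edge effects for the ramp
    r <- trim_trial(r, 10)
    ev <- detect_events(r$channels$foot_vertical, sr,
                        windows = r$usable_windows)
    list(strides = slice_and_register(r, ev))
  }))
  s <- pr$strides[[2]]
  grid <- seq(s$start_time, s$end_time, length.out = 201)
  expect_equal(s$registered[, "hip"], 2 + 0.5 * grid, tolerance = 1e-9)
})

test_that("strides crossing a gap are dropped, not erred", {
  cfg <- sim_config(n_neutral = 1, n_tilted = 1, trial_duration = 120,
                    batch_length = 50, gap_length = 20,
                    noise = zero_noise(), seed = 13)
  p <- generate_participant(cfg, "neutral", seed = 13)
  pr <- quiet_prep(p$recording)
  for (s in pr$strides) {
    inside <- (s$start_time >= 10 & s$end_time <= 50) |
      (s$start_time >= 70 & s$end_time <= 110)
    expect_true(inside)
  }
})

test_that("registration round-trips band-limited signals", {
  cfg <- clean_config(duration = 40)
  p <- generate_participant(cfg, "neutral", seed = 7)
  pr <- quiet_prep(p$recording)
  s <- pr$strides[[3]]
  grid <- seq(s$start_time, s$end_time, length.out = 201)
  back <- stats::approx(grid, s$registered[, "knee"],
                        xout = s$raw_times[s$raw_times >= s$start_time &
                                             s$raw_times <= s$end_time])$y
  orig <- s$raw[s$raw_times >= s$start_time & s$raw_times <= s$end_time,
                "knee"]
  rng <- diff(range(orig))
  expect_lt(max(abs(back - orig)), 0.01 * rng)
})

test_that("segment selection returns k strides nearest each landmark", {
  mk <- function(start) toy_stride(stride_time = 1, start_time = start,
                                   raw_fun = list(hip = function(t) 0 * t))
  strides <- lapply(seq(0, 499), mk)
  segs <- select_segment_strides(strides, c(0, 500), k = 50)
  expect_identical(vapply(segs, function(s) length(s$strides), 0L),
                   c(start = 50L, middle = 50L, end = 50L))
  # the start segment begins at the first usable stride
  first_starts <- vapply(segs$start$strides, function(s) s$start_time, 0)
  expect_identical(sort(first_starts), as.numeric(0:49))
  mid_starts <- vapply(segs$middle$strides, function(s) s$start_time, 0)
  expect_true(all(mid_starts >= 224 & mid_starts <= 275))

  short <- lapply(seq(0, 39), mk)
  expect_warning(segs2 <- select_segment_strides(short, c(0, 40), k = 50),
                 "short")
  expect_identical(vapply(segs2, function(s) length(s$strides), 0L),
                   c(start = 40L, middle = 40L, end = 40L))
  expect_true(all(vapply(segs2, function(s) s$short, TRUE)))
})

test_that("ties in landmark distance break toward the earlier stride", {
  mk <- function(start) toy_stride(stride_time = 1, start_time = start,
                                   raw_fun = list(hip = function(t) 0 * t))
  strides <- lapply(seq(0, 10), mk)     # midpoints 0.5 .. 10.5
  segs <- suppressWarnings(
    select_segment_strides(strides, c(0, 11), k = 1))
  # landmark 5.5 is equidistant from midpoints 5.5-eps? exactly at 5.5:
  # stride starting at 5 has midpoint 5.5 -> unique closest
  expect_equal(segs$middle$strides[[1]]$start_time, 5)
  # landmark 5.5 with even count: strides at 5 and 6 tie via midpoints 5.5, 6.5
  strides2 <- lapply(seq(0, 9), mk)     # midpoints 0.5..9.5, landmark 5
  segs2 <- suppressWarnings(
    select_segment_strides(strides2, c(0, 10), k = 1))
  # midpoints 4.5 and 5.5 tie at distance 0.5; earlier stride wins
  expect_equal(segs2$middle$strides[[1]]$start_time, 4)
})

test_that("breath filtering drops a gross outlier and keeps uniform windows", {
  # all-equal window: SD = 0, nothing excluded
  b <- make_breaths(times = seq(1, 29, by = 2), vo2 = rep(3000, 15))
  expect_true(all(filter_breaths(b)$kept))

  # one 10-SD outlier among 15 clean breaths in one 30-s window
  set.seed(42)
  clean <- stats::rnorm(15, 3000, 50)
  vo2 <- c(clean, 3000 + 10 * 50)
  b2 <- make_breaths(times = c(seq(1, 28, length.out = 15), 29), vo2 = vo2)
  kept <- filter_breaths(b2)$kept
  expect_identical(which(!kept), 16L)

  # empty series unchanged
  b3 <- make_breaths(times = numeric(0), vo2 = numeric(0))
  expect_length(filter_breaths(b3)$kept, 0)
})
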