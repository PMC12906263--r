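test_that("zero-noise trials reduce to template plus cluster offset", {
  cfg <- clean_config(duration = 60)
  nl <- generate_participant(cfg, "neutral", id = "N", seed = 1)
  tl <- generate_participant(cfg, "tilted", id = "T", seed = 2)
  pn <- quiet_prep(nl$recording)
  pt <- quiet_prep(tl$recording)

  # all registered strides of a zero-noise trial are identical
  mid <- pn$segments$middle$strides
  ref <- mid[[1]]$registered[, "hip"]
  for (s in mid[2:length(mid)])
    expect_lt(max(abs(s$registered[, "hip"] - ref)), 1e-6)

  # registered mean tracks the template shape (filtering rounds peaks a little)
  tmpl <- gait_templates()
  grid <- seq(0, 1, length.out = 201)
  hip_mean <- ensemble_curve(mid, "hip")$mean
  expect_lt(max(abs(hip_mean - tmpl$hip(grid))), 1.0)

  # tilted-minus-neutral pelvis equals the configured offset pointwise
  pel_n <- ensemble_curve(pn$segments$start$strides, "pelvis")$mean
  pel_t <- ensemble_curve(pt$segments$start$strides, "pelvis")$mean
  # sub-ms event-time differences between the trials shift the sampling
  # phase slightly; the offset survives to ~1e-3 deg
  expect_equal(pel_t - pel_n,
               rep(cfg$cluster_offsets$pelvis, 201), tolerance = 1e-3)
})

test_that("true stride count matches duration / base stride time", {
  cfg <- clean_config(duration = 60)
  p <- generate_participant(cfg, "neutral", seed = 5)
  n_true <- nrow(p$truth$stride_table)
  expect_lte(abs(n_true - 60 / cfg$base_stride_time), 1)
})

test_that("ground-truth events are strictly increasing and alternate", {
  cfg <- sim_config(n_neutral = 1, n_tilted = 1, trial_duration = 60,
                    batch_length = 60, gap_length = 0, seed = 4)
  p <- generate_participant(cfg, "tilted", seed = 4)
  for (side in c("right", "left")) {
    ev <- p$truth$events[[side]]
    expect_true(all(diff(ev$foot_strikes) > 0))
    n <- length(ev$toe_offs)
    expect_true(all(ev$toe_offs > ev$foot_strikes[seq_len(n)]))
    expect_true(all(ev$toe_offs < ev$foot_strikes[seq_len(n) + 1],
                    na.rm = TRUE))
  }
})

test_that("fatigue deltas ramp linearly: midpoint equals half the end value", {
  # keep stride timing fixed so the two trials sample identical phases and
  # the channel difference isolates the injected angular delta
  fat <- no_fatigue()
  fat$trunk_pelvis_delta <- 4
  cfg <- sim_config(n_neutral = 1, n_tilted = 1, trial_duration = 200,
                    batch_length = 200, gap_length = 0,
                    noise = zero_noise(), fatigue_effects = fat, seed = 8)
  with_f <- generate_participant(cfg, "neutral", seed = 3)
  cfg0 <- sim_config(n_neutral = 1, n_tilted = 1, trial_duration = 200,
                     batch_length = 200, gap_length = 0,
                     noise = zero_noise(),
                     fatigue_effects = no_fatigue(), seed = 8)
  without_f <- generate_participant(cfg0, "neutral", seed = 3)
  tt <- with_f$recording$time
  dd <- with_f$recording$channels$trunk_pelvis -
    without_f$recording$channels$trunk_pelvis
  m_mid <- max(dd[tt >= 99 & tt <= 101])
  m_end <- max(dd[tt >= 198])
  expect_equal(m_end, 4, tolerance = 0.02)
  expect_equal(m_mid, m_end / 2, tolerance = 0.02)
})

test_that("cohort generation is seeded, labelled, and non-degenerate", {
  cfg <- sim_config(n_neutral = 3, n_tilted = 2, trial_duration = 40,
                    batch_length = 40, gap_length = 0, seed = 21)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_length(coh1, 5)
  cl <- vapply(coh1, function(p) p$recording$meta$cluster, "")
  expect_identical(unname(table(cl)[c("neutral", "tilted")]),
                   c(3L, 2L), ignore_attr = TRUE)
  expect_identical(coh1[[2]]$recording$channels$hip,
                   coh2[[2]]$recording$channels$hip)

  cfg_b <- sim_config(n_neutral = 3, n_tilted = 2, trial_duration = 40,
                      batch_length = 40, gap_length = 0, seed = 22)
  coh3 <- generate_cohort(cfg_b)
  expect_gt(max(abs(coh1[[1]]$recording$channels$hip -
                      coh3[[1]]$recording$channels$hip)), 0)
})

test_that("default cohort counts mirror the study (32 neutral, 28 tilted)", {
  cfg <- sim_config()
  expect_identical(cfg$n_neutral, 32L)
  expect_identical(cfg$n_tilted, 28L)
})

test_that("invalid configuration names the offending field", {
  expect_error(sim_config(base_duty_factor = 1.2),
               "base_duty_factor", class = "strideworks_config_error")
  expect_error(sim_config(n_neutral = 0), "n_neutral",
               class = "strideworks_config_error")
  expect_error(sim_config(trial_duration = 10), "trial_duration",
               class = "strideworks_config_error")
})

test_that("samples inside recording gaps are missing", {
  cfg <- sim_config(n_neutral = 1, n_tilted = 1, trial_duration = 100,
                    batch_length = 40, gap_length = 10, seed = 2)
  p <- generate_participant(cfg, "neutral", seed = 2)
  t <- p$recording$time
  in_gap <- (t >= 40 & t < 50) | (t >= 90 & t < 100)
  expect_true(all(is.na(p$recording$channels$hip[in_gap])))
  expect_true(all(!is.na(p$recording$channels$hip[!in_gap])))
})

test_that("synthetic breaths respect rate, RQ identity and outlier truth", {
  b0 <- generate_breaths(600, outlier_rate = 0, seed = 14)
  expect_false(any(b0$outlier_truth))
  rq <- b0$vco2 / b0$vo2
  expect_true(all(rq > 0.85 & rq < 1.25))

  b <- generate_breaths(1200, outlier_rate = 0.05, seed = 15)
  n <- length(b$times)
  expect_gt(n, 400)
  k <- sum(b$outlier_truth)
  expect_lt(abs(k - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95))
})

test_that("curve cohorts have the requested structure and injected effect", {
  cc <- simulate_curve_cohort(n_neutral = 4, n_tilted = 3,
                              segment_effect = list(
                                segment = "end", delta = 4,
                                window = c(0.08, 0.26)),
                              seed = 6)
  expect_identical(dim(cc$y), c(21L, 201L))
  expect_identical(as.vector(table(cc$cluster)[c("neutral", "tilted")]),
                   c(12L, 9L))
  # window interior points carry the +4 offset relative to matched noise-free
  cc0 <- simulate_curve_cohort(n_neutral = 4, n_tilted = 3, seed = 6)
  diffm <- colMeans(cc$y[cc$segment == "end", ] - cc0$y[cc0$segment == "end", ])
  inside <- 23:47   # 11%-23% of stride, inside the tapered window edges
  expect_equal(unname(diffm[inside]), rep(4, length(inside)),
               tolerance = 1e-9)
})
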