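# Synthetic treadmill trials with known ground truth.
#
# Every generated channel is template + cluster offset + linearly ramped
# fatigue delta + smooth stride noise, so downstream stages can be tested
# against exact expectations.

#' Generate one synthetic treadmill trial
#'
#' Simulates a single participant's run to exhaustion: per-stride sagittal
#' joint/segment angle channels, vertical centre-of-mass position, and a
#' vertical foot-reference trajectory for event detection, together with
#' the exact ground truth that was injected (event times, per-stride
#' timing, offsets). Fatigue deltas ramp linearly in elapsed time from 0
#' at the trial start to their configured end-of-trial value. Samples
#' falling in recording gaps between batches are set to `NA`.
#'
#' @param config a [sim_config()].
#' @param cluster `"neutral"` or `"tilted"`.
#' @param id participant identifier.
#' @param seed optional integer; when given, seeds the RNG for this
#'   participant (otherwise the current RNG stream is used, as
#'   [generate_cohort()] does).
#' @param meta optional list with pre-drawn `leg_length` (m) and `sex`
#'   (`"F"`/`"M"`); drawn from the configured distributions when `NULL`.
#'
#' @return a list with elements `recording` (class `trial_recording`:
#'   `meta`, `sample_rate`, `duration`, `batch_windows`, `usable_windows`,
#'   `time`, and a named list `channels`) and `truth` (class
#'   `ground_truth`: per-side `events`, a per-stride `stride_table` with
#'   true stride time / contact time / duty factor, the injected
#'   `offsets`, and the `fatigue` settings).
#' @export
generate_participant <- function(config, cluster = c("neutral", "tilted"),
                                 id = "P01", seed = NULL, meta = NULL) {
  validate_sim_config(config)
  cluster <- match.arg(cluster)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sr <- config$sample_rate
  dur <- config$trial_duration
  nz <- config$noise
  fe <- config$fatigue_effects

  if (is.null(meta)) {
    leg <- stats::rnorm(1, config$leg_length_mean[[cluster]],
                        config$leg_length_sd)
    leg <- max(leg, 0.6)
    sex <- if (stats::runif(1) < config$female_prop[[cluster]]) "F" else "M"
    meta <- list(leg_length = leg, sex = sex)
  }
  if (is.null(meta$leg_length) || !is.finite(meta$leg_length) ||
      meta$leg_length <= 0)
    schema_error("participant '%s': missing or non-positive leg_length", id)
  meta <- list(id = id, cluster = cluster,
               leg_length = meta$leg_length, sex = meta$sex %||% "M")

  # participant-level deviations around the cluster means
  ang_off <- stats::rnorm(length(ANGLE_CHANNELS), 0, nz$participant_angle_sd)
  names(ang_off) <- ANGLE_CHANNELS
  st_i <- config$base_stride_time +
    stats::rnorm(1, 0, nz$participant_stride_time_sd)
  st_i <- max(st_i, 0.3)
  df_i <- config$base_duty_factor +
    stats::rnorm(1, 0, nz$participant_duty_factor_sd)
  if (cluster == "tilted") {
    co <- config$cluster_offsets
    for (ch in ANGLE_CHANNELS)
      if (!is.null(co[[ch]])) ang_off[ch] <- ang_off[ch] + co[[ch]]
    df_i <- df_i + (co$duty_factor %||% 0)
  }
  df_i <- min(max(df_i, 0.15), 0.6)

  # stride-by-stride timing, fatigue drift evaluated at each stride start
  starts <- 0
  st_k <- numeric(0)
  df_k <- numeric(0)
  repeat {
    t0 <- starts[length(starts)]
    ramp <- min(t0 / dur, 1)
    st <- st_i + ramp * fe$stride_time_delta +
      stats::rnorm(1, 0, nz$timing_jitter_sd)
    st <- max(st, 0.3)
    df <- min(max(df_i + ramp * fe$duty_factor_delta, 0.15), 0.6)
    st_k <- c(st_k, st)
    df_k <- c(df_k, df)
    starts <- c(starts, t0 + st)
    if (t0 + st > dur) break
  }
  n_strides <- length(st_k)

  nfr <- round(dur * sr)
  t <- (0:(nfr - 1)) / sr
  k <- findInterval(t, starts[-length(starts)])
  phi <- (t - starts[k]) / st_k[k]
  ramp_t <- t / dur

  tmpl <- gait_templates()
  channels <- vector("list", length(ALL_CHANNELS))
  names(channels) <- ALL_CHANNELS

  # swing-phase noise gain for coordination-variability inflation
  sw_gain <- 1 + (fe$cv_swing_inflation - 1) * ramp_t *
    taper_vec(phi, df_k[k] + 0.02, 0.97, edge = 0.04)

  fat_delta <- function(ch) {
    if (ch == "trunk_pelvis" && fe$trunk_pelvis_delta != 0)
      return(fe$trunk_pelvis_delta * ramp_t *
               phase_taper(phi, fe$trunk_pelvis_window))
    if (ch == "ankle" && fe$ankle_delta != 0)
      return(fe$ankle_delta * ramp_t * phase_taper(phi, fe$ankle_window))
    0
  }

  for (ch in ANGLE_CHANNELS) {
    x <- tmpl[[ch]](phi) + ang_off[ch] + fat_delta(ch)
    x <- x + smooth_noise(nfr, sr, nz$stride_sd) * sw_gain
    channels[[ch]] <- x
  }
  channels$vcom <- tmpl$vcom(phi) + smooth_noise(nfr, sr, nz$vcom_sd)

  foot <- numeric(nfr)
  for (s in seq_len(n_strides)) {
    idx <- which(k == s)
    if (!length(idx)) next
    foot[idx] <- foot_template(df_k[s])(phi[idx])
  }
  channels$foot_vertical <- foot + smooth_noise(nfr, sr, nz$foot_sd)

  bw <- batch_windows(config)
  gap <- !in_windows(t, bw)
  if (any(gap)) for (ch in ALL_CHANNELS) channels[[ch]][gap] <- NA_real_

  recording <- structure(
    list(meta = meta, sample_rate = sr, duration = dur,
         batch_windows = bw, usable_windows = bw,
         time = t, channels = channels, trimmed = FALSE),
    class = "trial_recording"
  )

  full <- which(starts[-1] <= dur)  # strides that end inside the trial
  right_fs <- starts[c(full, max(full) + 1)]
  right_to <- starts[full] + df_k[full] * st_k[full]
  left_fs <- starts[full] + 0.5 * st_k[full]
  left_to <- left_fs + df_k[full] * st_k[full]
  truth <- structure(
    list(
      events = list(
        right = list(foot_strikes = right_fs, toe_offs = right_to),
        left = list(foot_strikes = left_fs, toe_offs = left_to)
      ),
      stride_table = data.frame(
        index = full, start = starts[full], stride_time = st_k[full],
        contact_time = df_k[full] * st_k[full], duty_factor = df_k[full]
      ),
      offsets = list(angles = ang_off, stride_time = st_i,
                     duty_factor = df_i),
      fatigue = fe
    ),
    class = "ground_truth"
  )
  list(recording = recording, truth = truth)
}

# Band-limited (< 6 Hz) stride-to-stride waveform noise: low-passed white
# noise rescaled to the requested SD, so the 10 Hz trajectory filter in the
# preprocessing stage does not remove it.
smooth_noise <- function(n, sample_rate, sd, cutoff = 6) {
  if (sd <= 0) return(numeric(n))
  bf <- signal::butter(2, cutoff / (sample_rate / 2), type = "low")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x) * sd
}

# phase_taper with per-sample window start (used for the swing window,
# whose opening — toe-off — drifts with duty factor).
taper_vec <- function(phi, a, b, edge = 0.03) {
  out <- numeric(length(phi))
  u <- (phi - a) / edge
  v <- (b - phi) / edge
  rise <- u >= 0 & u < 1
  flat <- u >= 1 & v >= 1
  fall <- v >= 0 & v < 1 & u >= 1
  out[rise] <- 0.5 - 0.5 * cos(pi * u[rise])
  out[flat] <- 1
  out[fall] <- 0.5 - 0.5 * cos(pi * v[fall])
  out
}

#' Generate a synthetic cohort of treadmill trials
#'
#' Draws `n_neutral + n_tilted` participants with between-participant
#' variation in leg length, sex, baseline stride timing and angle offsets,
#' and simulates each trial with [generate_participant()]. The whole
#' cohort is reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list with one element per participant, each a
#'   `list(recording, truth)`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  clusters <- c(rep("neutral", config$n_neutral),
                rep("tilted", config$n_tilted))
  out <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    out[[i]] <- generate_participant(config, clusters[i],
                                     id = sprintf("P%02d", i))
  }
  names(out) <- vapply(out, function(p) p$recording$meta$id, "")
  out
}

#' Generate synthetic breath-by-breath gas-exchange records
#'
#' Emulates a portable metabolic cart during a run to exhaustion:
#' breathing frequency rises through the trial, oxygen uptake follows a
#' saturating on-kinetics profile, and the respiratory quotient drifts
#' upward. Clean breaths satisfy RQ = VCO2/VO2 by construction. A
#' configurable fraction of breaths is replaced by large (10 local-SD)
#' excursions and flagged in the ground truth.
#'
#' @param duration trial length, s (> 0).
#' @param outlier_rate probability each breath is an injected outlier.
#' @param seed optional RNG seed.
#' @return an object of class `breath_series`: `times` (s), `vo2`, `vco2`
#'   (ml/min), a logical `kept` mask (all `TRUE` until
#'   [filter_breaths()] is applied) and the ground-truth `outlier_truth`
#'   flags.
#' @export
generate_breaths <- function(duration, outlier_rate = 0, seed = NULL) {
  if (!is.numeric(duration) || duration <= 0)
    param_error("duration must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  times <- numeric(0)
  t <- 1.5
  while (t < duration) {
    times <- c(times, t)
    frac <- t / duration
    gap <- 2.4 - 1.0 * frac + stats::rnorm(1, 0, 0.12)
    t <- t + max(gap, 0.6)
  }
  n <- length(times)
  frac <- times / duration
  vo2 <- 3000 + 800 * (1 - exp(-times / 60)) + stats::rnorm(n, 0, 80)
  rq <- 0.95 + 0.20 * frac + stats::rnorm(n, 0, 0.01)
  vco2 <- rq * vo2
  outlier <- stats::runif(n) < outlier_rate
  if (any(outlier)) {
    sgn <- sample(c(-1, 1), sum(outlier), replace = TRUE)
    vo2[outlier] <- vo2[outlier] + sgn * 10 * 80
    vco2[outlier] <- rq[outlier] * vo2[outlier] + sgn * 10 * 80
  }
  structure(
    list(times = times, vo2 = vo2, vco2 = vco2,
         kept = rep(TRUE, n), outlier_truth = outlier),
    class = "breath_series"
  )
}

#' Simulate a cohort of per-subject, per-segment kinematic curves
#'
#' Curve-level companion to the full gait simulator, used to validate the
#' 1D statistical machinery at arbitrary cohort sizes: each subject
#' contributes one 201-point mean curve per trial segment (start, middle,
#' end), modelled as a common template plus a smooth subject-specific
#' offset curve plus smooth within-subject noise, with optional injected
#' cluster and segment effects.
#'
#' @param n_neutral,n_tilted subjects per cluster.
#' @param between_sd SD (deg) of the smooth between-subject offset curves.
#' @param within_sd SD (deg) of the smooth within-subject (segment-level)
#'   noise curves.
#' @param cluster_effect constant offset (deg) added to every tilted
#'   subject's curves.
#' @param segment_effect optional `list(segment =, delta =, window =)`:
#'   adds `delta` (deg) over the phase `window` (stride fraction, tapered
#'   edges) to the named segment's curves for every subject.
#' @param n_points points per curve.
#' @param smooth kernel SD, in points, of the Gaussian smoothing applied
#'   to the white noise from which curves are built.
#' @param seed optional RNG seed.
#' @return a list: matrix `y` ((subjects x segments) rows, `n_points`
#'   columns), and aligned vectors `subject`, `segment` (factor
#'   start/middle/end), `cluster`, plus the phase `grid`.
#' @export
simulate_curve_cohort <- function(n_neutral = 6, n_tilted = 6,
                                  between_sd = 5, within_sd = 3,
                                  cluster_effect = 0,
                                  segment_effect = NULL,
                                  n_points = 201, smooth = 8,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  N <- n_neutral + n_tilted
  segs <- c("start", "middle", "end")
  cluster_of <- c(rep("neutral", n_neutral), rep("tilted", n_tilted))
  grid <- seq(0, 1, length.out = n_points)
  base <- gait_templates()$hip(grid)

  subject <- rep(seq_len(N), each = length(segs))
  segment <- factor(rep(segs, times = N), levels = segs)
  cluster <- cluster_of[subject]

  y <- matrix(0, nrow = N * length(segs), ncol = n_points)
  for (i in seq_len(N)) {
    b <- smooth_curve_noise(n_points, smooth, between_sd)
    for (j in seq_along(segs)) {
      row <- (i - 1) * length(segs) + j
      y[row, ] <- base + b + smooth_curve_noise(n_points, smooth, within_sd)
    }
  }
  if (cluster_effect != 0)
    y[cluster == "tilted", ] <- y[cluster == "tilted", ] + cluster_effect
  if (!is.null(segment_effect)) {
    w <- segment_effect$delta * phase_taper(grid, segment_effect$window)
    rows <- which(segment == segment_effect$segment)
    y[rows, ] <- sweep(y[rows, , drop = FALSE], 2, w, "+")
  }
  list(y = y, subject = subject, segment = segment, cluster = cluster,
       grid = grid)
}

# Smooth 1D noise over curve points: white noise convolved with a Gaussian
# kernel (circularly), rescaled to the requested SD.
smooth_curve_noise <- function(n, smooth, sd) {
  if (sd <= 0) return(numeric(n))
  if (smooth <= 0) return(stats::rnorm(n, 0, sd))
  half <- ceiling(3 * smooth)
  kern <- stats::dnorm(-half:half, sd = smooth)
  kern <- kern / sum(kern)
  x <- stats::rnorm(n + 2 * half)
  y <- stats::filter(x, kern, sides = 2)[(half + 1):(half + n)]
  y <- as.numeric(y)
  y / stats::sd(y) * sd
}
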