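# Preprocessing: zero-lag filtering, gait-event detection, trial trimming,
# stride slicing with 201-point registration, segment selection, and
# breath-record cleaning.

REG_POINTS <- 201L

#' Zero-lag low-pass Butterworth filter
#'
#' Fourth-order-equivalent zero-phase low-pass: a 2nd-order Butterworth
#' filter applied forward and backward ([signal::filtfilt()]), with the
#' design cutoff raised by `1/(sqrt(2)-1)^(1/4)` so the -3 dB point of the
#' dual pass sits at `cutoff` — the dominant convention for motion-capture
#' trajectory smoothing. The signal is reflection-padded (up to 1 s) at
#' both ends before filtering to suppress edge transients; reflection is a
#' linear operation, so filtering remains linear in the input.
#'
#' @param x uniformly sampled numeric series without missing values.
#' @param sample_rate sampling rate, Hz.
#' @param cutoff -3 dB frequency of the dual pass, Hz; must be below the
#'   Nyquist frequency.
#' @return the filtered series (DC gain 1, zero phase lag).
#' @export
lowpass_filter <- function(x, sample_rate, cutoff = 10) {
  if (!is.numeric(cutoff) || cutoff <= 0)
    param_error("cutoff must be > 0")
  if (cutoff >= sample_rate / 2)
    param_error("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                cutoff, sample_rate / 2)
  if (anyNA(x))
    data_error("lowpass_filter: signal contains missing samples; filter each recorded batch separately")
  n <- length(x)
  if (n < 12)
    insufficient_data_error("lowpass_filter: need at least 12 samples, got %d", n)
  fc <- cutoff / (sqrt(2) - 1)^0.25
  if (fc >= sample_rate / 2)
    param_error("corrected cutoff (%g Hz) reaches the Nyquist frequency", fc)
  bf <- signal::butter(2, fc / (sample_rate / 2), type = "low")
  np <- min(n - 1, round(sample_rate))
  pad_l <- 2 * x[1] - rev(x[2:(np + 1)])
  pad_r <- 2 * x[n] - rev(x[(n - np):(n - 1)])
  y <- signal::filtfilt(bf, c(pad_l, x, pad_r))
  y[(np + 1):(np + n)]
}

#' Filter every channel of a recording
#'
#' Applies [lowpass_filter()] to each channel within each recorded batch
#' window independently; gap samples stay `NA`.
#'
#' @param recording a `trial_recording`.
#' @param cutoff Hz, passed to [lowpass_filter()].
#' @return the recording with filtered channels.
#' @export
filter_recording <- function(recording, cutoff = 10) {
  sr <- recording$sample_rate
  t <- recording$time
  for (w in seq_len(nrow(recording$batch_windows))) {
    idx <- which(t >= recording$batch_windows[w, 1] &
                   t < recording$batch_windows[w, 2])
    if (length(idx) < 12) next
    for (ch in names(recording$channels)) {
      seg <- recording$channels[[ch]][idx]
      if (anyNA(seg)) next
      recording$channels[[ch]][idx] <- lowpass_filter(seg, sr, cutoff)
    }
  }
  recording$filtered <- TRUE
  recording
}

#' Reject the mounting/dismounting margins of a trial
#'
#' Flags the first and last `margin` seconds of the trial as unusable
#' (strides there are aberrant: the runner is getting on or off the
#' treadmill belt). Samples are not removed; the usable-window set is
#' narrowed, and stride slicing honours it. Idempotent.
#'
#' @param recording a `trial_recording`.
#' @param margin seconds to reject at each end.
#' @return the recording with updated `usable_windows`.
#' @export
trim_trial <- function(recording, margin = 10) {
  if (recording$duration <= 2 * margin)
    insufficient_data_error(
      "trial of %g s is too short to trim %g s margins",
      recording$duration, margin)
  recording$usable_windows <- clip_windows(
    recording$batch_windows, margin, recording$duration - margin)
  recording$trimmed <- TRUE
  recording
}

#' Detect foot-strike and toe-off from a vertical foot trajectory
#'
#' Kinematic threshold detector. Within each contiguous recorded span, a
#' height threshold is set at 20% of the signal's range (5th to 95th
#' percentile) above its 5th percentile. Each maximal run of samples below
#' the threshold is one ground contact: foot-strike is the (parabolically
#' refined) minimum inside the run, toe-off the upward threshold crossing
#' (linearly interpolated) at its end. Runs touching the span edges are
#' discarded, so events are never reported inside recording gaps.
#'
#' @param foot_vertical filtered vertical foot-reference series (m); may
#'   contain `NA` in recording gaps.
#' @param sample_rate Hz.
#' @param windows optional two-column matrix of usable time windows (s);
#'   events outside are dropped.
#' @return an object of class `gait_events`: lists `foot_strikes` and
#'   `toe_offs` with a `right` component of strictly increasing times (s)
#'   alternating FS, TO, FS, ...
#' @export
detect_events <- function(foot_vertical, sample_rate, windows = NULL) {
  x <- foot_vertical
  n <- length(x)
  t <- (seq_len(n) - 1) / sample_rate
  ok <- !is.na(x)
  if (!is.null(windows)) ok <- ok & in_windows(t, windows)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  fs_all <- numeric(0)
  to_all <- numeric(0)
  for (r in which(runs$values)) {
    span <- starts[r]:ends[r]
    if (length(span) < 3 * sample_rate / 2) next
    ev <- detect_events_span(x[span], sample_rate)
    fs_all <- c(fs_all, ev$fs + t[span[1]])
    to_all <- c(to_all, ev$to + t[span[1]])
  }
  if (length(fs_all) < 3)
    insufficient_data_error(
      "detect_events: found %d foot-strikes; need at least 3 full cycles",
      length(fs_all))
  structure(
    list(foot_strikes = list(right = fs_all),
         toe_offs = list(right = to_all)),
    class = "gait_events"
  )
}

# Core detector for one contiguous gap-free span. Returns event times in
# seconds relative to the span start.
detect_events_span <- function(y, sample_rate) {
  n <- length(y)
  q <- stats::quantile(y, c(0.05, 0.95), names = FALSE)
  thr <- q[1] + 0.2 * (q[2] - q[1])
  below <- y < thr
  if (!any(below) || all(below))
    return(list(fs = numeric(0), to = numeric(0)))
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  fs <- numeric(0)
  to <- numeric(0)
  for (r in which(runs$values)) {
    i0 <- starts[r]; i1 <- ends[r]
    if (i0 == 1 || i1 == n) next        # partial contact at the span edge
    seg <- y[i0:i1]
    im <- i0 + which.min(seg) - 1
    # parabolic sub-frame refinement of the minimum
    d <- 0
    if (im > 1 && im < n) {
      a <- y[im - 1]; b <- y[im]; cc <- y[im + 1]
      den <- a - 2 * b + cc
      if (den > 0) d <- (a - cc) / (2 * den)
    }
    fs <- c(fs, (im - 1 + d) / sample_rate)
    # upward crossing at the end of the contact run
    j <- i1 + 1
    to <- c(to, (j - 2 + (thr - y[j - 1]) / (y[j] - y[j - 1])) / sample_rate)
  }
  list(fs = fs, to = to)
}

#' Slice a recording into registered strides
#'
#' Cuts the trial into strides running from each right foot-strike to the
#' next, keeps only strides lying entirely inside one usable window, and
#' registers every channel onto 201 equally spaced points of
#' normalized stride time (0% and 100% both included) by linear
#' interpolation. Contact time is the interval from the stride's
#' foot-strike to the toe-off inside it. The original-time samples of each
#' stride are retained for computations that need real time (angular
#' velocities). Strides crossing a gap or trimmed margin are dropped with
#' a message, not an error.
#'
#' @param recording a filtered `trial_recording`.
#' @param events a `gait_events`.
#' @return a list of `stride` objects (`start_time`, `end_time`,
#'   `stride_time`, `contact_time`, `registered` 201-row matrix with one
#'   column per channel, `raw_times`, `raw` matrix, `sample_rate`).
#' @export
slice_and_register <- function(recording, events) {
  fs <- events$foot_strikes$right
  to <- events$toe_offs$right
  t <- recording$time
  win <- recording$usable_windows
  chans <- names(recording$channels)
  strides <- list()
  dropped <- 0L
  for (i in seq_len(length(fs) - 1)) {
    a <- fs[i]; b <- fs[i + 1]
    if (!span_in_windows(a, b, win)) { dropped <- dropped + 1L; next }
    tos <- to[to > a & to < b]
    if (!length(tos)) { dropped <- dropped + 1L; next }
    ct <- tos[1] - a
    grid <- seq(a, b, length.out = REG_POINTS)
    idx <- which(t >= a - 2 / recording$sample_rate &
                   t <= b + 2 / recording$sample_rate)
    reg <- matrix(NA_real_, REG_POINTS, length(chans),
                  dimnames = list(NULL, chans))
    raw <- matrix(NA_real_, length(idx), length(chans),
                  dimnames = list(NULL, chans))
    bad <- FALSE
    for (ch in chans) {
      v <- recording$channels[[ch]]
      if (anyNA(v[idx])) { bad <- TRUE; break }
      reg[, ch] <- stats::approx(t[idx], v[idx], xout = grid)$y
      raw[, ch] <- v[idx]
    }
    if (bad) { dropped <- dropped + 1L; next }
    strides[[length(strides) + 1]] <- structure(
      list(start_time = a, end_time = b, stride_time = b - a,
           contact_time = ct, registered = reg,
           raw_times = t[idx], raw = raw,
           sample_rate = recording$sample_rate),
      class = "stride"
    )
  }
  if (dropped > 0)
    message(sprintf("slice_and_register: dropped %d stride(s) crossing gaps or margins", dropped))
  strides
}

#' Select the strides nearest the start, middle and end of the trial
#'
#' For each landmark (0%, 50% and 100% of the usable trial span) the `k`
#' strides whose temporal midpoints lie closest are selected; ties are
#' broken toward the earlier stride. If fewer than `k` strides are
#' available, all of them are used in every segment and a short-trial
#' warning is raised (segments may then share strides).
#'
#' @param strides list of `stride` objects.
#' @param trial_span numeric `c(start, end)` of the usable trial, s.
#' @param k target strides per segment.
#' @return named list (`start`, `middle`, `end`) of `segment_sample`
#'   objects (`label`, `landmark_time`, `strides`, `short` flag).
#' @export
select_segment_strides <- function(strides, trial_span, k = 50) {
  n <- length(strides)
  if (n == 0) insufficient_data_error("no usable strides to select from")
  mids <- vapply(strides, function(s) (s$start_time + s$end_time) / 2, 0)
  starts <- vapply(strides, function(s) s$start_time, 0)
  landmarks <- c(start = trial_span[1],
                 middle = mean(trial_span),
                 end = trial_span[2])
  short <- n < k
  if (short)
    warning(sprintf("short trial: only %d strides available (target %d per segment)", n, k))
  chosen <- lapply(names(landmarks), function(lbl) {
    ord <- order(abs(mids - landmarks[[lbl]]), starts)
    sel <- sort(ord[seq_len(min(k, n))])
    structure(
      list(label = lbl, landmark_time = landmarks[[lbl]],
           strides = strides[sel], short = short),
      class = "segment_sample"
    )
  })
  names(chosen) <- names(landmarks)
  if (!short) {
    idx <- lapply(chosen, function(s)
      vapply(s$strides, function(x) x$start_time, 0))
    if (length(intersect(idx$start, idx$middle)) > 0 ||
        length(intersect(idx$middle, idx$end)) > 0 ||
        length(intersect(idx$start, idx$end)) > 0)
      warning("trial segments share strides; trial may be short relative to k")
  }
  chosen
}

#' Exclude outlier breaths by local windowed statistics
#'
#' Reviews the gas-exchange record in consecutive non-overlapping windows
#' aligned to the trial start and drops any breath whose VO2 or VCO2 falls
#' outside `z` standard deviations of that window's mean. Windows with
#' fewer than two breaths, or zero spread, keep all their breaths.
#'
#' @param breaths a `breath_series`.
#' @param window window length, s.
#' @param z SD multiple defining an outlier.
#' @return the series with its `kept` mask updated.
#' @export
filter_breaths <- function(breaths, window = 30, z = 2) {
  times <- breaths$times
  kept <- rep(TRUE, length(times))
  if (length(times) == 0) {
    breaths$kept <- kept
    return(breaths)
  }
  wid <- floor(times / window)
  for (w in unique(wid)) {
    idx <- which(wid == w)
    if (length(idx) < 2) next
    for (var in c("vo2", "vco2")) {
      v <- breaths[[var]][idx]
      m <- mean(v); s <- stats::sd(v)
      if (s == 0) next
      kept[idx] <- kept[idx] & abs(v - m) <= z * s
    }
  }
  breaths$kept <- kept
  breaths
}

#' Preprocess a trial end to end
#'
#' Convenience wrapper: filter each batch, trim the mounting margins,
#' detect gait events inside the usable windows, slice into registered
#' strides and pick the three landmark segments.
#'
#' @param recording a raw `trial_recording`.
#' @param cutoff low-pass cutoff, Hz.
#' @param margin trim margin, s.
#' @param k strides per segment.
#' @return list with `recording` (filtered/trimmed), `events`, `strides`,
#'   and `segments` (from [select_segment_strides()]).
#' @export
prep_trial <- function(recording, cutoff = 10, margin = 10, k = 50) {
  rec <- filter_recording(recording, cutoff)
  rec <- trim_trial(rec, margin)
  events <- detect_events(rec$channels$foot_vertical, rec$sample_rate,
                          windows = rec$usable_windows)
  strides <- slice_and_register(rec, events)
  if (!length(strides))
    insufficient_data_error("no usable strides after slicing")
  span <- c(min(rec$usable_windows[, 1]), max(rec$usable_windows[, 2]))
  segments <- select_segment_strides(strides, span, k)
  list(recording = rec, events = events, strides = strides,
       segments = segments)
}
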