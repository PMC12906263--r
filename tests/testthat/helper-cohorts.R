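# Shared fixture builders: small, fast synthetic configurations.

zero_noise <- function() {
  list(stride_sd = 0, vcom_sd = 0, foot_sd = 0, timing_jitter_sd = 0,
       participant_angle_sd = 0, participant_stride_time_sd = 0,
       participant_duty_factor_sd = 0)
}

no_fatigue <- function() {
  list(trunk_pelvis_delta = 0, trunk_pelvis_window = c(0.08, 0.26),
       ankle_delta = 0, ankle_window = c(0.49, 0.91),
       stride_time_delta = 0, duty_factor_delta = 0,
       cv_swing_inflation = 1)
}

# deterministic trial: no noise, no drift, one long batch
clean_config <- function(duration = 80, ...) {
  sim_config(n_neutral = 1, n_tilted = 1, trial_duration = duration,
             noise = zero_noise(), fatigue_effects = no_fatigue(),
             batch_length = duration, gap_length = 0, seed = 11, ...)
}

quiet_prep <- function(recording, ...) {
  suppressWarnings(suppressMessages(prep_trial(recording, ...)))
}

# a bare-bones recording from explicit channel vectors (200 Hz)
toy_recording <- function(channels, sample_rate = 200, id = "T01",
                          leg_length = 0.95) {
  n <- length(channels[[1]])
  dur <- n / sample_rate
  structure(
    list(meta = list(id = id, cluster = "neutral",
                     leg_length = leg_length, sex = "F"),
         sample_rate = sample_rate, duration = dur,
         batch_windows = matrix(c(0, dur), 1),
         usable_windows = matrix(c(0, dur), 1),
         time = (0:(n - 1)) / sample_rate,
         channels = channels, trimmed = FALSE),
    class = "trial_recording"
  )
}

# synthetic stride carrying arbitrary registered/raw channels
toy_stride <- function(stride_time = 0.7, contact_time = 0.25,
                       registered = NULL, raw_fun = NULL,
                       sample_rate = 200, start_time = 0) {
  n_raw <- round(stride_time * sample_rate) + 1
  tt <- start_time + seq(0, stride_time, length.out = n_raw)
  if (is.null(raw_fun)) raw_fun <- function(t) 0 * t
  raw_vals <- vapply(names(raw_fun), function(ch) raw_fun[[ch]](tt),
                     numeric(n_raw))
  if (is.null(registered)) {
    grid <- start_time + seq(0, stride_time, length.out = 201)
    registered <- vapply(names(raw_fun), function(ch) raw_fun[[ch]](grid),
                         numeric(201))
  }
  structure(
    list(start_time = start_time, end_time = start_time + stride_time,
         stride_time = stride_time, contact_time = contact_time,
         registered = registered, raw_times = tt, raw = raw_vals,
         sample_rate = sample_rate),
    class = "stride"
  )
}

make_breaths <- function(times, vo2, vco2 = NULL) {
  structure(
    list(times = times, vo2 = vo2, vco2 = vco2 %||% vo2 * 1.0,
         kept = rep(TRUE, length(times)),
         outlier_truth = rep(FALSE, length(times))),
    class = "breath_series"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
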