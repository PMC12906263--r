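#' Simulation configuration for synthetic treadmill trials
#'
#' Builds and validates the configuration that drives the synthetic gait
#' generator. The defaults describe the study conditions the package is
#' designed around: a cohort of 60 runners split into a "neutral pelvis"
#' (n = 32) and a "tilted pelvis" (n = 28) technique cluster, constant-speed
#' treadmill trials of roughly 20 minutes recorded at 200 Hz in 9-minute
#' batches separated by 1.5-minute saving gaps, a base stride time of
#' 0.685 s, and progressive fatigue drift ramped linearly from zero at the
#' start of the trial to its full value at the end.
#'
#' @param n_neutral,n_tilted participants per technique cluster.
#' @param sample_rate recording rate, Hz.
#' @param trial_duration trial length, s.
#' @param base_stride_time cohort-mean stride time, s.
#' @param base_duty_factor cohort-mean duty factor (contact time / stride
#'   time), in (0, 1).
#' @param cluster_offsets named list of constant offsets added for the
#'   tilted-pelvis cluster: angle offsets in degrees (`pelvis` anterior
#'   tilt, `trunk_pelvis` flexion — negative means more extension, `hip`
#'   flexion) and a `duty_factor` offset (unitless).
#' @param fatigue_effects named list of end-of-trial deltas:
#'   `trunk_pelvis_delta` (deg) over `trunk_pelvis_window` (stride
#'   fraction), `ankle_delta` (deg, negative = more plantarflexion) over
#'   `ankle_window`, `stride_time_delta` (s), `duty_factor_delta`
#'   (unitless), and `cv_swing_inflation` (multiplier on stride-to-stride
#'   waveform noise during swing at the end of the trial).
#' @param noise named list of noise scales: `stride_sd` (deg, smooth
#'   stride-to-stride waveform noise, band-limited below 6 Hz so the 10 Hz
#'   low-pass cannot erase it), `vcom_sd` (m), `foot_sd` (m, on the
#'   event-reference trajectory), `timing_jitter_sd` (s, stride-time
#'   jitter), and between-participant SDs `participant_angle_sd` (deg),
#'   `participant_stride_time_sd` (s), `participant_duty_factor_sd`.
#' @param leg_length_mean named vector of cluster means (m);
#'   `leg_length_sd` between-participant SD (m).
#' @param female_prop named vector, probability a participant of each
#'   cluster is female.
#' @param batch_length,gap_length recording-batch structure, s.
#' @param seed integer RNG seed used by [generate_cohort()].
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [generate_participant()], [generate_cohort()]
#' @export
sim_config <- function(n_neutral = 32L,
                       n_tilted = 28L,
                       sample_rate = 200,
                       trial_duration = 1200,
                       base_stride_time = 0.685,
                       base_duty_factor = 0.35,
                       cluster_offsets = list(
                         pelvis = 4, trunk_pelvis = -5, hip = 5,
                         duty_factor = -0.015
                       ),
                       fatigue_effects = list(
                         trunk_pelvis_delta = 4,
                         trunk_pelvis_window = c(0.08, 0.26),
                         ankle_delta = -6,
                         ankle_window = c(0.49, 0.91),
                         stride_time_delta = 0.008,
                         duty_factor_delta = 0.005,
                         cv_swing_inflation = 1.5
                       ),
                       noise = list(
                         stride_sd = 1.5,
                         vcom_sd = 1e-3,
                         foot_sd = 2e-4,
                         timing_jitter_sd = 0.004,
                         participant_angle_sd = 2,
                         participant_stride_time_sd = 0.04,
                         participant_duty_factor_sd = 0.02
                       ),
                       leg_length_mean = c(neutral = 0.95, tilted = 0.96),
                       leg_length_sd = 0.05,
                       female_prop = c(neutral = 0.50, tilted = 0.32),
                       batch_length = 540,
                       gap_length = 90,
                       seed = 1L) {
  cfg <- list(
    n_neutral = as.integer(n_neutral), n_tilted = as.integer(n_tilted),
    sample_rate = sample_rate, trial_duration = trial_duration,
    base_stride_time = base_stride_time,
    base_duty_factor = base_duty_factor,
    cluster_offsets = cluster_offsets,
    fatigue_effects = fatigue_effects,
    noise = noise,
    leg_length_mean = leg_length_mean, leg_length_sd = leg_length_sd,
    female_prop = female_prop,
    batch_length = batch_length, gap_length = gap_length,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(cfg$n_neutral) || cfg$n_neutral <= 0)
    config_error("n_neutral", "must be a positive count")
  if (!num1(cfg$n_tilted) || cfg$n_tilted <= 0)
    config_error("n_tilted", "must be a positive count")
  if (!num1(cfg$sample_rate) || cfg$sample_rate <= 0)
    config_error("sample_rate", "must be > 0")
  if (!num1(cfg$trial_duration) || cfg$trial_duration <= 20)
    config_error("trial_duration", "must exceed 20 s")
  if (!num1(cfg$base_stride_time) || cfg$base_stride_time <= 0)
    config_error("base_stride_time", "must be > 0")
  if (!num1(cfg$base_duty_factor) ||
      cfg$base_duty_factor <= 0 || cfg$base_duty_factor >= 1)
    config_error("base_duty_factor", "must lie strictly between 0 and 1")
  if (!num1(cfg$batch_length) || cfg$batch_length <= 0)
    config_error("batch_length", "must be > 0")
  if (!num1(cfg$gap_length) || cfg$gap_length < 0)
    config_error("gap_length", "must be >= 0")
  if (!num1(cfg$leg_length_sd) || cfg$leg_length_sd < 0)
    config_error("leg_length_sd", "must be >= 0")
  if (is.null(cfg$leg_length_mean) || any(!is.finite(cfg$leg_length_mean)) ||
      any(cfg$leg_length_mean <= 0))
    config_error("leg_length_mean", "leg lengths must be positive")
  for (nm in c("stride_sd", "vcom_sd", "foot_sd", "timing_jitter_sd",
               "participant_angle_sd", "participant_stride_time_sd",
               "participant_duty_factor_sd")) {
    v <- cfg$noise[[nm]]
    if (is.null(v) || !num1(v) || v < 0)
      config_error(paste0("noise$", nm), "must be a non-negative number")
  }
  fe <- cfg$fatigue_effects
  for (nm in c("trunk_pelvis_window", "ankle_window")) {
    w <- fe[[nm]]
    if (is.null(w) || length(w) != 2 || w[1] < 0 || w[2] > 1 || w[1] >= w[2])
      config_error(paste0("fatigue_effects$", nm),
                   "must be an increasing pair inside [0, 1]")
  }
  if (!num1(fe$cv_swing_inflation %||% NA) || fe$cv_swing_inflation < 1)
    config_error("fatigue_effects$cv_swing_inflation", "must be >= 1")
  invisible(cfg)
}

# Recording-batch windows for a trial: [0, b), [b+g, 2b+g), ... clipped to
# the trial duration.
batch_windows <- function(cfg) {
  starts <- seq(0, cfg$trial_duration, by = cfg$batch_length + cfg$gap_length)
  clip_windows(cbind(starts, starts + cfg$batch_length), 0, cfg$trial_duration)
}
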