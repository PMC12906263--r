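#' Sagittal-plane stride waveform templates
#'
#' Periodic per-channel templates over normalized stride time (phase 0 at
#' right foot-strike, 1 at the next right foot-strike). Shapes are
#' plausible running kinematics in a flexion/anterior-tilt-positive,
#' extension/plantarflexion-negative convention — hip flexion peaking in
#' mid-swing, knee flexion peaking in early-mid swing, ankle
#' plantarflexion just after toe-off, a twice-per-stride pelvis and
#' trunk-to-pelvis oscillation, and a twice-per-stride vertical
#' centre-of-mass oscillation with minima in mid-stance. They are
#' synthetic stand-ins with known ground truth, not measurements.
#'
#' @return a named list of vectorized functions of stride phase; angle
#'   templates return degrees, `vcom` returns metres (absolute height
#'   around 1 m). The `foot_vertical` entry is a factory
#'   `function(duty_factor)` returning a phase function (metres), because
#'   the foot trajectory shape depends on when toe-off occurs.
#' @export
gait_templates <- function() {
  per <- function(x, y) {
    f <- stats::splinefun(x, y, method = "periodic")
    function(phi) f(phi %% 1)
  }
  list(
    trunk_pelvis = per(
      c(0, 0.10, 0.25, 0.40, 0.50, 0.60, 0.75, 0.90, 1),
      c(8, 10, 9, 7, 8, 10, 9, 7, 8)
    ),
    pelvis = per(
      c(0, 0.12, 0.25, 0.40, 0.50, 0.62, 0.75, 0.90, 1),
      c(8, 9.5, 8, 6.8, 8, 9.5, 8, 6.8, 8)
    ),
    hip = per(
      c(0, 0.10, 0.25, 0.35, 0.50, 0.70, 0.85, 0.95, 1),
      c(30, 15, -5, -12, 5, 35, 42, 35, 30)
    ),
    knee = per(
      c(0, 0.12, 0.25, 0.35, 0.50, 0.65, 0.80, 0.92, 1),
      c(15, 40, 30, 15, 60, 95, 60, 22, 15)
    ),
    ankle = per(
      c(0, 0.10, 0.25, 0.33, 0.40, 0.55, 0.70, 0.85, 1),
      c(2, 15, 20, 0, -22, -12, -5, 0, 2)
    ),
    vcom = function(phi) 1.0 - 0.04 * cos(4 * pi * ((phi %% 1) - 0.15)),
    foot_vertical = foot_template
  )
}

# Channels carrying joint/segment angles (degrees).
ANGLE_CHANNELS <- c("trunk_pelvis", "pelvis", "hip", "knee", "ankle")
ALL_CHANNELS <- c(ANGLE_CHANNELS, "vcom", "foot_vertical")

# Vertical trajectory of the event-reference point on the right foot.
#
# Built so that the kinematic event detector recovers the true events to
# sub-frame accuracy after 10 Hz zero-lag filtering:
#  * a symmetric V-shaped valley (slopes +/-0.3 m per stride over +/-5% of
#    the stride) centred on foot-strike, so the zero-phase filter rounds
#    the minimum without displacing it;
#  * a linear ramp through the detector's height threshold (~0.0376 m,
#    i.e. p5 + 20% of the p5-p95 range of this shape) crossing exactly at
#    toe-off, kept linear over +/-7% of the stride — wider than the
#    filter's kernel — so filtering preserves the crossing;
#  * monotone rise from foot-strike to a mid-swing peak (0.15 m) and
#    monotone fall back, so foot-strike is the only local minimum.
foot_template <- function(duty_factor) {
  df <- duty_factor
  peak <- df + 0.45 * (1 - df)
  fup <- stats::splinefun(
    c(0, 0.05, df - 0.07, df, df + 0.07, df + 0.15, peak),
    c(0.004, 0.019, 0.0205, 0.0376, 0.0547, 0.095, 0.150),
    method = "monoH.FC"
  )
  fdn <- stats::splinefun(
    c(peak, 0.80, 0.87, 0.95, 1),
    c(0.150, 0.080, 0.035, 0.019, 0.004),
    method = "monoH.FC"
  )
  function(phi) {
    phi <- phi %% 1
    ifelse(phi <= peak, fup(phi), fdn(phi))
  }
}
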