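# Spatiotemporal (0D) and time-series (1D) descriptors of running
# technique, per participant and trial segment.

#' Duty factor of a stride
#'
#' Fraction of the stride spent in ground contact: contact time divided by
#' stride time.
#'
#' @param stride a `stride` object (or a list with `contact_time` and
#'   `stride_time`).
#' @return duty factor in (0, 1).
#' @export
duty_factor <- function(stride) {
  ct <- stride$contact_time
  st <- stride$stride_time
  if (!is.finite(ct) || !is.finite(st) || ct <= 0 || st <= 0 || ct >= st)
    data_error("invalid stride: need 0 < contact_time < stride_time (got CT=%s, ST=%s)",
               format(ct), format(st))
  ct / st
}

#' Leg-length-normalised stride frequency
#'
#' Dimensionless stride frequency: `(1/stride_time) * sqrt(leg_length/g)`.
#' Dividing the raw frequency by the pendular frequency scale
#' `sqrt(g/leg_length)` removes the dependence of preferred cadence on
#' stature.
#'
#' @param stride a `stride` object, or a numeric stride time in seconds.
#' @param leg_length leg length, m.
#' @param g gravitational acceleration, m/s^2.
#' @return dimensionless stride frequency.
#' @export
stride_frequency_norm <- function(stride, leg_length, g = 9.81) {
  st <- if (is.numeric(stride)) stride else stride$stride_time
  if (!is.finite(st) || st <= 0) param_error("stride time must be > 0")
  if (!is.finite(leg_length) || leg_length <= 0)
    param_error("leg_length must be > 0")
  if (!is.finite(g) || g <= 0) param_error("g must be > 0")
  (1 / st) * sqrt(leg_length / g)
}

#' Pointwise ensemble mean and SD over registered strides
#'
#' @param strides list of at least two `stride` objects.
#' @param channel channel name present in the registered matrices.
#' @return a `curve_1d`: `channel`, 201-point `mean` and sample `sd`,
#'   `n_strides`, and unit metadata.
#' @export
ensemble_curve <- function(strides, channel) {
  if (length(strides) < 2)
    insufficient_data_error("ensemble_curve: need >= 2 strides, got %d",
                            length(strides))
  m <- stride_matrix(strides, channel)
  new_curve(channel, colMeans(m), sample_sd_cols(m), nrow(m),
            units = if (channel %in% ANGLE_CHANNELS) "deg" else "m")
}

#' Vertical centre-of-mass displacement curve
#'
#' Per stride, the vCOM channel is re-referenced to its own minimum
#' (displacement) and normalised by leg length; the ensemble mean and SD
#' over the supplied strides form the curve.
#'
#' @param strides one `stride` or a list of strides with a `vcom` channel.
#' @param leg_length leg length, m.
#' @return a dimensionless `curve_1d` named `"vcom"`.
#' @export
vcom_curve <- function(strides, leg_length) {
  if (inherits(strides, "stride")) strides <- list(strides)
  if (!is.finite(leg_length) || leg_length <= 0)
    param_error("leg_length must be > 0")
  m <- stride_matrix(strides, "vcom")
  disp <- sweep(m, 1, apply(m, 1, min), "-") / leg_length
  sd <- if (nrow(disp) >= 2) sample_sd_cols(disp) else rep(0, ncol(disp))
  new_curve("vcom", colMeans(disp), sd, nrow(disp), units = "dimensionless")
}

#' Difference between two curves (change from a reference)
#'
#' Pointwise mean difference (`curve_a` minus `curve_ref`) with the SDs
#' combined in quadrature.
#'
#' @param curve_a,curve_ref `curve_1d` objects on the same channel/grid.
#' @return a `curve_1d` of the change.
#' @export
change_curve <- function(curve_a, curve_ref) {
  if (!identical(curve_a$channel, curve_ref$channel))
    schema_error("change_curve: channel mismatch ('%s' vs '%s')",
                 curve_a$channel, curve_ref$channel)
  if (length(curve_a$mean) != length(curve_ref$mean))
    schema_error("change_curve: grids differ in length")
  new_curve(curve_a$channel,
            curve_a$mean - curve_ref$mean,
            sqrt(curve_a$sd^2 + curve_ref$sd^2),
            min(curve_a$n_strides, curve_ref$n_strides),
            units = curve_a$units)
}

#' Per-segment 0D features for one participant
#'
#' Unweighted segment means of duty factor and normalised stride
#' frequency over each segment's strides.
#'
#' @param segments output of [select_segment_strides()].
#' @param leg_length leg length, m.
#' @return data frame with one row per segment: `segment`, `duty_factor`,
#'   `stride_frequency_norm`, `n_strides`.
#' @export
features_0d <- function(segments, leg_length) {
  rows <- lapply(segments, function(seg) {
    dfs <- vapply(seg$strides, duty_factor, 0)
    sfs <- vapply(seg$strides, stride_frequency_norm, 0,
                  leg_length = leg_length)
    data.frame(segment = seg$label, duty_factor = mean(dfs),
               stride_frequency_norm = mean(sfs),
               n_strides = length(seg$strides))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

stride_matrix <- function(strides, channel) {
  if (!length(strides)) insufficient_data_error("no strides supplied")
  if (!channel %in% colnames(strides[[1]]$registered))
    schema_error("channel '%s' not present in registered strides", channel)
  t(vapply(strides, function(s) s$registered[, channel],
           numeric(nrow(strides[[1]]$registered))))
}

new_curve <- function(channel, mean, sd, n, units = "deg",
                      participant = NA_character_, segment = NA_character_) {
  structure(
    list(channel = channel, mean = as.numeric(mean), sd = as.numeric(sd),
         n_strides = n, participant = participant, segment = segment,
         units = units),
    class = "curve_1d"
  )
}
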