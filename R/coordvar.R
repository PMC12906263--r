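# Coordination variability via the angular-velocity ellipse-area method:
# at each instant of the normalized stride, the stride-to-stride scatter of
# a joint coupling's angular-velocity pair is summarised by the area of
# its 95% prediction ellipse.

# chi-square(2 df) 0.95 quantile: scaling that makes the ellipse cover 95%
# of new bivariate-normal observations.
ellipse_scale_95 <- function() stats::qchisq(0.95, df = 2)

#' Registered angular velocity of a stride channel
#'
#' Differentiates the channel in original (unnormalised) time by central
#' differences — preserving physical deg/s magnitudes — and then registers
#' the velocity onto the stride's 201-point normalized-time grid by linear
#' interpolation. One-sided differences are used at the stride ends.
#'
#' @param stride a `stride` object carrying raw samples.
#' @param channel channel name.
#' @return numeric vector of 201 velocities, deg/s.
#' @export
angular_velocity <- function(stride, channel) {
  tt <- stride$raw_times
  if (length(tt) < 5)
    data_error("invalid stride: too few samples (%d) to differentiate",
               length(tt))
  if (!channel %in% colnames(stride$raw))
    schema_error("channel '%s' not present in stride", channel)
  x <- stride$raw[, channel]
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  # second-order one-sided differences at the stride ends
  v[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (tt[3] - tt[1])
  v[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (tt[n] - tt[n - 2])
  grid <- seq(stride$start_time, stride$end_time,
              length.out = nrow(stride$registered))
  stats::approx(tt, v, xout = grid)$y
}

#' Ellipse-area coordination variability of a joint coupling
#'
#' At each of the 201 normalized-time points, the 2x2 sample covariance of
#' the two channels' angular velocities across strides is computed; with
#' eigenvalues `l1, l2`, the area of the ellipse scaled to contain 95% of
#' hypothetical new observations is `pi * c * sqrt(l1 * l2)` where `c` is
#' the 0.95 quantile of the chi-square distribution with 2 df (about
#' 5.9915). Larger area means less stride-to-stride consistency of the
#' coupling at that instant.
#'
#' @param strides list of at least three `stride` objects.
#' @param coupling character pair of channel names, e.g.
#'   `c("hip", "knee")`.
#' @return a `coupling_cv` object: `coupling`, 201-point `area`
#'   (deg^2/s^2), `n_strides`.
#' @export
ellipse_area_series <- function(strides, coupling) {
  if (length(strides) < 3)
    insufficient_data_error("ellipse_area_series: need >= 3 strides, got %d",
                            length(strides))
  if (length(coupling) != 2)
    param_error("coupling must name exactly two channels")
  v1 <- t(vapply(strides, angular_velocity, numeric(201), channel = coupling[1]))
  v2 <- t(vapply(strides, angular_velocity, numeric(201), channel = coupling[2]))
  if (!all(is.finite(v1)) || !all(is.finite(v2)))
    data_error("non-finite angular velocities in coupling %s-%s",
               coupling[1], coupling[2])
  n <- nrow(v1)
  m1 <- colMeans(v1); m2 <- colMeans(v2)
  s11 <- (colSums(v1 * v1) - n * m1^2) / (n - 1)
  s22 <- (colSums(v2 * v2) - n * m2^2) / (n - 1)
  s12 <- (colSums(v1 * v2) - n * m1 * m2) / (n - 1)
  det <- pmax(s11 * s22 - s12^2, 0)   # clip tiny negative round-off
  structure(
    list(coupling = coupling,
         area = pi * ellipse_scale_95() * sqrt(det),
         n_strides = n,
         participant = NA_character_, segment = NA_character_),
    class = "coupling_cv"
  )
}

#' Area of the 95% prediction ellipse of a 2x2 covariance
#'
#' Closed form `pi * qchisq(0.95, 2) * sqrt(det(sigma))`; for an isotropic
#' covariance `sigma^2 * I` this is `pi * qchisq(0.95, 2) * sigma^2`.
#'
#' @param sigma 2x2 covariance matrix.
#' @return scalar area.
#' @export
ellipse_area <- function(sigma) {
  if (!is.matrix(sigma) || any(dim(sigma) != 2))
    param_error("sigma must be a 2x2 matrix")
  d <- det(sigma)
  if (d < 0) d <- 0
  pi * ellipse_scale_95() * sqrt(d)
}

#' Monte-Carlo coverage of the scaled prediction ellipse
#'
#' Draws fresh bivariate-normal samples from `sigma` and reports the
#' fraction falling inside the 95% ellipse (squared Mahalanobis distance
#' below the chi-square(2) 0.95 quantile). Converges to 0.95 for any
#' positive-definite covariance; used to validate the scaling constant
#' rather than assume it.
#'
#' @param sigma 2x2 positive-definite covariance matrix.
#' @param n number of draws.
#' @return fraction of draws inside the ellipse.
#' @export
ellipse_coverage <- function(sigma, n = 1e5) {
  L <- chol(sigma)
  z <- matrix(stats::rnorm(2 * n), ncol = 2) %*% L
  d2 <- stats::mahalanobis(z, center = c(0, 0), cov = sigma)
  mean(d2 <= ellipse_scale_95())
}

# The couplings analysed by default, proximal channel first.
DEFAULT_COUPLINGS <- list(
  c("trunk_pelvis", "hip"),
  c("hip", "knee"),
  c("knee", "ankle")
)
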