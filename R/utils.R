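# Interval helpers. Windows are two-column matrices [start, end), seconds.

as_windows <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), ncol = 2))
  if (is.matrix(x)) return(x)
  if (is.list(x)) return(do.call(rbind, lapply(x, function(w) w[1:2])))
  matrix(x, ncol = 2, byrow = TRUE)
}

# Intersect every window with [lo, hi]; drop empty results.
clip_windows <- function(windows, lo, hi) {
  w <- as_windows(windows)
  if (nrow(w) == 0) return(w)
  s <- pmax(w[, 1], lo)
  e <- pmin(w[, 2], hi)
  keep <- e > s
  cbind(s[keep], e[keep])
}

in_windows <- function(t, windows) {
  w <- as_windows(windows)
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(w))) out <- out | (t >= w[i, 1] & t < w[i, 2])
  out
}

# TRUE when [a, b] lies entirely inside a single window.
span_in_windows <- function(a, b, windows) {
  w <- as_windows(windows)
  any(w[, 1] <= a & b <= w[, 2])
}

# Smoothly tapered indicator of a phase window [a, b] (stride fraction),
# with raised-cosine edges of width `edge` inside the window. Used both to
# inject fatigue deltas band-limited in phase and to gate swing-phase noise.
phase_taper <- function(phi, window, edge = 0.03) {
  a <- window[1]; b <- window[2]
  out <- numeric(length(phi))
  rise <- phi >= a & phi < a + edge
  flat <- phi >= a + edge & phi <= b - edge
  fall <- phi > b - edge & phi <= b
  out[rise] <- 0.5 - 0.5 * cos(pi * (phi[rise] - a) / edge)
  out[flat] <- 1
  out[fall] <- 0.5 - 0.5 * cos(pi * (b - phi[fall]) / edge)
  out
}

sample_sd_cols <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(colSums(m * m) - n * mu^2, 0) / (n - 1))
}
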