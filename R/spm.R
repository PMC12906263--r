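# Nonparametric statistical parametric mapping (SPM): permutation-based
# two-way mixed-design repeated-measures ANOVA over 201-point kinematic
# continua, with suprathreshold-cluster inference, plus post hoc t
# continua.
#
# The family-wise critical threshold for each effect is the k-th largest
# of the B permutation maxima of the statistic continuum, with
# k = floor(alpha * (B + 1)); an observed continuum is significant where
# it strictly exceeds that threshold (exact level k/(B+1) under
# exchangeability). Cluster p-values use suprathreshold extent:
# p = (1 + #{permutations whose largest suprathreshold extent >= observed
# extent}) / (B + 1).

#' Study design for the two-way mixed-model comparisons
#'
#' @param subject subject identifiers, one entry per observation.
#' @param segment within-subject factor (trial segment: start, middle,
#'   end), one entry per observation.
#' @param cluster between-subject factor (technique cluster), one entry
#'   per observation; must be constant within subject.
#' @param alpha family-wise significance level.
#' @param n_perm number of label permutations (exhaustive enumeration is
#'   used instead when the total number of arrangements is at most
#'   `n_perm`).
#' @param seed optional RNG seed for the permutation draws.
#' @return a `spm_design` list after validation.
#' @export
spm_design <- function(subject, segment, cluster, alpha = 0.05,
                       n_perm = 10000, seed = NULL) {
  subject <- as.factor(subject)
  segment <- as.factor(segment)
  cluster <- as.factor(cluster)
  if (alpha <= 0 || alpha >= 1) design_error("alpha must lie in (0, 1)")
  tab <- table(subject, segment)
  if (any(tab != 1))
    design_error("unbalanced design: every subject must contribute each segment exactly once")
  cl_by_sub <- tapply(as.character(cluster), subject,
                      function(x) length(unique(x)))
  if (any(cl_by_sub != 1))
    design_error("cluster must be constant within subject")
  cl_sub <- factor(tapply(as.character(cluster), subject, `[`, 1),
                   levels = levels(cluster))
  if (any(table(cl_sub) < 2))
    design_error("need at least 2 subjects per cluster")
  if (n_perm < 100)
    warning("n_perm < 100 gives a very coarse permutation distribution")
  structure(
    list(subject = subject, segment = segment, cluster = cluster,
         cluster_by_subject = cl_sub, alpha = alpha,
         n_perm = as.integer(n_perm), seed = seed),
    class = "spm_design"
  )
}

# ---- shared sums-of-squares kernel -------------------------------------
# Y: (n_obs x P) matrix, one row per subject x segment observation.
# Verified against stats::aov on unbalanced toy designs (exact agreement).
mixed_ss <- function(Y, subject, segment, cl_sub) {
  s <- nlevels(segment)
  N <- nlevels(subject)
  n_c <- as.numeric(table(cl_sub))
  C <- length(n_c)
  sub_i <- as.integer(subject)
  seg_i <- as.integer(segment)
  cl_i <- as.integer(cl_sub)

  Si <- rowsum(Y, sub_i, reorder = TRUE) / s          # N x P
  m <- colMeans(Y)                                     # P
  Mc <- rowsum(Si, cl_i, reorder = TRUE) / n_c         # C x P
  Ms <- rowsum(Y, seg_i, reorder = TRUE) / N           # s x P
  cell_id <- cl_i[sub_i] + C * (seg_i - 1)
  Cell <- rowsum(Y, cell_id, reorder = TRUE) /
    rep(n_c, times = s)                                # (C*s) x P

  dev_c <- sweep(Mc, 2, m)
  SSC <- s * colSums(n_c * dev_c^2)
  SSsub <- s * colSums((Si - Mc[cl_i, , drop = FALSE])^2)
  SSS <- N * colSums(sweep(Ms, 2, m)^2)
  exp_cell <- Mc[rep(seq_len(C), times = s), , drop = FALSE] +
    Ms[rep(seq_len(s), each = C), , drop = FALSE]
  dev_int <- Cell - exp_cell + matrix(m, C * s, length(m), byrow = TRUE)
  SSint <- colSums(rep(n_c, times = s) * dev_int^2)
  SSwtot <- colSums((Y - Si[sub_i, , drop = FALSE])^2)
  SSE <- pmax(SSwtot - SSS - SSint, 0)

  list(SSC = SSC, SSsub = SSsub, SSS = SSS, SSint = SSint, SSE = SSE,
       df = list(C = C - 1, sub = N - C, S = s - 1,
                 int = (C - 1) * (s - 1), err = (N - C) * (s - 1)))
}

safe_f <- function(ss_num, df_num, ss_den, df_den) {
  f <- (ss_num / df_num) / (ss_den / df_den)
  f[ss_num == 0] <- 0
  f
}

mixed_f_continua <- function(Y, subject, segment, cl_sub) {
  ss <- mixed_ss(Y, subject, segment, cl_sub)
  d <- ss$df
  list(
    cluster = safe_f(ss$SSC, d$C, ss$SSsub, d$sub),
    exhaustion = safe_f(ss$SSS, d$S, ss$SSE, d$err),
    interaction = safe_f(ss$SSint, d$int, ss$SSE, d$err),
    df = d
  )
}

# One-way F continuum across cluster labels on subject-mean curves
# (identical to the mixed-design between-subjects F).
oneway_f <- function(Si, cl_i, n_c) {
  m <- colMeans(Si)
  Mc <- rowsum(Si, cl_i, reorder = TRUE) / n_c
  SSB <- colSums(n_c * sweep(Mc, 2, m)^2)
  SSW <- colSums((Si - Mc[cl_i, , drop = FALSE])^2)
  C <- length(n_c); N <- nrow(Si)
  safe_f(SSB, C - 1, SSW, N - C)
}

# ---- suprathreshold clusters -------------------------------------------
clusters_above <- function(stat, thr) {
  above <- stat > thr
  if (!any(above))
    return(data.frame(start_pct = numeric(0), end_pct = numeric(0),
                      extent = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(
    start_pct = (starts[keep] - 1) / (length(stat) - 1) * 100,
    end_pct = (ends[keep] - 1) / (length(stat) - 1) * 100,
    extent = r$lengths[keep]
  )
}

max_extent <- function(stat, thr) {
  above <- stat > thr
  if (!any(above)) return(0L)
  r <- rle(above)
  max(r$lengths[r$values])
}

perm_threshold <- function(max_stats, alpha) {
  B <- length(max_stats)
  k <- max(1L, floor(alpha * (B + 1)))
  sort(max_stats, decreasing = TRUE)[k]
}

new_spm_result <- function(effect, stat, thr, clusters, alpha, n_perm,
                           statistic = "F") {
  structure(
    list(effect = effect, statistic = statistic, statistic_curve = stat,
         critical_threshold = thr, clusters = clusters, alpha = alpha,
         n_perm = n_perm),
    class = "spm_result"
  )
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("SPM %s continuum, effect: %s\n", x$statistic, x$effect))
  cat(sprintf("  critical threshold (alpha=%g, %d permutations): %.3f\n",
              x$alpha, x$n_perm, x$critical_threshold))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: %.1f-%.1f%% of stride, p = %.4g\n",
                  i, x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$p[i]))
  }
  invisible(x)
}

# ---- permutation schemes ------------------------------------------------

# Between-subjects: permutations of cluster labels across subjects.
# Exhaustive (all label assignments) when feasible.
between_perms <- function(cl_i, n_perm) {
  N <- length(cl_i)
  n1 <- sum(cl_i == 1)
  total <- choose(N, n1)
  if (total <= n_perm) {
    combos <- utils::combn(N, n1)
    lapply(seq_len(ncol(combos)), function(j) {
      lab <- rep(2L, N); lab[combos[, j]] <- 1L; lab
    })
  } else {
    lapply(seq_len(n_perm), function(j) sample(cl_i))
  }
}

# Within-subject: independent permutation of segment labels inside each
# subject. Exhaustive ((s!)^N arrangements) when feasible.
within_perms <- function(N, s, n_perm) {
  perms_s <- all_perms(s)
  total <- nrow(perms_s)^N
  if (total <= n_perm) {
    idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms_s))), N)))
    lapply(seq_len(nrow(idx)), function(j)
      lapply(seq_len(N), function(i) perms_s[idx[j, i], ]))
  } else {
    lapply(seq_len(n_perm), function(j)
      lapply(seq_len(N), function(i) sample.int(s)))
  }
}

all_perms <- function(s) {
  if (s == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(s - 1)
  out <- NULL
  for (pos in seq_len(s)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], s,
                   sub[, seq(pos, s - 1)[seq_len(s - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  out
}

# ---- main entry points --------------------------------------------------

#' Permutation-based two-way mixed-design SPM ANOVA on curves
#'
#' Tests the between-subject (cluster), within-subject (exhaustion
#' segment) and interaction effects pointwise along 201-point kinematic
#' continua, with family-wise inference from the permutation distribution
#' of the continuum maximum F. Permutation schemes follow restricted-
#' permutation practice for mixed designs: cluster labels are permuted
#' across subjects (on subject-mean curves) for the between effect;
#' segment labels are permuted within each subject for the within effect;
#' and within-subject residuals (after removing subject and segment
#' means) are permuted within subjects for the interaction.
#'
#' @param Y numeric matrix, one row per subject-by-segment observation
#'   (aligned with the design), one column per continuum point.
#' @param design a [spm_design()].
#' @return named list of three `spm_result` objects (`cluster`,
#'   `exhaustion`, `interaction`), each with the observed F continuum,
#'   the permutation critical threshold, and suprathreshold clusters with
#'   extent-based p-values.
#' @export
spm_anova2_rm <- function(Y, design) {
  stopifnot(inherits(design, "spm_design"))
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  if (nrow(Y) != length(design$subject))
    design_error("Y must have one row per subject x segment observation")
  if (!is.null(design$seed)) set.seed(design$seed)

  subject <- design$subject
  segment <- design$segment
  cl_sub <- design$cluster_by_subject
  s <- nlevels(segment)
  N <- nlevels(subject)
  n_c <- as.numeric(table(cl_sub))
  cl_i <- as.integer(cl_sub)
  sub_i <- as.integer(subject)
  seg_i <- as.integer(segment)
  alpha <- design$alpha
  B <- design$n_perm

  obs <- mixed_f_continua(Y, subject, segment, cl_sub)
  Si <- rowsum(Y, sub_i, reorder = TRUE) / s

  # between: one-way F on subject means under cluster-label permutation
  perms_b <- between_perms(cl_i, B)
  stat_b <- lapply(perms_b, function(lab) oneway_f(Si, lab, n_c))
  res_cluster <- finish_effect("cluster", obs$cluster, stat_b, alpha, B)

  # within: segment-label permutation inside each subject
  perms_w <- within_perms(N, s, B)
  stat_w <- lapply(perms_w, function(pl) {
    seg_perm <- permute_segments(seg_i, sub_i, pl)
    ss <- mixed_ss_within(Y, sub_i, seg_perm, cl_i, n_c, N, s)
    safe_f(ss$SSS, s - 1, ss$SSE, (N - length(n_c)) * (s - 1))
  })
  res_within <- finish_effect("exhaustion", obs$exhaustion, stat_w, alpha, B)

  # interaction: permute within-subject residual curves across segments
  m <- colMeans(Y)
  Ms <- rowsum(Y, seg_i, reorder = TRUE) / N
  R <- Y - Si[sub_i, , drop = FALSE] - Ms[seg_i, , drop = FALSE] +
    matrix(m, nrow(Y), ncol(Y), byrow = TRUE)
  perms_i <- within_perms(N, s, B)
  stat_i <- lapply(perms_i, function(pl) {
    seg_perm <- permute_segments(seg_i, sub_i, pl)
    ss <- mixed_ss_within(R, sub_i, seg_perm, cl_i, n_c, N, s)
    C <- length(n_c)
    safe_f(ss$SSint, (C - 1) * (s - 1), ss$SSE, (N - C) * (s - 1))
  })
  res_int <- finish_effect("interaction", obs$interaction, stat_i, alpha, B)

  list(cluster = res_cluster, exhaustion = res_within,
       interaction = res_int)
}

# Relabel each subject's segment indices by its permutation.
permute_segments <- function(seg_i, sub_i, perm_list) {
  out <- seg_i
  for (i in seq_along(perm_list)) {
    rows <- which(sub_i == i)
    out[rows] <- perm_list[[i]][seg_i[rows]]
  }
  out
}

# Within-stratum SS (segment + interaction + error) for a given segment
# relabelling; subject means are invariant so SSwtot is reusable, but we
# recompute it here for clarity at modest cost.
mixed_ss_within <- function(Y, sub_i, seg_i, cl_i, n_c, N, s) {
  Si <- rowsum(Y, sub_i, reorder = TRUE) / s
  m <- colMeans(Y)
  C <- length(n_c)
  Ms <- rowsum(Y, seg_i, reorder = TRUE) / N
  Mc <- rowsum(Si, cl_i, reorder = TRUE) / n_c
  cell_id <- cl_i[sub_i] + C * (seg_i - 1)
  Cell <- rowsum(Y, cell_id, reorder = TRUE) / rep(n_c, times = s)
  SSS <- N * colSums(sweep(Ms, 2, m)^2)
  exp_cell <- Mc[rep(seq_len(C), times = s), , drop = FALSE] +
    Ms[rep(seq_len(s), each = C), , drop = FALSE]
  dev_int <- Cell - exp_cell + matrix(m, C * s, length(m), byrow = TRUE)
  SSint <- colSums(rep(n_c, times = s) * dev_int^2)
  SSwtot <- colSums((Y - Si[sub_i, , drop = FALSE])^2)
  SSE <- pmax(SSwtot - SSS - SSint, 0)
  list(SSS = SSS, SSint = SSint, SSE = SSE)
}

finish_effect <- function(effect, obs_stat, perm_stats, alpha, n_perm) {
  max_f <- vapply(perm_stats, max, 0)
  thr <- perm_threshold(max_f, alpha)
  cl <- clusters_above(obs_stat, thr)
  if (nrow(cl) > 0) {
    exts <- vapply(perm_stats, max_extent, 0L, thr = thr)
    cl$p <- vapply(cl$extent, function(e)
      (1 + sum(exts >= e)) / (length(exts) + 1), 0)
  } else {
    cl$p <- numeric(0)
  }
  new_spm_result(effect, obs_stat, thr, cl, alpha, length(perm_stats))
}

#' Post hoc SPM t continuum between two conditions
#'
#' Paired contrasts (segment vs segment) use the one-sample t continuum
#' of the per-subject difference curves with sign-flipping permutations;
#' unpaired contrasts (cluster vs cluster) use the pooled two-sample t
#' continuum with group-label exchange. Inference is two-sided on |t|;
#' the supplied `alpha` should already carry any Bonferroni adjustment
#' for the family of post hoc contrasts. Exhaustive enumeration (all
#' 2^n sign patterns / label assignments) replaces random sampling when
#' it fits within `n_perm`.
#'
#' @param curves_a,curves_b numeric matrices (subjects x points); aligned
#'   by row when `paired`.
#' @param paired logical.
#' @param alpha adjusted significance level for this contrast.
#' @param n_perm permutation count.
#' @param seed optional RNG seed.
#' @return an `spm_result` with the signed t continuum, the |t| critical
#'   threshold, and suprathreshold clusters of |t|.
#' @export
spm_posthoc_t <- function(curves_a, curves_b, paired = TRUE,
                          alpha = 0.05, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- as.matrix(curves_a)
  Bm <- as.matrix(curves_b)
  if (ncol(A) != ncol(Bm))
    design_error("condition curves must share the grid")
  if (paired) {
    if (nrow(A) != nrow(Bm))
      design_error("paired contrast requires the same subjects in both conditions")
    D <- A - Bm
    n <- nrow(D)
    t_obs <- paired_t(D)
    total <- 2^n
    flips <- if (total <= n_perm) {
      m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      lapply(seq_len(nrow(m)), function(j) m[j, ])
    } else {
      lapply(seq_len(n_perm), function(j)
        sample(c(-1, 1), n, replace = TRUE))
    }
    perm_stats <- lapply(flips, function(s) abs(paired_t(D * s)))
  } else {
    n1 <- nrow(A); n2 <- nrow(Bm)
    X <- rbind(A, Bm)
    t_obs <- two_sample_t(X, n1)
    total <- choose(n1 + n2, n1)
    assigns <- if (total <= n_perm) {
      combos <- utils::combn(n1 + n2, n1)
      lapply(seq_len(ncol(combos)), function(j) combos[, j])
    } else {
      lapply(seq_len(n_perm), function(j) sample.int(n1 + n2, n1))
    }
    perm_stats <- lapply(assigns, function(g1)
      abs(two_sample_t(rbind(X[g1, , drop = FALSE],
                             X[-g1, , drop = FALSE]), n1)))
  }
  max_t <- vapply(perm_stats, max, 0)
  thr <- perm_threshold(max_t, alpha)
  cl <- clusters_above(abs(t_obs), thr)
  if (nrow(cl) > 0) {
    exts <- vapply(perm_stats, max_extent, 0L, thr = thr)
    cl$p <- vapply(cl$extent, function(e)
      (1 + sum(exts >= e)) / (length(exts) + 1), 0)
  } else {
    cl$p <- numeric(0)
  }
  new_spm_result(if (paired) "paired contrast" else "two-sample contrast",
                 t_obs, thr, cl, alpha, length(perm_stats),
                 statistic = "t")
}

paired_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  se <- sample_sd_cols(D) / sqrt(n)
  t <- m / se
  t[se == 0] <- 0
  t
}

two_sample_t <- function(X, n1) {
  n2 <- nrow(X) - n1
  A <- X[seq_len(n1), , drop = FALSE]
  Bm <- X[-seq_len(n1), , drop = FALSE]
  m1 <- colMeans(A); m2 <- colMeans(Bm)
  v1 <- sample_sd_cols(A)^2
  v2 <- sample_sd_cols(Bm)^2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  t
}
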