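# Conventional 0D statistics: two-way mixed-design repeated-measures
# ANOVA, Bonferroni-corrected post hoc t-tests with Cohen's d, and
# baseline group comparisons (Shapiro-Wilk-gated t / Mann-Whitney U,
# chi-squared for categorical variables).

#' Two-way mixed-design repeated-measures ANOVA on scalars
#'
#' Classical univariate decomposition for one between-subject factor
#' (cluster) crossed with one within-subject factor (segment): the
#' cluster effect is tested against subjects-within-cluster, the segment
#' and interaction effects against the segment-by-subject-within-cluster
#' residual. No sphericity correction is applied.
#'
#' @param values numeric vector, one observation per subject x segment.
#' @param design a [spm_design()] aligned with `values`.
#' @return data frame with rows `cluster`, `exhaustion`, `interaction`:
#'   `df1`, `df2`, `F`, `p`.
#' @export
anova0d_rm <- function(values, design) {
  stopifnot(inherits(design, "spm_design"))
  if (length(values) != length(design$subject))
    design_error("values must align with the design")
  ss <- mixed_ss(matrix(values, ncol = 1), design$subject, design$segment,
                 design$cluster_by_subject)
  d <- ss$df
  f <- c(
    cluster = safe_f(ss$SSC, d$C, ss$SSsub, d$sub),
    exhaustion = safe_f(ss$SSS, d$S, ss$SSE, d$err),
    interaction = safe_f(ss$SSint, d$int, ss$SSE, d$err)
  )
  df1 <- c(d$C, d$S, d$int)
  df2 <- c(d$sub, d$err, d$err)
  p <- ifelse(f == 0, 1, stats::pf(f, df1, df2, lower.tail = FALSE))
  data.frame(effect = c("cluster", "exhaustion", "interaction"),
             df1 = df1, df2 = df2, F = as.numeric(f), p = as.numeric(p),
             row.names = NULL)
}

#' Bonferroni-corrected post hoc comparison with effect size
#'
#' A t-test between two sets of scalars (paired for segment contrasts,
#' independent for cluster contrasts), with the raw p-value multiplied by
#' the number of comparisons in the family (capped at 1), Cohen's d
#' (mean difference over the SD of differences when paired, pooled SD
#' when unpaired), and a large-sample normal-approximation 95% CI for d.
#'
#' @param values_a,values_b numeric vectors; aligned by subject when
#'   `paired`.
#' @param paired logical.
#' @param m_comparisons Bonferroni family size.
#' @return one-row data frame: `t`, `p_adjusted`, `d`, `d_ci_lower`,
#'   `d_ci_upper`, `n_a`, `n_b`.
#' @export
posthoc_0d <- function(values_a, values_b, paired = TRUE,
                       m_comparisons = 1) {
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) < 2 || length(b) < 2)
    insufficient_data_error("posthoc_0d: need n >= 2 per group")
  if (paired && length(a) != length(b))
    design_error("paired comparison requires equal-length, subject-aligned vectors")
  if (paired) {
    dd <- a - b
    n <- length(dd)
    sdd <- stats::sd(dd)
    if (sdd == 0) {
      t_stat <- 0
      p_raw <- 1
      d <- 0
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      t_stat <- unname(tt$statistic)
      p_raw <- tt$p.value
      d <- mean(dd) / sdd
    }
    se_d <- sqrt(1 / n + d^2 / (2 * (n - 1)))
  } else {
    n1 <- length(a); n2 <- length(b)
    sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
                 (n1 + n2 - 2))
    if (sp == 0) {
      t_stat <- 0
      p_raw <- 1
      d <- 0
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      t_stat <- unname(tt$statistic)
      p_raw <- tt$p.value
      d <- (mean(a) - mean(b)) / sp
    }
    se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  }
  data.frame(
    t = t_stat,
    p_adjusted = min(1, p_raw * m_comparisons),
    d = d,
    d_ci_lower = d - stats::qnorm(0.975) * se_d,
    d_ci_upper = d + stats::qnorm(0.975) * se_d,
    n_a = length(a), n_b = length(b)
  )
}

#' Baseline comparison of participant characteristics between clusters
#'
#' For each numeric variable, a Shapiro-Wilk test is run on each cluster;
#' when both pass at 0.05 an equal-variance independent-groups t-test is
#' used, otherwise a Mann-Whitney U test. Categorical variables are
#' compared with a chi-squared test (no continuity correction). Constant
#' variables are flagged and left untested.
#'
#' @param table data frame of per-participant scalars/categories with a
#'   `cluster` column.
#' @param cluster_col name of the grouping column.
#' @return data frame: `variable`, `test` (`t`, `U`, `X2` or `none`),
#'   `statistic`, `p`.
#' @export
baseline_compare <- function(table, cluster_col = "cluster") {
  if (!cluster_col %in% names(table))
    schema_error("baseline_compare: missing grouping column '%s'", cluster_col)
  grp <- factor(table[[cluster_col]])
  if (nlevels(grp) != 2)
    design_error("baseline_compare: expected exactly 2 clusters")
  if (any(base::table(grp) < 3))
    insufficient_data_error("baseline_compare: need >= 3 participants per cluster")
  vars <- setdiff(names(table), cluster_col)
  rows <- lapply(vars, function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      a <- x[grp == levels(grp)[1]]
      b <- x[grp == levels(grp)[2]]
      if (stats::sd(x) == 0)
        return(data.frame(variable = v, test = "none",
                          statistic = NA_real_, p = NA_real_))
      normal <- stats::sd(a) > 0 && stats::sd(b) > 0 &&
        stats::shapiro.test(a)$p.value > 0.05 &&
        stats::shapiro.test(b)$p.value > 0.05
      if (normal) {
        tt <- stats::t.test(a, b, var.equal = TRUE)
        data.frame(variable = v, test = "t",
                   statistic = unname(tt$statistic), p = tt$p.value)
      } else {
        wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
        data.frame(variable = v, test = "U",
                   statistic = unname(wt$statistic), p = wt$p.value)
      }
    } else {
      tab <- base::table(x, grp)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, test = "X2",
                 statistic = unname(ct$statistic), p = ct$p.value)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
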