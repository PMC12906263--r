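# Brute-force sums-of-squares oracle: plain loops over the cell means,
# independent of the package's vectorized kernel.
brute_force_mixed_anova <- function(d) {
  subs <- unique(d$subject)
  segs <- unique(d$segment)
  cls <- unique(d$cluster)
  N <- length(subs); s <- length(segs); C <- length(cls)
  cl_of <- sapply(subs, function(i) unique(d$cluster[d$subject == i]))
  n_c <- sapply(cls, function(c) sum(cl_of == c))
  m <- mean(d$y)
  m_i <- sapply(subs, function(i) mean(d$y[d$subject == i]))
  m_c <- sapply(cls, function(c) mean(m_i[cl_of == c]))
  m_s <- sapply(segs, function(g) mean(d$y[d$segment == g]))
  SSC <- 0; for (ci in seq_along(cls)) SSC <- SSC + s * n_c[ci] * (m_c[ci] - m)^2
  SSsub <- 0
  for (i in seq_along(subs))
    SSsub <- SSsub + s * (m_i[i] - m_c[match(cl_of[i], cls)])^2
  SSS <- 0; for (g in seq_along(segs)) SSS <- SSS + N * (m_s[g] - m)^2
  SSint <- 0
  for (ci in seq_along(cls)) for (g in seq_along(segs)) {
    cell <- mean(d$y[d$cluster == cls[ci] & d$segment == segs[g]])
    SSint <- SSint + n_c[ci] * (cell - m_c[ci] - m_s[g] + m)^2
  }
  SSW <- 0
  for (r in seq_len(nrow(d)))
    SSW <- SSW + (d$y[r] - m_i[match(d$subject[r], subs)])^2
  SSE <- SSW - SSS - SSint
  list(
    F_cluster = (SSC / (C - 1)) / (SSsub / (N - C)),
    F_seg = (SSS / (s - 1)) / (SSE / ((N - C) * (s - 1))),
    F_int = (SSint / ((C - 1) * (s - 1))) / (SSE / ((N - C) * (s - 1)))
  )
}

toy_design_data <- function(N = 4, n1 = 2, seed = 123) {
  set.seed(seed)
  segs <- c("start", "middle", "end")
  d <- expand.grid(segment = segs, subject = seq_len(N))
  d$cluster <- ifelse(d$subject <= n1, "neutral", "tilted")
  d$y <- stats::rnorm(nrow(d)) + 0.8 * (d$segment == "end") +
    0.5 * (d$cluster == "tilted") + stats::rnorm(N)[d$subject]
  d
}

test_that("mixed RM ANOVA matches the brute-force oracle and aov", {
  for (cse in list(c(4, 2, 123), c(7, 3, 99))) {
    d <- toy_design_data(cse[1], cse[2], cse[3])
    des <- spm_design(d$subject, d$segment, d$cluster, n_perm = 100)
    a <- suppressWarnings(anova0d_rm(d$y, des))
    bf <- brute_force_mixed_anova(d)
    expect_equal(a$F[a$effect == "cluster"], unname(bf$F_cluster),
                 tolerance = 1e-10)
    expect_equal(a$F[a$effect == "exhaustion"], unname(bf$F_seg),
                 tolerance = 1e-10)
    expect_equal(a$F[a$effect == "interaction"], unname(bf$F_int),
                 tolerance = 1e-10)

    # independent route: stats::aov error strata
    dd <- data.frame(y = d$y, subject = factor(d$subject),
                     segment = factor(d$segment),
                     cluster = factor(d$cluster))
    av <- summary(stats::aov(y ~ cluster * segment + Error(subject),
                             data = dd))
    f_btw <- av[["Error: subject"]][[1]]["cluster", "F value"]
    f_win <- av[["Error: Within"]][[1]][c("segment", "cluster:segment"),
                                        "F value"]
    expect_equal(a$F, unname(c(f_btw, f_win)), tolerance = 1e-8)
  }
})

test_that("degenerate and shifted inputs behave predictably", {
  d <- toy_design_data(4, 2)
  des <- spm_design(d$subject, d$segment, d$cluster, n_perm = 100)
  a0 <- suppressWarnings(anova0d_rm(rep(2.5, nrow(d)), des))
  expect_equal(a0$F, rep(0, 3))
  expect_equal(a0$p, rep(1, 3))

  a1 <- suppressWarnings(anova0d_rm(d$y, des))
  a2 <- suppressWarnings(anova0d_rm(d$y + 1000, des))
  expect_equal(a1$F, a2$F, tolerance = 1e-8)
})

test_that("design validation rejects unbalanced or degenerate layouts", {
  d <- toy_design_data(4, 2)
  expect_error(spm_design(d$subject[-1], d$segment[-1], d$cluster[-1]),
               class = "strideworks_design_error")
  expect_error(spm_design(d$subject, d$segment, d$cluster, alpha = 1.5),
               class = "strideworks_design_error")
  one_per <- d
  one_per$cluster <- ifelse(one_per$subject == 1, "neutral", "tilted")
  expect_error(spm_design(one_per$subject, one_per$segment, one_per$cluster),
               class = "strideworks_design_error")
  expect_warning(spm_design(d$subject, d$segment, d$cluster, n_perm = 50),
                 "n_perm")
})

test_that("post hoc t with effect size handles identity and known effects", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7)
  r <- posthoc_0d(x, x, paired = TRUE)
  expect_equal(r$t, 0)
  expect_equal(r$d, 0)
  expect_true(r$d_ci_lower <= 0 && r$d_ci_upper >= 0)

  set.seed(11)
  a <- stats::rnorm(30, 1, 1)
  b <- stats::rnorm(30, 0, 1)
  r2 <- posthoc_0d(a, b, paired = FALSE)
  expect_equal(r2$d, 1, tolerance = 0.5)
  expect_true(r2$d_ci_lower <= r2$d & r2$d <= r2$d_ci_upper)

  # Bonferroni triples the raw p before capping
  set.seed(12)
  a3 <- stats::rnorm(15); b3 <- stats::rnorm(15, 0.3)
  r_raw <- posthoc_0d(a3, b3, paired = FALSE, m_comparisons = 1)
  r_adj <- posthoc_0d(a3, b3, paired = FALSE, m_comparisons = 3)
  expect_equal(r_adj$p_adjusted, min(1, 3 * r_raw$p_adjusted))
})

test_that("baseline comparisons route by normality and handle categories", {
  set.seed(5)
  n <- 20
  tab <- data.frame(
    cluster = rep(c("neutral", "tilted"), each = n),
    gaussian = stats::rnorm(2 * n, 10, 1),
    skewed = stats::rlnorm(2 * n, 0, 1.5),
    sex = rep(c("F", "M"), n),
    constant = 1
  )
  out <- baseline_compare(tab)
  expect_identical(out$test[out$variable == "gaussian"], "t")
  expect_identical(out$test[out$variable == "skewed"], "U")
  expect_identical(out$test[out$variable == "sex"], "X2")
  expect_identical(out$test[out$variable == "constant"], "none")

  # identical category counts: X2 = 0, p = 1
  bal <- data.frame(cluster = rep(c("neutral", "tilted"), each = 20),
                    sex = rep(c("F", "M"), 20))
  ob <- baseline_compare(bal)
  expect_equal(ob$statistic, 0)
  expect_equal(ob$p, 1)
})
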