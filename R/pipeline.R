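# End-to-end orchestration: simulate -> prep -> features -> coordvar ->
# stats, with plain-text artifacts and a reproducibility manifest.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the synthetic cohort.
#' @param cutoff trajectory low-pass cutoff, Hz.
#' @param margin trial trim margin, s.
#' @param k strides per trial segment.
#' @param alpha family-wise significance level for all tests.
#' @param n_perm permutations for the 1D SPM tests.
#' @param seed RNG seed for the statistical stage.
#' @param channels 1D channels to analyse.
#' @param couplings list of channel pairs for coordination variability.
#' @param write_trials also write each simulated trial to disk (wide CSV
#'   + JSON sidecar); off by default because trials are large.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), cutoff = 10, margin = 10,
                            k = 50, alpha = 0.05, n_perm = 1000,
                            seed = 7L,
                            channels = c(ANGLE_CHANNELS, "vcom"),
                            couplings = DEFAULT_COUPLINGS,
                            write_trials = FALSE) {
  validate_sim_config(sim)
  if (alpha <= 0 || alpha >= 1) config_error("alpha", "must lie in (0, 1)")
  if (cutoff <= 0 || cutoff >= sim$sample_rate / 2)
    config_error("cutoff", "must lie in (0, Nyquist)")
  if (margin < 0 || sim$trial_duration <= 2 * margin)
    config_error("margin", "must leave a usable span")
  if (k < 1) config_error("k", "must be >= 1")
  if (n_perm < 1) config_error("n_perm", "must be >= 1")
  structure(
    list(sim = sim, cutoff = cutoff, margin = margin, k = k,
         alpha = alpha, n_perm = as.integer(n_perm),
         seed = as.integer(seed), channels = channels,
         couplings = couplings, write_trials = write_trials),
    class = "pipeline_config"
  )
}

# ---- stages -------------------------------------------------------------

#' Preprocess a simulated cohort
#'
#' Runs [prep_trial()] on every participant and keeps the per-segment
#' stride samples plus a participant metadata table.
#'
#' @param cohort output of [generate_cohort()].
#' @param config a `pipeline_config`.
#' @return list with `participants` (per-id `meta` + `segments`) and
#'   `meta_table`.
#' @export
stage_prep <- function(cohort, config) {
  participants <- lapply(cohort, function(p) {
    pr <- prep_trial(p$recording, cutoff = config$cutoff,
                     margin = config$margin, k = config$k)
    list(meta = p$recording$meta, segments = pr$segments)
  })
  meta_table <- do.call(rbind, lapply(participants, function(p)
    data.frame(participant = p$meta$id, cluster = p$meta$cluster,
               leg_length = p$meta$leg_length, sex = p$meta$sex)))
  rownames(meta_table) <- NULL
  list(participants = participants, meta_table = meta_table)
}

#' Extract 0D features and 1D ensemble curves from a prepped cohort
#'
#' @param prep output of [stage_prep()].
#' @param channels channels for the ensemble curves (`vcom` is
#'   re-referenced and leg-length normalised).
#' @return list with tidy `features` (participant, cluster, segment,
#'   variable, value) and `curves` (participant, cluster, segment,
#'   channel, point, mean, sd) tables.
#' @export
stage_features <- function(prep, channels = c(ANGLE_CHANNELS, "vcom")) {
  feats <- list()
  curves <- list()
  for (p in prep$participants) {
    f0 <- features_0d(p$segments, p$meta$leg_length)
    for (i in seq_len(nrow(f0))) {
      feats[[length(feats) + 1]] <- data.frame(
        participant = p$meta$id, cluster = p$meta$cluster,
        segment = f0$segment[i],
        variable = c("duty_factor", "stride_frequency_norm"),
        value = c(f0$duty_factor[i], f0$stride_frequency_norm[i])
      )
    }
    for (seg in p$segments) {
      for (ch in channels) {
        cv <- if (ch == "vcom") {
          vcom_curve(seg$strides, p$meta$leg_length)
        } else {
          ensemble_curve(seg$strides, ch)
        }
        curves[[length(curves) + 1]] <- data.frame(
          participant = p$meta$id, cluster = p$meta$cluster,
          segment = seg$label, channel = ch,
          point = 0:(length(cv$mean) - 1),
          mean = cv$mean, sd = cv$sd
        )
      }
    }
  }
  list(features = do.call(rbind, feats), curves = do.call(rbind, curves))
}

#' Compute coordination-variability series for a prepped cohort
#'
#' @param prep output of [stage_prep()].
#' @param couplings list of channel pairs.
#' @return tidy table (participant, cluster, segment, coupling, point,
#'   area).
#' @export
stage_coordvar <- function(prep, couplings = DEFAULT_COUPLINGS) {
  rows <- list()
  for (p in prep$participants) {
    for (seg in p$segments) {
      for (cp in couplings) {
        cv <- ellipse_area_series(seg$strides, cp)
        rows[[length(rows) + 1]] <- data.frame(
          participant = p$meta$id, cluster = p$meta$cluster,
          segment = seg$label, coupling = paste(cp, collapse = "-"),
          point = 0:(length(cv$area) - 1), area = cv$area
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Statistical comparison stage
#'
#' For every 0D variable: two-way mixed RM ANOVA plus Bonferroni post
#' hocs (with Cohen's d) for the effects found significant. For every
#' 1D channel and coupling: nonparametric SPM mixed ANOVA, with post hoc
#' t continua at `alpha/3` following significant effects. Baseline
#' participant characteristics are compared between clusters.
#'
#' @param features,curves,cv,meta_table stage outputs.
#' @param config a `pipeline_config`.
#' @return list: `anova0d`, `posthoc0d`, `spm` (nested per
#'   channel/effect), `spm_posthoc`, `baseline`.
#' @export
stage_stats <- function(features, curves, cv, meta_table, config) {
  set.seed(config$seed)
  alpha <- config$alpha
  B <- config$n_perm
  segs <- c("start", "middle", "end")
  pids <- meta_table$participant
  cl_of <- stats::setNames(meta_table$cluster, pids)

  subject <- factor(rep(pids, each = length(segs)), levels = pids)
  segment <- factor(rep(segs, times = length(pids)), levels = segs)
  cluster <- factor(cl_of[as.character(subject)])
  design <- spm_design(subject, segment, cluster, alpha = alpha,
                       n_perm = B)

  # ---- 0D ----
  an0 <- list(); ph0 <- list()
  for (v in unique(features$variable)) {
    val <- aligned_values(features[features$variable == v, ],
                          subject, segment)
    a <- anova0d_rm(val, design)
    a$variable <- v
    an0[[v]] <- a
    sig <- a$effect[a$p < alpha]
    if ("exhaustion" %in% sig || "interaction" %in% sig) {
      for (pair in list(c("middle", "start"), c("end", "start"),
                        c("end", "middle"))) {
        r <- posthoc_0d(val[segment == pair[1]], val[segment == pair[2]],
                        paired = TRUE, m_comparisons = 3)
        r$variable <- v
        r$contrast <- paste(pair, collapse = " vs ")
        ph0[[length(ph0) + 1]] <- r
      }
    }
    if ("cluster" %in% sig) {
      for (sg in segs) {
        idx <- segment == sg
        r <- posthoc_0d(val[idx & cluster == "tilted"],
                        val[idx & cluster == "neutral"],
                        paired = FALSE, m_comparisons = 3)
        r$variable <- v
        r$contrast <- paste("tilted vs neutral @", sg)
        ph0[[length(ph0) + 1]] <- r
      }
    }
  }

  # ---- 1D ----
  spm_res <- list(); spm_ph <- list()
  one_d <- c(
    stats::setNames(lapply(unique(curves$channel), function(ch)
      curve_matrix(curves[curves$channel == ch, ], "mean",
                   subject, segment)), unique(curves$channel)),
    stats::setNames(lapply(unique(cv$coupling), function(cp)
      curve_matrix(cv[cv$coupling == cp, ], "area",
                   subject, segment, key = "coupling")),
      unique(cv$coupling))
  )
  for (nm in names(one_d)) {
    Y <- one_d[[nm]]
    res <- spm_anova2_rm(Y, design)
    spm_res[[nm]] <- res
    if (nrow(res$exhaustion$clusters) > 0 ||
        nrow(res$interaction$clusters) > 0) {
      for (pair in list(c("middle", "start"), c("end", "start"),
                        c("end", "middle"))) {
        ph <- spm_posthoc_t(Y[segment == pair[1], , drop = FALSE],
                            Y[segment == pair[2], , drop = FALSE],
                            paired = TRUE, alpha = alpha / 3, n_perm = B)
        spm_ph[[paste0(nm, ": ", paste(pair, collapse = " vs "))]] <- ph
      }
    }
    if (nrow(res$cluster$clusters) > 0) {
      for (sg in segs) {
        idx <- segment == sg
        ph <- spm_posthoc_t(Y[idx & cluster == "tilted", , drop = FALSE],
                            Y[idx & cluster == "neutral", , drop = FALSE],
                            paired = FALSE, alpha = alpha / 3, n_perm = B)
        spm_ph[[paste0(nm, ": tilted vs neutral @ ", sg)]] <- ph
      }
    }
  }

  baseline <- if (all(base::table(meta_table$cluster) >= 3)) {
    baseline_compare(meta_table[, c("cluster", "leg_length", "sex")])
  } else {
    message("stage_stats: < 3 participants per cluster; baseline comparison skipped")
    data.frame(variable = character(0), test = character(0),
               statistic = numeric(0), p = numeric(0))
  }

  list(
    anova0d = do.call(rbind, an0),
    posthoc0d = if (length(ph0)) do.call(rbind, ph0) else NULL,
    spm = spm_res, spm_posthoc = spm_ph, baseline = baseline
  )
}

aligned_values <- function(df, subject, segment) {
  key <- paste(df$participant, df$segment)
  v <- stats::setNames(df$value, key)
  out <- v[paste(as.character(subject), as.character(segment))]
  if (anyNA(out)) schema_error("features table misses subject x segment cells")
  unname(out)
}

curve_matrix <- function(df, value_col, subject, segment, key = "channel") {
  want <- paste(as.character(subject), as.character(segment))
  split_key <- paste(df$participant, df$segment)
  rows <- split(df[[value_col]], split_key)
  n_pts <- length(rows[[1]])
  ord <- split(df$point, split_key)
  Y <- matrix(NA_real_, length(want), n_pts)
  for (i in seq_along(want)) {
    v <- rows[[want[i]]]
    if (is.null(v)) schema_error("curve table misses cell '%s'", want[i])
    Y[i, ] <- v[order(ord[[want[i]]])]
  }
  Y
}

# ---- orchestrator -------------------------------------------------------

#' Run the whole analysis pipeline
#'
#' simulate -> prep -> features -> coordvar -> stats. All stage outputs
#' are written as plain CSV/JSON under `out_dir`, together with a
#' manifest recording the package version, configuration, seeds,
#' per-stage row counts and MD5 checksums of every artifact. Identical
#' configuration and seeds give identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with all stage results and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- generate_cohort(config$sim)
  if (config$write_trials) {
    tdir <- file.path(out_dir, "trials")
    for (p in cohort) write_trial(p$recording, tdir, truth = p$truth)
  }

  prep <- stage_prep(cohort, config)
  feat <- stage_features(prep, config$channels)
  cv <- stage_coordvar(prep, config$couplings)
  stats_out <- stage_stats(feat$features, feat$curves, cv,
                           prep$meta_table, config)

  files <- c(
    write_table(prep$meta_table, file.path(out_dir, "participants.csv")),
    write_table(feat$features, file.path(out_dir, "features.csv")),
    write_table(feat$curves, file.path(out_dir, "curves.csv")),
    write_table(cv, file.path(out_dir, "coordination_variability.csv")),
    write_table(stats_out$anova0d, file.path(out_dir, "anova0d.csv")),
    write_table(stats_out$baseline, file.path(out_dir, "baseline.csv"))
  )
  if (!is.null(stats_out$posthoc0d))
    files <- c(files, write_table(stats_out$posthoc0d,
                                  file.path(out_dir, "posthoc0d.csv")))
  spm_json <- file.path(out_dir, "spm.json")
  jsonlite::write_json(
    list(spm = spm_summarise(stats_out$spm),
         posthoc = lapply(stats_out$spm_posthoc, spm_result_summary)),
    spm_json, auto_unbox = TRUE, digits = NA
  )
  files <- c(files, spm_json)

  manifest <- list(
    package = "strideworks",
    version = as.character(utils::packageVersion("strideworks")),
    sim_seed = config$sim$seed,
    stats_seed = config$seed,
    parameters = list(
      n_neutral = config$sim$n_neutral, n_tilted = config$sim$n_tilted,
      trial_duration = config$sim$trial_duration,
      sample_rate = config$sim$sample_rate, cutoff = config$cutoff,
      margin = config$margin, k = config$k, alpha = config$alpha,
      n_perm = config$n_perm
    ),
    rows = list(
      participants = nrow(prep$meta_table),
      features = nrow(feat$features),
      curves = nrow(feat$curves),
      coordination_variability = nrow(cv)
    ),
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(prep = prep, features = feat$features,
                 curves = feat$curves, cv = cv, stats = stats_out,
                 manifest = manifest, out_dir = out_dir))
}

spm_result_summary <- function(r) {
  list(effect = r$effect, statistic = r$statistic,
       critical_threshold = r$critical_threshold,
       alpha = r$alpha, n_perm = r$n_perm,
       clusters = r$clusters)
}

spm_summarise <- function(spm) {
  lapply(spm, function(effects) lapply(effects, spm_result_summary))
}

#' Summarise a pipeline run as a markdown report
#'
#' Tables of the 0D effects and post hocs, the 1D suprathreshold
#' intervals per effect and channel/coupling, quantile summaries of duty
#' factor and stride frequency per cluster and segment, and the baseline
#' comparison. Deterministic given the run outputs (idempotent).
#'
#' @param run result of [run_pipeline()], or an output directory
#'   containing its artifacts.
#' @param path optional file to write; defaults to `report.md` in the
#'   run's output directory.
#' @return invisibly, the report text.
#' @export
report <- function(run, path = NULL) {
  if (is.character(run)) {
    dir <- run
    need <- file.path(dir, c("features.csv", "anova0d.csv", "spm.json",
                             "baseline.csv"))
    if (!all(file.exists(need)))
      sw_stop("strideworks_stage_error",
              "report: missing stage outputs in %s (run the stats stage first)", dir)
    features <- utils::read.csv(file.path(dir, "features.csv"))
    anova0d <- utils::read.csv(file.path(dir, "anova0d.csv"))
    ph_file <- file.path(dir, "posthoc0d.csv")
    posthoc0d <- if (file.exists(ph_file)) utils::read.csv(ph_file) else NULL
    spm <- jsonlite::read_json(file.path(dir, "spm.json"),
                               simplifyVector = TRUE)
    baseline <- utils::read.csv(file.path(dir, "baseline.csv"))
    out_dir <- dir
  } else {
    features <- run$features
    anova0d <- run$stats$anova0d
    posthoc0d <- run$stats$posthoc0d
    spm <- list(spm = spm_summarise(run$stats$spm),
                posthoc = lapply(run$stats$spm_posthoc, spm_result_summary))
    baseline <- run$stats$baseline
    out_dir <- run$out_dir
  }
  lines <- c("# strideworks run report", "")

  lines <- c(lines, "## 0D variables by cluster and segment", "")
  for (v in unique(features$variable)) {
    lines <- c(lines, sprintf("### %s", v), "")
    sub <- features[features$variable == v, ]
    agg <- stats::aggregate(value ~ cluster + segment, sub, function(x)
      c(q25 = stats::quantile(x, 0.25), med = stats::median(x),
        q75 = stats::quantile(x, 0.75)))
    for (i in seq_len(nrow(agg)))
      lines <- c(lines, sprintf(
        "- %s / %s: median %.4f (IQR %.4f-%.4f)", agg$cluster[i],
        agg$segment[i], agg$value[i, 2], agg$value[i, 1], agg$value[i, 3]))
    lines <- c(lines, "")
  }

  lines <- c(lines, "## 0D mixed-design RM ANOVA", "")
  for (i in seq_len(nrow(anova0d)))
    lines <- c(lines, sprintf(
      "- %s, %s: F(%d, %d) = %.3f, p = %.4g", anova0d$variable[i],
      anova0d$effect[i], anova0d$df1[i], anova0d$df2[i], anova0d$F[i],
      anova0d$p[i]))
  lines <- c(lines, "")
  if (!is.null(posthoc0d) && nrow(posthoc0d) > 0) {
    lines <- c(lines, "## 0D post hoc comparisons (Bonferroni)", "")
    for (i in seq_len(nrow(posthoc0d)))
      lines <- c(lines, sprintf(
        "- %s, %s: t = %.3f, p_adj = %.4g, d = %.3f, 95%% CI [%.3f, %.3f]",
        posthoc0d$variable[i], posthoc0d$contrast[i], posthoc0d$t[i],
        posthoc0d$p_adjusted[i], posthoc0d$d[i], posthoc0d$d_ci_lower[i],
        posthoc0d$d_ci_upper[i]))
    lines <- c(lines, "")
  }

  lines <- c(lines, "## 1D SPM effects (suprathreshold intervals)", "")
  for (nm in names(spm$spm)) {
    for (eff in names(spm$spm[[nm]])) {
      r <- spm$spm[[nm]][[eff]]
      cl <- r$clusters
      if (is.null(cl) || (is.data.frame(cl) && nrow(cl) == 0) ||
          length(cl) == 0) next
      cl <- as.data.frame(cl)
      for (i in seq_len(nrow(cl)))
        lines <- c(lines, sprintf(
          "- %s, %s effect: %.1f-%.1f%% of stride (%s* = %.2f, p = %.4g)",
          nm, eff, cl$start_pct[i], cl$end_pct[i], r$statistic,
          r$critical_threshold, cl$p[i]))
    }
  }
  if (length(spm$posthoc) > 0) {
    lines <- c(lines, "", "## 1D post hoc contrasts", "")
    for (nm in names(spm$posthoc)) {
      r <- spm$posthoc[[nm]]
      cl <- as.data.frame(r$clusters)
      if (nrow(cl) == 0) next
      for (i in seq_len(nrow(cl)))
        lines <- c(lines, sprintf(
          "- %s: %.1f-%.1f%% of stride (t* = %.2f, p = %.4g)", nm,
          cl$start_pct[i], cl$end_pct[i], r$critical_threshold, cl$p[i]))
    }
  }

  lines <- c(lines, "", "## Baseline cluster comparison", "")
  for (i in seq_len(nrow(baseline)))
    lines <- c(lines, sprintf(
      "- %s: %s = %.3f, p = %.4g", baseline$variable[i],
      baseline$test[i], baseline$statistic[i], baseline$p[i]))

  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) path <- file.path(out_dir, "report.md")
  writeLines(txt, path)
  invisible(txt)
}
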