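#' Pipeline run configuration
#'
#' Combines a simulation configuration, per-track QC rules and
#' significance settings into a single serializable object. The four
#' tracks mirror the score pathways compared in the study design the
#' generator emulates: a sparse chip, a dense chip (taken as error-free),
#' imputed-sequence hard calls (accuracy-filtered), and imputed-sequence
#' dosages (all SNPs, uncertainty carried by the scores).
#'
#' @param sim A [sim_config()].
#' @param tracks Character subset of
#'   `c("chip", "dense", "iwgs_genotype", "iwgs_dosage")`.
#' @param qc Named list of [qc_rules()] per track (sensible defaults:
#'   the accuracy filter applies only to `iwgs_genotype`).
#' @param seq_rules [qc_rules()] for the sequence-variant filters
#'   applied before imputation.
#' @param alpha Type-1 error target.
#' @param window_bp QTL-region half-width in bp.
#' @param shared_threshold `"max-me"` (one threshold per run, from the
#'   largest per-track effective segment count) or `"per-track"`.
#' @param out_dir Optional directory for TSV artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       tracks = c("chip", "dense", "iwgs_genotype", "iwgs_dosage"),
                       qc = NULL, seq_rules = qc_rules(),
                       alpha = 0.05, window_bp = 5e5,
                       shared_threshold = c("max-me", "per-track"),
                       out_dir = NULL) {
  tracks <- match.arg(tracks, several.ok = TRUE)
  shared_threshold <- match.arg(shared_threshold)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (window_bp <= 0) stop("`window_bp` must be positive", call. = FALSE)
  default_qc <- list(
    chip = qc_rules(apply_r2_filter = FALSE),
    dense = qc_rules(apply_r2_filter = FALSE),
    iwgs_genotype = qc_rules(apply_r2_filter = TRUE),
    iwgs_dosage = qc_rules(apply_r2_filter = FALSE))
  if (!is.null(qc)) default_qc[names(qc)] <- qc
  cfg <- list(sim = sim, tracks = tracks, qc = default_qc,
              seq_rules = seq_rules, alpha = alpha, window_bp = window_bp,
              shared_threshold = shared_threshold, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full simulation-to-QTL pipeline for one line
#'
#' Stages: simulate haplotypes, genotypes, sequencing annotations and
#' trait; apply sequence-variant filters; simulate imputation with the
#' MAF-dependent accuracy curve; assemble the configured score tracks;
#' per track, apply QC, build leave-one-chromosome-out GRMs, run the
#' mixed-model scan, compute the inflation factor and effective segment
#' count, genomic-control-adjust, threshold and call QTL regions.
#' Fully deterministic given the configuration (which includes the
#' seed).
#'
#' @param config A [run_config()].
#' @return An object of class `run_artifacts`: `tracks` (per-track list
#'   with `assoc`, `lambda`, `me`, `threshold`, `regions`, `summary`,
#'   `qc_report`, `n_snps`), plus `trait`, `truth` (causal map rows),
#'   `config`, and `paths` when artifacts were written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  seed <- sim$seed

  hap <- simulate_haplotypes(sim)
  gp <- sample_genotypes(hap, sim$n_individuals, seed = seed, line = sim$line)
  ann <- simulate_sequencing(gp, mean_depth = sim$mean_depth, seed = seed,
                             qual_shift = sim$qual_shift,
                             qual_shape = sim$qual_shape,
                             qual_scale = sim$qual_scale,
                             missing_rate = sim$missing_rate)
  trait <- simulate_trait(gp, sim$n_causal, sim$h2, sim$pheno_var, seed = seed)
  y <- trait$phenotype

  svf <- sequence_variant_filter(gp, ann, config$seq_rules)
  seq_keep <- svf$report$keep
  masked <- svf$panel

  p_emp <- colMeans(masked$calls, na.rm = TRUE) / 2
  maf <- pmin(p_emp, 1 - p_emp)
  r2_targets <- target_accuracy(pmin(pmax(maf, 0), 0.5),
                                plateau = sim$accuracy_plateau,
                                scale = sim$accuracy_scale)
  dp <- simulate_imputation(masked, r2_targets, seed = seed)

  chip_idx <- spaced_subset(maf, sim$chip_fraction, sim$maf_spectrum$rare_max %||% 0.01)
  dense_idx <- spaced_subset(maf, sim$dense_fraction, sim$maf_spectrum$rare_max %||% 0.01)

  track_data <- list()
  for (tr in config$tracks) {
    track_data[[tr]] <- switch(tr,
      chip = list(x = gp$calls[, chip_idx, drop = FALSE],
                  map = gp$map[chip_idx, , drop = FALSE],
                  score = "genotype", dp = NULL),
      dense = list(x = gp$calls[, dense_idx, drop = FALSE],
                   map = gp$map[dense_idx, , drop = FALSE],
                   score = "genotype", dp = NULL),
      iwgs_genotype = list(x = dp$hard_call[, seq_keep, drop = FALSE],
                           map = gp$map[seq_keep, , drop = FALSE],
                           score = "genotype",
                           dp = subset_dosage(dp, seq_keep)),
      iwgs_dosage = list(x = dp$dosage[, seq_keep, drop = FALSE],
                         map = gp$map[seq_keep, , drop = FALSE],
                         score = "dosage",
                         dp = subset_dosage(dp, seq_keep)))
  }

  artifacts <- list(tracks = list(), trait = trait,
                    truth = gp$map[trait$causal_idx, , drop = FALSE],
                    config = config)
  artifacts$truth$effect <- trait$effects
  artifacts$truth$target_r2 <- dp$target_r2[trait$causal_idx]

  for (tr in names(track_data)) {
    td <- track_data[[tr]]
    rules <- config$qc[[tr]]

    if (td$score == "dosage") {
      # dosage carries no discrete genotype classes: MAF/map filters only
      pd <- colMeans(td$x) / 2
      mafd <- pmin(pd, 1 - pd)
      keep <- mafd >= rules$maf_min & col_vars(td$x) > 0
      reason <- ifelse(keep, NA_character_, "maf")
      rep_track <- new_qc_report(ncol(td$x), keep, reason)
    } else {
      tmp_panel <- list(calls = td$x, map = td$map, line = gp$line)
      class(tmp_panel) <- "genotype_panel"
      rep_track <- genotype_qc(tmp_panel, rules)
      if (!is.null(td$dp) && rules$apply_r2_filter) {
        rep_track <- combine_qc(rep_track, accuracy_filter(td$dp, rules))
      }
    }
    keep_idx <- rep_track$kept_idx
    if (length(keep_idx) == 0L) {
      stop("track ", tr, ": QC removed every SNP", call. = FALSE)
    }

    x <- td$x[, keep_idx, drop = FALSE]
    map_t <- td$map[keep_idx, , drop = FALSE]
    loco <- loco_grms(x, map_t)
    assoc <- run_gwas(x, map_t, y, loco,
                      score_type = if (td$score == "dosage") "dosage" else "genotype",
                      var_pheno = sim$pheno_var)
    lam <- inflation_factor(assoc$p)
    assoc <- gc_adjust(assoc, lam)
    me <- effective_segments(attr(loco, "full"))

    artifacts$tracks[[tr]] <- list(
      assoc = assoc, lambda = lam, me = me, qc_report = rep_track,
      n_snps = length(keep_idx))
  }

  # thresholds: one per run (largest Me) or per track
  mes <- vapply(artifacts$tracks, function(t) t$me, numeric(1))
  for (tr in names(artifacts$tracks)) {
    me_use <- if (config$shared_threshold == "max-me") max(mes) else mes[[tr]]
    thr <- bonferroni_threshold(me_use, config$alpha)
    regions <- call_qtl_regions(artifacts$tracks[[tr]]$assoc, as.numeric(thr),
                                config$window_bp)
    artifacts$tracks[[tr]]$threshold <- thr
    artifacts$tracks[[tr]]$regions <- regions
    artifacts$tracks[[tr]]$summary <- summarize_regions(regions)
  }

  if (!is.null(config$out_dir)) {
    artifacts$paths <- write_artifacts(artifacts, config$out_dir)
  }
  class(artifacts) <- "run_artifacts"
  artifacts
}

# Evenly spaced subset of the SNPs with MAF at or above `maf_min`
# (chips preferentially assay common variants).
spaced_subset <- function(maf, fraction, maf_min = 0.01) {
  eligible <- which(maf >= maf_min)
  k <- max(1L, round(fraction * length(maf)))
  k <- min(k, length(eligible))
  eligible[unique(round(seq(1, length(eligible), length.out = k)))]
}

# Column subset of a dosage panel (keeps accuracy vectors aligned).
subset_dosage <- function(dp, idx) {
  out <- list(dosage = dp$dosage[, idx, drop = FALSE],
              g_obs = dp$g_obs[, idx, drop = FALSE],
              hard_call = dp$hard_call[, idx, drop = FALSE],
              pi = dp$pi[idx], freq = dp$freq[idx],
              target_r2 = dp$target_r2[idx],
              realized_r2 = dp$realized_r2[idx],
              estimated_r2 = dp$estimated_r2[idx],
              map = dp$map[idx, , drop = FALSE])
  class(out) <- "dosage_panel"
  out
}

write_artifacts <- function(artifacts, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  log_lines <- character(0)
  for (tr in names(artifacts$tracks)) {
    t <- artifacts$tracks[[tr]]
    pa <- file.path(out_dir, paste0("assoc_", tr, ".tsv"))
    assoc <- t$assoc
    assoc$b <- sprintf("%.6g", assoc$b)
    assoc$se <- sprintf("%.6g", assoc$se)
    assoc$chisq <- sprintf("%.6g", assoc$chisq)
    assoc$p <- sprintf("%.6g", assoc$p)
    assoc$chisq_adj <- sprintf("%.6g", assoc$chisq_adj)
    assoc$p_adj <- sprintf("%.6g", assoc$p_adj)
    assoc$var_explained_pct <- sprintf("%.6g", assoc$var_explained_pct)
    assoc$freq <- sprintf("%.6g", assoc$freq)
    utils::write.table(assoc, pa, sep = "\t", quote = FALSE, row.names = FALSE)
    pr <- file.path(out_dir, paste0("regions_", tr, ".tsv"))
    reg <- t$regions
    if (nrow(reg)) {
      reg$lead_neglog10p <- sprintf("%.6g", reg$lead_neglog10p)
      reg$lead_var_explained_pct <- sprintf("%.6g", reg$lead_var_explained_pct)
      reg$lead_freq <- sprintf("%.6g", reg$lead_freq)
    }
    utils::write.table(reg, pr, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("assoc_", tr)]] <- pa
    paths[[paste0("regions_", tr)]] <- pr
    log_lines <- c(log_lines, sprintf(
      "track=%s n_snps=%d lambda=%.4f me=%.1f threshold=%.3f n_regions=%d",
      tr, t$n_snps, t$lambda, t$me, as.numeric(t$threshold),
      nrow(t$regions)))
  }
  paths$log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, paths$log)
  paths
}

#' @export
print.run_artifacts <- function(x, ...) {
  cat("run_artifacts (line", x$config$sim$line, ", seed",
      x$config$sim$seed, "):\n")
  for (tr in names(x$tracks)) {
    t <- x$tracks[[tr]]
    cat(sprintf("  %-14s %6d SNPs  lambda=%.3f  Me=%.1f  thr=%.2f  regions=%d\n",
                tr, t$n_snps, t$lambda, t$me, as.numeric(t$threshold),
                nrow(t$regions)))
  }
  invisible(x)
}

#' Compare QTL regions across tracks
#'
#' For every ordered pair of tracks, counts regions whose lead SNP falls
#' within a region span (extended by the window) of the other track, and
#' scores each track against the simulated ground truth: a region is a
#' true positive when a causal SNP lies within the region window of its
#' lead.
#'
#' @param artifacts A `run_artifacts`.
#' @param window_bp Window for overlap; defaults to the run's
#'   `window_bp`.
#' @return A list with `pairwise` (data.frame: `track_a`, `track_b`,
#'   `n_a`, `shared`, `unique_a`) and `truth` (data.frame: `track`,
#'   `n_regions`, `true_positives`, `false_positives`).
#' @export
compare_tracks <- function(artifacts, window_bp = NULL) {
  stopifnot(inherits(artifacts, "run_artifacts"))
  if (length(artifacts$tracks) < 2) stop("need at least 2 tracks", call. = FALSE)
  window_bp <- window_bp %||% artifacts$config$window_bp

  reg <- lapply(artifacts$tracks, function(t) t$regions)
  trs <- names(reg)

  shared_count <- function(a, b) {
    if (nrow(a) == 0L) return(0L)
    hits <- vapply(seq_len(nrow(a)), function(i) {
      same <- b[b$chrom == a$chrom[i], , drop = FALSE]
      any(a$lead_bp[i] >= same$span_start - window_bp &
            a$lead_bp[i] <= same$span_end + window_bp)
    }, logical(1))
    sum(hits)
  }

  pairs <- expand.grid(track_a = trs, track_b = trs,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$track_a != pairs$track_b, ]
  pairs$n_a <- vapply(pairs$track_a, function(tr) nrow(reg[[tr]]), numeric(1))
  pairs$shared <- mapply(function(a, b) shared_count(reg[[a]], reg[[b]]),
                         pairs$track_a, pairs$track_b)
  pairs$unique_a <- pairs$n_a - pairs$shared
  rownames(pairs) <- NULL

  truth <- artifacts$truth
  tp_count <- function(r) {
    if (nrow(r) == 0L) return(0L)
    sum(vapply(seq_len(nrow(r)), function(i) {
      any(truth$chrom == r$chrom[i] &
            abs(truth$pos - r$lead_bp[i]) <= window_bp)
    }, logical(1)))
  }
  tp <- vapply(reg, tp_count, numeric(1))
  truth_df <- data.frame(track = trs,
                         n_regions = vapply(reg, nrow, numeric(1)),
                         true_positives = tp,
                         false_positives = vapply(reg, nrow, numeric(1)) - tp,
                         row.names = NULL, stringsAsFactors = FALSE)
  list(pairwise = pairs, truth = truth_df)
}
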