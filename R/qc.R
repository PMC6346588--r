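#' Quality-control rule set
#'
#' Thresholds for the three filter families applied in the pipeline:
#' sequence-variant filters (per-call depth window, site quality,
#' missingness, inter-site spacing), chip-style genotype QC (indels, MAF,
#' genotype-class frequency, map presence), and the imputation-accuracy
#' filter applied to hard-call tracks only. Boundary strictness follows
#' the conventions the thresholds come from: MAF below 0.01 is dropped,
#' QUAL must be strictly above 20, sites with more than 20% missing are
#' dropped, and accuracy R2 less than or equal to 0.6 is dropped.
#'
#' @param exclude_indels Drop insertion/deletion variants.
#' @param maf_min Minimum minor allele frequency (kept if MAF >= this).
#' @param genotype_class_freq_min Minimum sample frequency for each of
#'   the three genotype classes.
#' @param require_map Drop variants with missing map information.
#' @param depth_min,depth_max Per-call read-depth window; calls outside
#'   it are set missing.
#' @param qual_min Sites kept only when QUAL is strictly greater.
#' @param max_missing_fraction Sites with a larger missing fraction
#'   (after depth masking) are dropped.
#' @param min_spacing_bp Greedy left-to-right thinning keeps a site only
#'   when at least this far from the last kept site.
#' @param r2_min Accuracy filter: kept only when R2 is strictly greater.
#' @param apply_r2_filter Whether the accuracy filter applies (TRUE for
#'   hard-call imputed tracks, FALSE for dosage tracks).
#'
#' @return An object of class `qc_rules`.
#' @export
qc_rules <- function(exclude_indels = TRUE, maf_min = 0.01,
                     genotype_class_freq_min = 0.1, require_map = TRUE,
                     depth_min = 4L, depth_max = 35L, qual_min = 20,
                     max_missing_fraction = 0.20, min_spacing_bp = 3L,
                     r2_min = 0.6, apply_r2_filter = TRUE) {
  if (maf_min < 0 || maf_min > 0.5) stop("`maf_min` must be in [0, 0.5]", call. = FALSE)
  if (depth_min > depth_max) stop("`depth_min` must not exceed `depth_max`", call. = FALSE)
  rules <- list(exclude_indels = exclude_indels, maf_min = maf_min,
                genotype_class_freq_min = genotype_class_freq_min,
                require_map = require_map,
                depth_min = depth_min, depth_max = depth_max,
                qual_min = qual_min,
                max_missing_fraction = max_missing_fraction,
                min_spacing_bp = as.integer(min_spacing_bp),
                r2_min = r2_min, apply_r2_filter = apply_r2_filter)
  stopifnot(all(vapply(rules, function(x) length(x) == 1 && !is.na(x), logical(1))))
  class(rules) <- "qc_rules"
  rules
}

new_qc_report <- function(n_input, keep, reason) {
  stopifnot(length(keep) == n_input, length(reason) == n_input)
  reason[keep] <- NA_character_
  counts <- table(reason[!keep])
  rep <- list(n_input = n_input, n_kept = sum(keep), keep = keep,
              kept_idx = which(keep), fail_reason = reason,
              removal_counts = as.list(counts))
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$n_kept, "of", x$n_input, "SNPs kept\n")
  for (nm in names(x$removal_counts)) {
    cat(sprintf("  %-18s %d removed\n", nm, x$removal_counts[[nm]]))
  }
  invisible(x)
}

#' Sequence-variant filters
#'
#' Applies, in order: indel exclusion; per-call depth masking (calls with
#' depth outside \[depth_min, depth_max\] become missing); site-quality
#' filtering (QUAL must exceed `qual_min` strictly); missingness
#' filtering (sites with more than `max_missing_fraction` missing calls
#' after depth masking are dropped); and greedy left-to-right spacing
#' thinning (a site is kept only when at least `min_spacing_bp` from the
#' last kept site on its chromosome). Each removed site is attributed to
#' the first rule that failed it.
#'
#' @param gp A `genotype_panel` (its `map` may carry an `is_indel`
#'   logical column; absent means all sites are SNPs).
#' @param ann A `seq_annotations` for the same panel.
#' @param rules A [qc_rules()].
#'
#' @return A list with `report` (a `qc_report`) and `panel` (the panel
#'   with depth-masked calls, all sites retained so indices stay
#'   aligned).
#' @export
sequence_variant_filter <- function(gp, ann, rules = qc_rules()) {
  stopifnot(inherits(gp, "genotype_panel"), inherits(ann, "seq_annotations"))
  map <- gp$map
  validate_map(map)
  n <- nrow(gp$calls); m <- ncol(gp$calls)

  calls <- gp$calls
  bad_depth <- ann$depth < rules$depth_min | ann$depth > rules$depth_max
  calls[bad_depth | ann$missing] <- NA_integer_

  keep <- rep(TRUE, m)
  reason <- rep(NA_character_, m)
  fail <- function(which, why) {
    hit <- which & keep
    reason[hit] <<- why
    keep[hit] <<- FALSE
  }

  if (rules$exclude_indels) {
    is_indel <- map$is_indel %||% (nchar(map$ref) != 1L | nchar(map$alt) != 1L)
    fail(is_indel, "indel")
  }
  fail(ann$qual <= rules$qual_min, "qual")
  miss_frac <- colMeans(is.na(calls))
  fail(miss_frac > rules$max_missing_fraction, "missingness")

  # greedy spacing thinning among sites still in play
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch & keep)
    if (length(idx) < 2) next
    last_kept <- map$pos[idx[1]]
    for (i in idx[-1]) {
      if (map$pos[i] - last_kept < rules$min_spacing_bp) {
        keep[i] <- FALSE
        reason[i] <- "spacing"
      } else {
        last_kept <- map$pos[i]
      }
    }
  }

  out <- gp
  out$calls <- calls
  list(report = new_qc_report(m, keep, reason), panel = out)
}

#' Chip-style genotype QC
#'
#' A SNP is kept iff it is a true SNP (not an indel), has map
#' information, MAF >= `maf_min`, and each of the three genotype classes
#' occurs with sample frequency >= `genotype_class_freq_min` (among
#' non-missing calls).
#'
#' @param gp A `genotype_panel`.
#' @param rules A [qc_rules()].
#' @return A `qc_report`.
#' @export
genotype_qc <- function(gp, rules = qc_rules()) {
  stopifnot(inherits(gp, "genotype_panel"))
  m <- ncol(gp$calls)
  if (m == 0L) stop("empty genotype panel", call. = FALSE)
  keep <- rep(TRUE, m)
  reason <- rep(NA_character_, m)
  fail <- function(which, why) {
    hit <- which & keep
    reason[hit] <<- why
    keep[hit] <<- FALSE
  }

  if (rules$exclude_indels) {
    is_indel <- gp$map$is_indel %||% (nchar(gp$map$ref) != 1L | nchar(gp$map$alt) != 1L)
    fail(is_indel, "indel")
  }
  if (rules$require_map) {
    no_map <- is.na(gp$map$chrom) | is.na(gp$map$pos)
    fail(no_map, "no_map")
  }

  p <- colMeans(gp$calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail(is.na(maf) | maf < rules$maf_min, "maf")

  n_ok <- colSums(!is.na(gp$calls))
  f0 <- colSums(gp$calls == 0L, na.rm = TRUE) / n_ok
  f1 <- colSums(gp$calls == 1L, na.rm = TRUE) / n_ok
  f2 <- colSums(gp$calls == 2L, na.rm = TRUE) / n_ok
  fail(pmin(f0, f1, f2) < rules$genotype_class_freq_min, "genotype_class")

  rep <- new_qc_report(m, keep, reason)
  if (rep$n_kept == 0L) {
    warning("genotype QC removed every SNP; downstream stages need a non-empty panel",
            call. = FALSE)
  }
  rep
}

#' Realized imputation accuracy of one SNP
#'
#' Squared Pearson correlation between a dosage vector and the true
#' genotypes; defined as 0 when either vector has zero variance.
#'
#' @param dosage Numeric vector of dosages.
#' @param truth Genotype vector (0/1/2) of the same length.
#' @return A scalar in \[0, 1\].
#' @export
realized_r2 <- function(dosage, truth) {
  if (length(dosage) != length(truth)) stop("length mismatch", call. = FALSE)
  if (length(dosage) < 2) stop("need at least 2 individuals", call. = FALSE)
  ok <- !is.na(dosage) & !is.na(truth)
  dosage <- dosage[ok]; truth <- truth[ok]
  if (length(dosage) < 2) return(0)
  if (stats::var(dosage) == 0 || stats::var(truth) == 0) return(0)
  stats::cor(dosage, truth)^2
}

#' Truth-free allelic R2 from genotype probabilities
#'
#' The allelic-R2 estimator reported by posterior-probability imputation
#' software: the variance of the posterior expected dosage across
#' individuals divided by the expected variance if the posteriors were
#' perfect calls, i.e. `Var(e) / (E[u] - E[e]^2)` with
#' `e_i = GP1 + 2 GP2` and `u_i = GP1 + 4 GP2` (population-variance
#' convention). Clipped to \[0, 1\]; 0 when the denominator vanishes.
#'
#' @param gp An n x 3 matrix of genotype-probability triplets for one
#'   SNP.
#' @return A scalar in \[0, 1\].
#' @export
estimated_allelic_r2 <- function(gp) {
  gp <- as.matrix(gp)
  if (nrow(gp) < 2) stop("need at least 2 individuals", call. = FALSE)
  if (ncol(gp) != 3 || any(gp < -1e-9) || any(abs(rowSums(gp) - 1) > 1e-6)) {
    stop("`gp` must be valid probability triplets", call. = FALSE)
  }
  e <- gp[, 2] + 2 * gp[, 3]
  u <- gp[, 2] + 4 * gp[, 3]
  num <- mean(e^2) - mean(e)^2
  den <- mean(u) - mean(e)^2
  if (den <= 1e-12) return(0)
  min(max(num / den, 0), 1)
}

# Vectorized allelic R2 over all SNPs of a dosage panel, using the
# factored GP representation.
panel_estimated_r2 <- function(dp) {
  e <- dp$dosage
  n <- nrow(e)
  # u_i = GP1 + 4*GP2
  u <- t(dp$pi * t((dp$g_obs == 1L) + 4 * (dp$g_obs == 2L))) +
    matrix(rep((1 - dp$pi) * (2 * dp$freq * (1 - dp$freq) + 4 * dp$freq^2),
               each = n), nrow = n)
  num <- colMeans(e^2) - colMeans(e)^2
  den <- colMeans(u) - colMeans(e)^2
  out <- ifelse(den <= 1e-12, 0, pmin(pmax(num / den, 0), 1))
  as.numeric(out)
}

#' Imputation-accuracy filter
#'
#' For hard-call imputed tracks (`apply_r2_filter = TRUE`), keeps a SNP
#' only when its accuracy R2 is strictly greater than `r2_min` (the
#' conventional "drop R2 <= 0.6" rule). Dosage tracks carry their
#' uncertainty in the scores themselves, so the filter is skipped for
#' them.
#'
#' @param dp A `dosage_panel`, or any list with an accuracy vector.
#' @param rules A [qc_rules()].
#' @param which_r2 Accuracy estimate to filter on: the truth-free
#'   `"estimated"` R2 (default; the only one available in real
#'   pipelines) or the ground-truth `"realized"` R2.
#' @return A `qc_report`.
#' @export
accuracy_filter <- function(dp, rules = qc_rules(),
                            which_r2 = c("estimated", "realized")) {
  which_r2 <- match.arg(which_r2)
  r2 <- dp[[paste0(which_r2, "_r2")]]
  if (is.null(r2)) stop("dosage panel carries no ", which_r2, " accuracy values",
                        call. = FALSE)
  m <- length(r2)
  if (!rules$apply_r2_filter) {
    return(new_qc_report(m, rep(TRUE, m), rep(NA_character_, m)))
  }
  keep <- r2 > rules$r2_min
  reason <- ifelse(keep, NA_character_, "accuracy_r2")
  new_qc_report(m, keep, reason)
}

#' Combine QC reports by intersecting their kept sets
#'
#' @param ... `qc_report` objects over the same SNP set.
#' @return A `qc_report` whose kept set is the intersection; each removed
#'   SNP keeps the reason from the first report that failed it.
#' @export
combine_qc <- function(...) {
  reps <- list(...)
  stopifnot(length(reps) >= 1)
  m <- reps[[1]]$n_input
  keep <- rep(TRUE, m)
  reason <- rep(NA_character_, m)
  for (r in reps) {
    stopifnot(r$n_input == m)
    newfail <- keep & !r$keep
    reason[newfail] <- r$fail_reason[newfail]
    keep <- keep & r$keep
  }
  new_qc_report(m, keep, reason)
}
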