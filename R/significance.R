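# Median of the 1-df chi-square distribution, the genomic-control
# reference value.
CHI2_MEDIAN_1DF <- stats::qchisq(0.5, df = 1, lower.tail = FALSE)

#' Chi-square statistic from a p-value
#'
#' Upper-tail 1-df chi-square quantile, the statistic a two-sided Wald
#' p-value corresponds to.
#'
#' @param p P-value(s) in (0, 1].
#' @return Chi-square statistic(s).
#' @export
#' @examples
#' chisq_from_p(0.3173)  # ~1
chisq_from_p <- function(p) {
  if (any(p <= 0 | p > 1)) stop("`p` must lie in (0, 1]", call. = FALSE)
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}

#' Genomic inflation factor
#'
#' lambda = median(observed chi-square) / median(chi-square, 1 df), with
#' the observed statistics recovered from the p-values. Values above 1
#' indicate inflation of the test statistics, e.g. from population
#' structure or ascertainment bias.
#'
#' @param pvals P-values in (0, 1].
#' @return A positive scalar.
#' @export
inflation_factor <- function(pvals) {
  if (length(pvals) == 0) stop("no p-values supplied", call. = FALSE)
  stats::median(chisq_from_p(pvals)) / CHI2_MEDIAN_1DF
}

#' Genomic-control adjustment of an association table
#'
#' Divides each chi-square by the inflation factor and recomputes the
#' p-value from the 1-df upper tail; original statistics are retained in
#' `chisq` / `p`, adjusted ones appear as `chisq_adj` / `p_adj`.
#'
#' @param table An `assoc_table` (or data.frame with `chisq` and `p`).
#' @param lam Inflation factor (> 0); defaults to the table's own
#'   [inflation_factor()].
#' @return The table with `chisq_adj`, `p_adj` and `lambda` attribute.
#' @export
gc_adjust <- function(table, lam = NULL) {
  lam <- lam %||% inflation_factor(table$p)
  if (lam <= 0) stop("`lam` must be positive", call. = FALSE)
  table$chisq_adj <- table$chisq / lam
  table$p_adj <- stats::pchisq(table$chisq_adj, df = 1, lower.tail = FALSE)
  attr(table, "lambda") <- lam
  table
}

#' Bonferroni threshold on the effective number of independent tests
#'
#' `-log10(alpha / me)` with `me` the effective number of independent
#' chromosome segments standing in for the number of independent tests.
#' The raw value is used for thresholding; the 1-decimal rounding is a
#' reporting convention.
#'
#' @param me Effective number of independent tests (> 0).
#' @param alpha Type-1 error target in (0, 1).
#' @return A scalar with attribute `rounded` (1-dp value).
#' @export
#' @examples
#' bonferroni_threshold(782.3)  # 4.194...; rounds to 4.2
bonferroni_threshold <- function(me, alpha = 0.05) {
  if (me <= 0) stop("`me` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  thr <- -log10(alpha / me)
  attr(thr, "rounded") <- round(thr, 1)
  thr
}

#' Greedy QTL-region calling
#'
#' Per chromosome: among unassigned significant SNPs, take the one with
#' the largest -log10(p) as the lead; assign every unassigned
#' significant SNP within `window_bp` of the lead to its region; repeat
#' until every significant SNP is assigned. Regions on different
#' chromosomes never merge. Ties in significance are broken by smaller
#' chromosome, then smaller position, so the caller is deterministic.
#'
#' @param table A GC-adjusted `assoc_table` (uses `p_adj` when present,
#'   else `p`).
#' @param threshold_neglog10 Significance threshold on the -log10(p)
#'   scale.
#' @param window_bp Half-width of the region window (default 0.5 Mb).
#' @return A data.frame of regions, one row each: `region_id`, `chrom`,
#'   `lead_snp`, `lead_bp`, `lead_neglog10p`, `lead_freq`,
#'   `lead_var_explained_pct`, `n_members`, `span_start`, `span_end`;
#'   member SNP ids in `attr(, "members")` (a list). Zero rows when
#'   nothing is significant.
#' @export
call_qtl_regions <- function(table, threshold_neglog10, window_bp = 5e5) {
  if (window_bp <= 0) stop("`window_bp` must be positive", call. = FALSE)
  pv <- table$p_adj %||% table$p
  neglog <- -log10(pv)
  sig <- which(neglog > threshold_neglog10)

  cols <- c("region_id", "chrom", "lead_snp", "lead_bp", "lead_neglog10p",
            "lead_freq", "lead_var_explained_pct", "n_members",
            "span_start", "span_end")
  if (length(sig) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    attr(out, "members") <- list()
    return(out)
  }

  # global deterministic order: significance desc, then chrom, then bp
  ord <- sig[order(-neglog[sig], table$chr[sig], table$bp[sig])]
  assigned <- rep(FALSE, length(pv))
  regions <- list()
  for (lead in ord) {
    if (assigned[lead]) next
    same_chr <- sig[table$chr[sig] == table$chr[lead]]
    members <- same_chr[!assigned[same_chr] &
                          abs(table$bp[same_chr] - table$bp[lead]) <= window_bp]
    assigned[members] <- TRUE
    regions[[length(regions) + 1L]] <- list(lead = lead, members = members)
  }

  out <- do.call(rbind, lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    data.frame(
      region_id = i, chrom = table$chr[r$lead],
      lead_snp = table$snp[r$lead], lead_bp = table$bp[r$lead],
      lead_neglog10p = neglog[r$lead], lead_freq = table$freq[r$lead],
      lead_var_explained_pct = table$var_explained_pct[r$lead],
      n_members = length(r$members),
      span_start = max(min(table$bp[r$members]), table$bp[r$lead] - window_bp),
      span_end = min(max(table$bp[r$members]), table$bp[r$lead] + window_bp),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "members") <- lapply(regions, function(r) table$snp[r$members])
  out
}

#' Summarize QTL regions
#'
#' Region counts and the distribution of the percentage of phenotypic
#' variance explained by the lead SNPs, including how many regions
#' explain more than 1%.
#'
#' @param regions Output of [call_qtl_regions()].
#' @param breaks Bin edges (percent) for the lead variance-explained
#'   histogram.
#' @return A list: `n_regions`, `n_above_1pct`, `var_explained_hist`
#'   (named counts), `total_members`.
#' @export
summarize_regions <- function(regions,
                              breaks = c(0, 0.5, 1, 2, 5, Inf)) {
  if (nrow(regions) == 0L) {
    h <- table(cut(numeric(0), breaks, right = FALSE))
    return(list(n_regions = 0L, n_above_1pct = 0L,
                var_explained_hist = h, total_members = 0L))
  }
  ve <- regions$lead_var_explained_pct
  list(n_regions = nrow(regions),
       n_above_1pct = sum(ve > 1),
       var_explained_hist = table(cut(ve, breaks, right = FALSE)),
       total_members = sum(regions$n_members))
}
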