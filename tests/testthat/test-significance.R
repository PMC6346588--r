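test_that("chi-square statistics recover known p-value quantiles", {
  expect_equal(chisq_from_p(0.3173), 1, tolerance = 1e-3)
  expect_equal(chisq_from_p(1), 0)
  expect_equal(round(chisq_from_p(0.0455), 2), 4)
  expect_error(chisq_from_p(0), "\\(0, 1\\]")
  expect_error(chisq_from_p(-0.1), "\\(0, 1\\]")
})

test_that("the inflation factor is the median chi-square ratio", {
  expect_equal(inflation_factor(rep(0.5, 11)), 1, tolerance = 1e-12)
  # doubling every statistic doubles lambda
  p2 <- pchisq(2 * qchisq(0.5, 1, lower.tail = FALSE), 1, lower.tail = FALSE)
  expect_equal(inflation_factor(rep(p2, 11)), 2, tolerance = 1e-12)
  # null calibration on uniform p-values
  set.seed(71)
  expect_equal(inflation_factor(runif(1e5)), 1, tolerance = 0.01)
  expect_error(inflation_factor(numeric(0)), "no p-values")
})

test_that("genomic control is a fixed point after one adjustment", {
  set.seed(72)
  tab <- rand_assoc_table(72, n = 500)
  adj <- gc_adjust(tab)
  lam <- attr(adj, "lambda")
  expect_equal(adj$chisq_adj, tab$chisq / lam)
  expect_equal(adj$p_adj, pchisq(adj$chisq_adj, 1, lower.tail = FALSE))
  expect_equal(inflation_factor(adj$p_adj), 1, tolerance = 1e-9)
  # identity adjustment leaves p unchanged
  same <- gc_adjust(tab, lam = 1)
  expect_equal(same$p_adj, tab$p)
  expect_error(gc_adjust(tab, lam = 0), "positive")
})

test_that("effective-segment thresholds reproduce the reference values", {
  t_lw <- bonferroni_threshold(782.3, 0.05)
  expect_equal(as.numeric(t_lw), 4.194, tolerance = 5e-4)
  expect_equal(attr(t_lw, "rounded"), 4.2)
  t_dl <- bonferroni_threshold(280.6, 0.05)
  expect_equal(as.numeric(t_dl), 3.749, tolerance = 5e-4)
  expect_equal(attr(t_dl, "rounded"), 3.7)
  expect_equal(as.numeric(bonferroni_threshold(100, 0.05)),
               -log10(5e-4), tolerance = 1e-12)
  expect_error(bonferroni_threshold(0), "positive")
  expect_error(bonferroni_threshold(100, 1.5), "alpha")
})

test_that("the worked clustering example assigns members to the strongest lead", {
  tab <- data.frame(chr = 1L, snp = paste0("s", 1:4), allele = "A",
                    bp = c(1.0e6, 1.3e6, 1.6e6, 2.5e6),
                    freq = 0.3, b = 1, se = 1, chisq = 1,
                    p = c(1e-5, 1e-8, 1e-5, 1e-6),
                    var_explained_pct = 1, score_type = "genotype")
  reg <- call_qtl_regions(tab, threshold_neglog10 = 4, window_bp = 5e5)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$lead_bp, c(1.3e6, 2.5e6))
  expect_equal(reg$n_members, c(3, 1))
  expect_setequal(attr(reg, "members")[[1]], c("s1", "s2", "s3"))

  # nothing significant
  expect_equal(nrow(call_qtl_regions(tab, 10, 5e5)), 0)
  # a single significant SNP forms its own region
  one <- call_qtl_regions(tab, 7, 5e5)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_members, 1)
})

test_that("equal significance ties break on chromosome then position", {
  tab <- data.frame(chr = c(2L, 1L, 1L), snp = c("a", "b", "c"), allele = "A",
                    bp = c(100L, 900L, 200L), freq = 0.3, b = 1, se = 1,
                    chisq = 1, p = rep(1e-6, 3), var_explained_pct = 1,
                    score_type = "genotype")
  reg <- call_qtl_regions(tab, 4, window_bp = 1000)
  expect_equal(reg$lead_snp[1], "c")  # chrom 1, smallest bp wins
  expect_equal(sum(reg$n_members), 3)
})

test_that("the caller matches the brute-force implementation on random tables", {
  for (seed in 1:100) {
    tab <- rand_assoc_table(seed)
    thr <- runif(1, 2, 6)
    win <- sample(c(2e5, 5e5, 1e6), 1)
    reg <- call_qtl_regions(tab, thr, win)
    oracle <- brute_qtl(tab, thr, win)
    expect_equal(nrow(reg), length(oracle))
    if (length(oracle)) {
      expect_identical(reg$lead_snp, tab$snp[vapply(oracle, `[[`, 0L, "lead")])
      got <- lapply(attr(reg, "members"), sort)
      want <- lapply(oracle, function(r) sort(tab$snp[r$members]))
      expect_identical(got, want)
    }
    # membership partitions the significant set
    sig <- tab$snp[-log10(tab$p) > thr]
    members <- unlist(attr(reg, "members"))
    expect_setequal(members, sig)
    expect_identical(anyDuplicated(members), 0L)
  }
})

test_that("region counts are monotone in threshold and window", {
  for (seed in 101:150) {
    tab <- rand_assoc_table(seed)
    n_lo <- nrow(call_qtl_regions(tab, 2, 5e5))
    n_hi <- nrow(call_qtl_regions(tab, 4, 5e5))
    expect_lte(n_hi, n_lo)
    n_wide <- nrow(call_qtl_regions(tab, 2, 1e6))
    expect_lte(n_wide, n_lo)
  }
})

test_that("region summaries bin the lead variance explained", {
  reg <- data.frame(region_id = 1:3, chrom = 1, lead_snp = c("a", "b", "c"),
                    lead_bp = c(1, 2, 3) * 1e6, lead_neglog10p = 5,
                    lead_freq = 0.3,
                    lead_var_explained_pct = c(0.5, 1.2, 3.0),
                    n_members = c(2, 1, 4),
                    span_start = 1, span_end = 2)
  s <- summarize_regions(reg)
  expect_equal(s$n_regions, 3)
  expect_equal(s$n_above_1pct, 2)
  expect_equal(s$total_members, 7)
  expect_equal(sum(s$var_explained_hist), 3)

  empty <- call_qtl_regions(rand_assoc_table(1), 99, 5e5)
  s0 <- summarize_regions(empty)
  expect_equal(s0$n_regions, 0)
  expect_equal(s0$n_above_1pct, 0)
})
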