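# helper: annotations with everything passing unless overridden
clean_ann <- function(n, m, qual = 60) {
  structure(list(depth = matrix(10L, n, m), qual = rep(qual, m),
                 missing = matrix(FALSE, n, m)), class = "seq_annotations")
}

test_that("spacing thinning keeps the greedy left-to-right survivor set", {
  gp <- make_panel(matrix(c(0L, 1L, 2L), nrow = 3, ncol = 3),
                   pos = c(100L, 102L, 105L))
  out <- sequence_variant_filter(gp, clean_ann(3, 3))
  expect_identical(out$report$kept_idx, c(1L, 3L))  # 102-100 < 3, 105-100 >= 3
  expect_identical(out$report$fail_reason[2], "spacing")

  # chains restart from the last kept site, not the last seen site
  gp2 <- make_panel(matrix(1L, 2, 4), pos = c(100L, 102L, 104L, 105L))
  out2 <- sequence_variant_filter(gp2, clean_ann(2, 4))
  expect_identical(out2$report$kept_idx, c(1L, 3L))
})

test_that("site-quality and missingness boundaries are strict as documented", {
  # QUAL exactly 20 is removed ("higher than 20" is strict)
  gp <- make_panel(matrix(1L, 5, 3), pos = c(100L, 200L, 300L))
  ann <- clean_ann(5, 3)
  ann$qual <- c(20, 20.01, 60)
  out <- sequence_variant_filter(gp, ann)
  expect_identical(out$report$fail_reason[1], "qual")
  expect_true(all(c(2L, 3L) %in% out$report$kept_idx))

  # depth outside [4, 35] masks calls; > 20% missing drops the site
  gp2 <- make_panel(matrix(1L, 10, 2), pos = c(100L, 500L))
  ann2 <- clean_ann(10, 2)
  ann2$depth[1:3, 1] <- 2L      # 30% missing -> removed
  ann2$depth[1:2, 2] <- 36L     # 20% missing -> kept (not "more than 20%")
  out2 <- sequence_variant_filter(gp2, ann2)
  expect_identical(out2$report$fail_reason[1], "missingness")
  expect_identical(out2$report$kept_idx, 2L)
  expect_true(all(is.na(out2$panel$calls[1:2, 2])))
})

test_that("indels are excluded and removal counts partition the input", {
  calls <- matrix(1L, 4, 4)
  gp <- make_panel(calls, pos = c(100L, 200L, 300L, 400L),
                   ref = c("A", "AT", "G", "C"), alt = c("C", "A", "GTT", "T"))
  out <- sequence_variant_filter(gp, clean_ann(4, 4))
  expect_identical(out$report$fail_reason[c(2, 3)], c("indel", "indel"))
  rep <- out$report
  expect_equal(sum(unlist(rep$removal_counts)) + rep$n_kept, rep$n_input)
})

test_that("chip-style genotype QC applies the documented keep rule", {
  # counts (AA=90, Aa=8, aa=2): MAF 0.06 passes, class freq 0.02 fails
  x1 <- rep(c(0L, 1L, 2L), c(90, 8, 2))
  # counts (45, 35, 20): MAF 0.375, all class freqs >= 0.1 -> kept
  x2 <- rep(c(0L, 1L, 2L), c(45, 35, 20))
  x3 <- rep(0L, 100)  # monomorphic -> MAF 0 fails
  gp <- make_panel(cbind(x1, x2, x3), pos = c(100L, 200L, 300L))
  rep <- genotype_qc(gp)
  expect_identical(rep$kept_idx, 2L)
  expect_identical(rep$fail_reason[1], "genotype_class")
  expect_identical(rep$fail_reason[3], "maf")

  # missing map information fails the SNP
  gp$map$chrom[2] <- NA
  rep2 <- suppressWarnings(genotype_qc(gp))
  expect_identical(rep2$fail_reason[2], "no_map")
  expect_warning(genotype_qc(make_panel(cbind(x3))), "every SNP")
})

test_that("realized R2 is the squared Pearson correlation with stated conventions", {
  expect_equal(realized_r2(c(0, 1, 2, 2), c(0, 1, 2, 2)), 1)
  expect_equal(realized_r2(rep(1.3, 5), c(0, 1, 2, 1, 0)), 0)
  # hand-computed: r = 2 / sqrt(2.75 * 2), r^2 = 8/11
  expect_equal(realized_r2(c(0, 1, 2, 2), c(0, 1, 1, 2)), 8 / 11,
               tolerance = 1e-12)
  expect_error(realized_r2(c(0, 1), c(0, 1, 2)), "length mismatch")
  expect_error(realized_r2(1, 1), "at least 2")
})

test_that("allelic R2 matches its limits and the mixture calibration", {
  # certain polymorphic calls -> 1
  onehot <- diag(3)[c(1, 2, 3, 2, 1), ]
  expect_equal(estimated_allelic_r2(onehot), 1)
  # identical HWE triplets -> no dosage variance -> 0
  hwe <- matrix(rep(c(0.49, 0.42, 0.09), each = 6), ncol = 3)
  expect_equal(estimated_allelic_r2(hwe), 0)
  expect_error(estimated_allelic_r2(matrix(c(0.5, 0.2, 0.2), 1, 3)), "2 individuals")
  expect_error(estimated_allelic_r2(matrix(c(0.5, 0.3, 0.4), 4, 3)), "probability")

  # mixture with pi = 0.8 estimates pi^2 = 0.64
  cfg <- sim_config(n_individuals = 5000, n_snps_sequence = 10,
                    n_chromosomes = 1, seed = 19,
                    maf_spectrum = list(fixed = 0.3))
  hap <- simulate_haplotypes(cfg, n_haplotypes = 10000, copy_prob = 0)
  gp <- sample_genotypes(hap, 5000, seed = 19)
  dp <- simulate_imputation(gp, 0.64, seed = 19)
  est <- vapply(1:10, function(s) estimated_allelic_r2(gp_triplets(dp, s)),
                numeric(1))
  expect_equal(mean(est), 0.64, tolerance = 0.05)
})

test_that("the accuracy filter removes R2 <= 0.6 only on hard-call tracks", {
  dp <- list(estimated_r2 = c(0.59, 0.6, 0.61, 1), realized_r2 = c(1, 1, 1, 0))
  rep <- accuracy_filter(dp, qc_rules(apply_r2_filter = TRUE))
  expect_identical(rep$kept_idx, c(3L, 4L))  # 0.6 exactly is removed
  rep2 <- accuracy_filter(dp, qc_rules(apply_r2_filter = FALSE))
  expect_identical(rep2$kept_idx, 1:4)
  rep3 <- accuracy_filter(dp, qc_rules(), which_r2 = "realized")
  expect_identical(rep3$kept_idx, c(1L, 2L, 3L))
  expect_error(accuracy_filter(list(), qc_rules()), "no estimated accuracy")
})

test_that("QC is idempotent: filtering the kept set removes nothing", {
  s <- small_sim(seed = 41, n = 120, m = 300)
  ann <- simulate_sequencing(s$gp, 11.6, seed = 41, missing_rate = 0.05)
  out <- sequence_variant_filter(s$gp, ann)
  keep <- out$report$kept_idx

  gp2 <- structure(list(calls = out$panel$calls[, keep],
                        map = s$gp$map[keep, ], line = s$gp$line),
                   class = "genotype_panel")
  ann2 <- structure(list(depth = ann$depth[, keep], qual = ann$qual[keep],
                         missing = matrix(FALSE, 120, length(keep))),
                    class = "seq_annotations")
  ann2$depth[is.na(gp2$calls)] <- 10L  # masking already applied to calls
  out2 <- sequence_variant_filter(gp2, ann2)
  expect_identical(out2$report$kept_idx, seq_along(keep))

  repg <- genotype_qc(s$gp)
  gp3 <- structure(list(calls = s$gp$calls[, repg$kept_idx],
                        map = s$gp$map[repg$kept_idx, ], line = s$gp$line),
                   class = "genotype_panel")
  expect_identical(genotype_qc(gp3)$kept_idx, seq_along(repg$kept_idx))
})

test_that("higher accuracy plateaus fail the R2 filter less often", {
  s <- small_sim(seed = 42, n = 400, m = 300)
  maf <- pmin(colMeans(s$gp$calls) / 2, 1 - colMeans(s$gp$calls) / 2)
  frac_fail <- vapply(c(0.5, 0.7, 0.9), function(pl) {
    dp <- simulate_imputation(s$gp, target_accuracy(pmin(maf, 0.5), pl),
                              seed = 42)
    1 - accuracy_filter(dp)$n_kept / 300
  }, numeric(1))
  expect_true(all(diff(frac_fail) < 0))
})

test_that("truth-free and truth-based accuracy agree on simulator output", {
  cfg <- sim_config(n_individuals = 2000, n_snps_sequence = 150,
                    n_chromosomes = 1, seed = 43)
  hap <- simulate_haplotypes(cfg)
  gp <- sample_genotypes(hap, 2000, seed = 43)
  maf <- pmin(colMeans(gp$calls) / 2, 1 - colMeans(gp$calls) / 2)
  dp <- simulate_imputation(gp, target_accuracy(pmin(maf, 0.5), 0.9), seed = 7)
  poly <- maf > 0.01
  expect_lt(mean(abs(dp$estimated_r2[poly] - dp$realized_r2[poly])), 0.05)
})

test_that("combined reports attribute each SNP to its first failing rule", {
  r1 <- seqgwas:::new_qc_report(4, c(TRUE, FALSE, TRUE, TRUE),
                                c(NA, "maf", NA, NA))
  r2 <- seqgwas:::new_qc_report(4, c(FALSE, FALSE, TRUE, TRUE),
                                c("accuracy_r2", "accuracy_r2", NA, NA))
  cmb <- combine_qc(r1, r2)
  expect_identical(cmb$kept_idx, c(3L, 4L))
  expect_identical(cmb$fail_reason[1:2], c("accuracy_r2", "maf"))
})
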