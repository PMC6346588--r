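test_that("an identity relationship matrix is flagged unidentifiable", {
  set.seed(61)
  y <- rnorm(50)
  fit <- reml_fit(y, diag(50))
  expect_false(fit$identifiable)
  expect_equal(fit$sigma_g2, 0)
  expect_equal(fit$sigma_e2, var(y))
  expect_error(reml_fit(rnorm(5), diag(5)), "at least 10")
})

test_that("with no genetic variance the test collapses to ordinary least squares", {
  set.seed(62)
  n <- 80
  x <- rbinom(n, 2, 0.4)
  y <- 0.3 * x + rnorm(n)
  fit <- reml_fit(y, diag(n))  # sigma_g2 = 0 via the identifiability path
  rec <- snp_test(y, x, fit)
  ols <- lm(y ~ x)
  expect_equal(rec$b, unname(coef(ols)[2]), tolerance = 1e-10)
  # same point estimate as GLS with V proportional to I
  expect_equal(rec$chisq, (rec$b / rec$se)^2)
})

test_that("GLS matches the dense-inverse oracle", {
  s <- small_sim(seed = 63, n = 120, m = 300, n_chr = 2)
  maf <- pmin(colMeans(s$gp$calls) / 2, 1 - colMeans(s$gp$calls) / 2)
  x <- s$gp$calls[, maf > 0.05]; map <- s$gp$map[maf > 0.05, ]
  tr <- simulate_trait(s$gp, 10, 0.4, 1.08, seed = 63)
  loco <- loco_grms(x, map)
  fit <- reml_fit(tr$phenotype, loco[["1"]])
  V <- fit$sigma_g2 * loco[["1"]]$matrix + fit$sigma_e2 * diag(120)
  for (j in which(map$chrom == 1)[c(1, 5, 20)]) {
    rec <- snp_test(tr$phenotype, x[, j], fit)
    oracle <- dense_gls(tr$phenotype, x[, j], V)
    expect_equal(rec$b, oracle$b, tolerance = 1e-8)
    expect_equal(rec$se, oracle$se, tolerance = 1e-8)
  }
  expect_error(snp_test(tr$phenotype, rep(1, 120), fit), "monomorphic")
  expect_error(snp_test(tr$phenotype, x[1:50, 1], fit), "dimension")
})

test_that("a planted effect is recovered within its standard error", {
  set.seed(64)
  n <- 200
  x <- rbinom(n, 2, 0.3)
  y <- 2 * x + rnorm(n, sd = 0.1)
  fit <- reml_fit(y, diag(n))
  rec <- snp_test(y, x, fit)
  expect_lt(abs(rec$b - 2), 3 * rec$se)
})

test_that("null permutations produce uniform p-values", {
  set.seed(65)
  n <- 150
  x <- rbinom(n, 2, 0.3)
  y <- rnorm(n)
  fit <- reml_fit(y, diag(n))
  ps <- vapply(1:1000, function(i) snp_test(y, sample(x), fit)$p, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("variance explained reproduces the printed expression", {
  expect_equal(variance_explained(0.5, 1, 1), 50)
  expect_equal(variance_explained(0.3, 0, 1.08), 0)
  expect_equal(variance_explained(0.1, 2, 1.08), 2 * 0.1 * 0.9 * 4 / 1.08 * 100)
  expect_equal(round(variance_explained(0.1, 2, 1.08), 2), 66.67)
  expect_error(variance_explained(0.5, 1, 0), "positive")
  expect_error(variance_explained(0, 1, 1), "strictly inside")
})

test_that("the genome scan fits once per chromosome and reuses the components", {
  cfg <- sim_config(n_individuals = 120, n_snps_sequence = 100,
                    n_chromosomes = 2, seed = 66,
                    maf_spectrum = list(fixed = 0.3))
  hap <- simulate_haplotypes(cfg)
  gp <- sample_genotypes(hap, 120, seed = 66)
  tr <- simulate_trait(gp, 5, 0.4, seed = 66)
  loco <- loco_grms(gp$calls, gp$map)
  at <- run_gwas(gp$calls, gp$map, tr$phenotype, loco)
  expect_equal(attr(at, "n_reml_fits"), 2)
  expect_equal(nrow(at), 100)
  expect_identical(at$bp, at$bp[order(at$chr, at$bp)])
  expect_true(all(at$chisq == (at$b / at$se)^2))
  expect_equal(at$p, pchisq(at$chisq, 1, lower.tail = FALSE))

  # per-SNP record agrees with the vectorized scan
  fit1 <- reml_fit(tr$phenotype, loco[["1"]])
  j <- which(gp$map$chrom == 1)[3]
  rec <- snp_test(tr$phenotype, gp$calls[, j], fit1)
  row <- at[at$snp == gp$map$snp_id[j], ]
  expect_equal(row$b, rec$b, tolerance = 1e-10)
  expect_equal(row$p, rec$p, tolerance = 1e-10)

  expect_error(run_gwas(gp$calls, gp$map, tr$phenotype, loco["1"]),
               "no LOCO GRM")
  expect_error(run_gwas(gp$calls, gp$map, tr$phenotype, loco, keep = integer(0)),
               "empty kept")
})

test_that("genotype and dosage tracks coincide when imputation is perfect", {
  s <- small_sim(seed = 67, n = 150, m = 120, n_chr = 2,
                 maf_spectrum = list(fixed = 0.3))
  dp <- simulate_imputation(s$gp, 1, seed = 67)
  tr <- simulate_trait(s$gp, 8, 0.4, seed = 67)
  loco <- loco_grms(s$gp$calls, s$gp$map)
  at_g <- run_gwas(dp$hard_call, s$gp$map, tr$phenotype, loco, "genotype")
  at_d <- run_gwas(dp$dosage, s$gp$map, tr$phenotype, loco, "dosage")
  expect_equal(at_g$b, at_d$b, tolerance = 1e-10)
  expect_equal(at_g$p, at_d$p, tolerance = 1e-10)
})

test_that("dosage scores beat error-ridden hard calls at a causal locus", {
  wins <- 0; b_hard <- b_dose <- numeric(20)
  for (s in 1:20) {
    cfg <- sim_config(n_individuals = 400, n_snps_sequence = 40,
                      n_chromosomes = 2, seed = 700 + s,
                      maf_spectrum = list(fixed = 0.3))
    hap <- simulate_haplotypes(cfg)
    gp <- sample_genotypes(hap, 400, seed = 700 + s)
    causal <- which(gp$map$chrom == 1)[5]
    set.seed(800 + s)
    y <- 0.35 * gp$calls[, causal] + rnorm(400)
    dp <- simulate_imputation(gp, 0.5, seed = 700 + s)
    fit <- reml_fit(y, compute_grm(gp$calls[, gp$map$chrom == 2]))
    ph <- snp_test(y, dp$hard_call[, causal], fit)
    pd <- snp_test(y, dp$dosage[, causal], fit)
    wins <- wins + (pd$p < ph$p)
    b_hard[s] <- ph$b; b_dose[s] <- pd$b
  }
  expect_gte(wins, 11)  # dosage more significant in the median seed
  # hard calls attenuate the effect estimate more than dosages
  expect_lt(median(abs(b_hard)), median(abs(b_dose)))
})

test_that("modelling the polygenic term removes two-line structure inflation", {
  cfg <- sim_config(n_individuals = 250, n_snps_sequence = 1200,
                    n_chromosomes = 4, seed = 68)
  two <- simulate_two_lines(cfg)
  gpA <- sample_genotypes(two$A, 250, seed = 1, line = "A")
  gpB <- sample_genotypes(two$B, 250, seed = 2, line = "B")
  calls <- rbind(gpA$calls, gpB$calls)
  gp <- structure(list(calls = calls, map = two$A$map,
                       line = c(gpA$line, gpB$line)), class = "genotype_panel")
  maf <- pmin(colMeans(calls) / 2, 1 - colMeans(calls) / 2)
  keep <- maf >= 0.05
  x <- calls[, keep]; map <- gp$map[keep, ]

  # polygenic trait on chromosomes 3-4; chromosomes 1-2 carry no causal
  # SNPs but their frequencies differ between the lines
  tr <- simulate_trait(gp, "all", 0.5, 1, seed = 68,
                       candidates = which(keep & gp$map$chrom >= 3))
  y <- tr$phenotype
  test_idx <- which(map$chrom <= 2)

  # no polygenic term: line structure inflates the median statistic
  fit0 <- reml_fit(y, diag(500))
  p0 <- vapply(test_idx, function(j) snp_test(y, x[, j], fit0)$p, numeric(1))
  lam0 <- inflation_factor(p0)
  # mixed model with LOCO GRMs restores calibration
  at <- run_gwas(x, map, y, loco_grms(x, map), keep = test_idx)
  lam1 <- inflation_factor(at$p)
  expect_gt(lam0, 1.3)
  expect_lt(abs(lam1 - 1), 0.1)
})
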