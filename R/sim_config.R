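#' Simulation configuration for a two-line sequence GWAS study
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' describe the study the generator emulates: a commercial pig line with
#' on the order of a thousand phenotyped individuals, a quantitative trait
#' of heritability 0.4, mean sequencing depth 11.6x, and an
#' imputation-accuracy curve rising over the 0-0.15 MAF range to a
#' line-specific plateau (0.9 for line A, 0.7 for line B). Two line
#' presets carry the line-specific phenotypic variances (1.08 / 0.96)
#' and accuracy plateaus.
#'
#' @param n_individuals Number of individuals in the line.
#' @param n_snps_sequence Number of diallelic SNPs at sequence density.
#' @param n_chromosomes Number of chromosomes; sequence SNPs are spread
#'   evenly across them.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param ld_decay_bp Distance (bp) at which expected pairwise r2 has
#'   fallen to 0.3; beyond it mean r2 is below 0.3. Default 0.5 Mb.
#' @param maf_spectrum List describing the allele-frequency spectrum:
#'   `rare_mass` (probability mass below MAF 0.01), `rare_min`,
#'   `rare_max` bounds of the rare tail, and `common` (`"loguniform"`,
#'   approximating the 1/p neutral spectrum on \[0.01, 0.5\], or
#'   `"uniform"`). A degenerate spectrum `list(fixed = p)` puts every
#'   SNP at frequency `p` (useful for calibration checks).
#' @param chip_fraction Fraction of sequence SNPs placed on the sparse
#'   "chip" panel (evenly spaced among SNPs with MAF >= 0.01).
#' @param dense_fraction Fraction for the dense chip panel.
#' @param n_causal Number of causal SNPs behind the trait.
#' @param h2 Narrow-sense heritability in \[0, 1\].
#' @param pheno_var Phenotypic variance of the trait.
#' @param accuracy_plateau Asymptotic imputation-accuracy target R2.
#' @param accuracy_scale MAF at which the accuracy curve reaches about
#'   63\% of the plateau.
#' @param mean_depth Mean per-individual read depth.
#' @param qual_shift,qual_shape,qual_scale Site QUAL is drawn as
#'   `qual_shift + Gamma(qual_shape, scale = qual_scale)`; defaults put
#'   roughly 9\% of sites below Phred 20.
#' @param missing_rate Per-call missingness rate before depth masking.
#' @param seed Integer seed; identical config + seed gives identical data.
#' @param line Optional preset, `"A"` (plateau 0.9, phenotypic variance
#'   1.08) or `"B"` (plateau 0.7, variance 0.96); explicit arguments
#'   override the preset.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 100, n_snps_sequence = 500,
#'                   n_chromosomes = 2, line = "B")
#' cfg$accuracy_plateau
sim_config <- function(n_individuals = 1000,
                       n_snps_sequence = 20000,
                       n_chromosomes = 10,
                       chrom_length_bp = 1e7,
                       ld_decay_bp = 5e5,
                       maf_spectrum = list(rare_mass = 0.1, rare_min = 0.002,
                                           rare_max = 0.01, common = "loguniform"),
                       chip_fraction = 0.05,
                       dense_fraction = 0.25,
                       n_causal = 50,
                       h2 = 0.4,
                       pheno_var = NULL,
                       accuracy_plateau = NULL,
                       accuracy_scale = 0.05,
                       mean_depth = 11.6,
                       qual_shift = 5, qual_shape = 2, qual_scale = 30,
                       missing_rate = 0.03,
                       seed = 1,
                       line = c("A", "B")) {
  line <- match.arg(line)
  if (is.null(pheno_var)) pheno_var <- if (line == "A") 1.08 else 0.96
  if (is.null(accuracy_plateau)) accuracy_plateau <- if (line == "A") 0.9 else 0.7

  assert_scalar(n_individuals, "n_individuals", 1)
  assert_scalar(n_snps_sequence, "n_snps_sequence", 1)
  assert_scalar(n_chromosomes, "n_chromosomes", 1)
  assert_scalar(chrom_length_bp, "chrom_length_bp", 1)
  assert_scalar(ld_decay_bp, "ld_decay_bp", 1)
  assert_scalar(chip_fraction, "chip_fraction", 0, 1)
  assert_scalar(dense_fraction, "dense_fraction", 0, 1)
  assert_scalar(n_causal, "n_causal", 0)
  assert_scalar(h2, "h2", 0, 1)
  assert_scalar(pheno_var, "pheno_var", 0)
  assert_scalar(accuracy_scale, "accuracy_scale", 1e-6)
  assert_scalar(mean_depth, "mean_depth", 1e-6)
  assert_scalar(missing_rate, "missing_rate", 0, 1)
  if (accuracy_plateau <= 0 || accuracy_plateau > 1) {
    stop("`accuracy_plateau` must be in (0, 1]", call. = FALSE)
  }
  if (chip_fraction >= 1) stop("chip panel must be a strict subset of the sequence panel",
                               call. = FALSE)
  if (n_snps_sequence < n_chromosomes) {
    stop("need at least one SNP per chromosome", call. = FALSE)
  }

  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_snps_sequence = as.integer(n_snps_sequence),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    ld_decay_bp = as.numeric(ld_decay_bp),
    maf_spectrum = maf_spectrum,
    chip_fraction = chip_fraction,
    dense_fraction = dense_fraction,
    n_causal = as.integer(n_causal),
    h2 = h2,
    pheno_var = pheno_var,
    accuracy_plateau = accuracy_plateau,
    accuracy_scale = accuracy_scale,
    mean_depth = mean_depth,
    qual_shift = qual_shift, qual_shape = qual_shape, qual_scale = qual_scale,
    missing_rate = missing_rate,
    seed = as.integer(seed),
    line = line
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (line", x$line, "):",
      x$n_individuals, "individuals,",
      x$n_snps_sequence, "SNPs on", x$n_chromosomes, "chromosomes\n")
  cat("  h2 =", x$h2, " pheno_var =", x$pheno_var,
      " accuracy plateau =", x$accuracy_plateau,
      " mean depth =", x$mean_depth, " seed =", x$seed, "\n")
  invisible(x)
}

# Draw allele frequencies from the configured spectrum: a point mass of
# rare alleles below 0.01 plus a log-uniform (approximately 1/p) bulk
# on [0.01, 0.5].
sample_maf_spectrum <- function(n, spectrum) {
  if (!is.null(spectrum$fixed)) return(rep(spectrum$fixed, n))
  rare_mass <- spectrum$rare_mass %||% 0.1
  rare_min <- spectrum$rare_min %||% 0.002
  rare_max <- spectrum$rare_max %||% 0.01
  common <- spectrum$common %||% "loguniform"
  rare <- stats::runif(n) < rare_mass
  p <- numeric(n)
  p[rare] <- stats::runif(sum(rare), rare_min, rare_max)
  n_c <- sum(!rare)
  p[!rare] <- switch(common,
    loguniform = exp(stats::runif(n_c, log(0.01), log(0.5))),
    uniform = stats::runif(n_c, 0.01, 0.5),
    stop("unknown maf_spectrum$common: ", common)
  )
  p
}
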