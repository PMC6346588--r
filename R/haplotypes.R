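#' Simulate an LD-structured haplotype panel
#'
#' Haplotypes follow a first-order Markov copying process along each
#' chromosome, run on a latent quantile: each haplotype carries a latent
#' uniform that is copied from SNP s-1 to SNP s with a
#' distance-dependent probability and redrawn otherwise, and the allele
#' at SNP s is the indicator that the latent value falls below the
#' SNP's frequency. Copying the quantile rather than the allele value
#' keeps every SNP's marginal frequency exactly at its draw from the
#' configured spectrum while still producing LD: two SNPs sharing the
#' latent value are maximally correlated given their frequencies (r2 = 1
#' when the frequencies are equal, attenuated otherwise, as in real
#' data). The copy probability decays exponentially with physical
#' distance, calibrated so that the expected pairwise r2 of
#' equal-frequency SNPs falls to 0.3 at `ld_decay_bp` (0.5 Mb by
#' default), mirroring the LD decay reported for commercial pig lines;
#' frequency differences push the average below that bound.
#'
#' @param config A [sim_config()].
#' @param n_haplotypes Number of haplotypes; defaults to
#'   `2 * config$n_individuals`.
#' @param copy_prob Optional constant copy probability overriding the
#'   distance-based decay (useful for the degenerate limits: 0 gives
#'   fully independent SNPs, 1 gives a perfectly correlated chromosome).
#' @param map Optional variant map to reuse (chromosomes/positions of an
#'   existing panel); frequencies are still drawn fresh, which is how a
#'   second line segregating the same variants at line-specific
#'   frequencies is generated (see [simulate_two_lines()]).
#' @param seed_label Internal label deriving this panel's seed stream
#'   from `config$seed`.
#'
#' @return An object of class `haplotype_panel`: a list with `haplotypes`
#'   (0/1 integer matrix, haplotypes x SNPs), `map` (data.frame with
#'   `chrom`, `pos`, `ref`, `alt`), and `freq` (the per-SNP target
#'   frequency of the alternate allele).
#' @export
simulate_haplotypes <- function(config, n_haplotypes = NULL, copy_prob = NULL,
                                map = NULL, seed_label = "haplotypes") {
  stopifnot(inherits(config, "sim_config"))
  nh <- as.integer(n_haplotypes %||% (2L * config$n_individuals))
  set.seed(derive_seed(config$seed, seed_label))

  bases <- c("A", "C", "G", "T")
  if (is.null(map)) {
    m_total <- config$n_snps_sequence
    n_chr <- config$n_chromosomes
    m_per <- diff(round(seq(0, m_total, length.out = n_chr + 1)))
    maps <- vector("list", n_chr)
    for (ch in seq_len(n_chr)) {
      m <- m_per[ch]
      if (m == 0L) next
      pos <- sort(sample.int(config$chrom_length_bp, m))
      ref <- sample(bases, m, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
      maps[[ch]] <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                               stringsAsFactors = FALSE)
    }
    map <- do.call(rbind, maps)
    rownames(map) <- NULL
    map$snp_id <- sprintf("snp_%d_%d", map$chrom, map$pos)
  }
  validate_map(map)

  chroms <- unique(map$chrom)
  haps <- vector("list", length(chroms))
  freqs <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    idx <- which(map$chrom == chroms[i])
    m <- length(idx)
    pos <- map$pos[idx]
    p <- sample_maf_spectrum(m, config$maf_spectrum)
    freqs[[i]] <- p

    H <- matrix(0L, nrow = nh, ncol = m)
    u <- stats::runif(nh)
    H[, 1] <- as.integer(u < p[1])
    if (m > 1L) {
      d <- diff(pos)
      cp <- if (is.null(copy_prob)) {
        exp(-d * log(1 / 0.3) / (2 * config$ld_decay_bp))
      } else {
        rep(copy_prob, m - 1L)
      }
      for (s in 2:m) {
        redraw <- stats::runif(nh) >= cp[s - 1L]
        if (any(redraw)) u[redraw] <- stats::runif(sum(redraw))
        H[, s] <- as.integer(u < p[s])
      }
    }
    haps[[i]] <- H
  }

  panel <- list(haplotypes = do.call(cbind, haps), map = map,
                freq = unlist(freqs, use.names = FALSE))
  class(panel) <- "haplotype_panel"
  panel
}

#' Simulate two lines segregating the same variants
#'
#' Generates two haplotype pools sharing one variant map but with
#' independently drawn allele-frequency spectra and haplotypes, so each
#' SNP has line-specific frequencies — a variant common in one line can
#' be nearly absent from the other, as observed between commercial pig
#' lines. The line presets (phenotypic variance, accuracy plateau)
#' still come from each line's [sim_config()].
#'
#' @param config_a,config_b Configurations for the two lines; `config_b`
#'   defaults to `config_a` with the line preset switched to `"B"`
#'   (accuracy plateau 0.7, phenotypic variance 0.96).
#' @return A list with `haplotype_panel`s `A` and `B` (shared `map`).
#' @export
simulate_two_lines <- function(config_a, config_b = NULL) {
  stopifnot(inherits(config_a, "sim_config"))
  if (is.null(config_b)) {
    config_b <- config_a
    config_b$line <- "B"
    config_b$pheno_var <- 0.96
    config_b$accuracy_plateau <- 0.7
  }
  a <- simulate_haplotypes(config_a)
  b <- simulate_haplotypes(config_b, map = a$map, seed_label = "haplotypes-lineB")
  list(A = a, B = b)
}

# Positions must be strictly increasing within each chromosome.
validate_map <- function(map) {
  for (ch in unique(map$chrom)) {
    pos <- map$pos[map$chrom == ch]
    if (any(diff(pos) <= 0)) {
      stop("invalid variant map: positions not strictly increasing on chromosome ",
           ch, call. = FALSE)
    }
  }
  invisible(map)
}

#' Sample diploid genotypes from a haplotype panel
#'
#' Pairs haplotypes at random, so Hardy-Weinberg proportions hold
#' marginally at every SNP; the genotype is the sum of the two sampled
#' haplotype rows.
#'
#' @param panel A `haplotype_panel`.
#' @param n Number of individuals to draw.
#' @param seed Integer seed.
#' @param replace Sample haplotypes with replacement. Required when
#'   `2 * n` exceeds the number of haplotypes in the panel.
#' @param line Line label attached to every sampled individual.
#'
#' @return An object of class `genotype_panel`: `calls` (n x SNPs integer
#'   matrix in 0/1/2 with NA for missing), `map`, `line` (per-individual
#'   label).
#' @export
sample_genotypes <- function(panel, n, seed = 1, replace = FALSE, line = "A") {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- as.integer(n)
  if (n <= 0L) stop("`n` must be positive", call. = FALSE)
  nh <- nrow(panel$haplotypes)
  if (!replace && 2L * n > nh) {
    stop("panel has fewer than 2n haplotypes; use `replace = TRUE`", call. = FALSE)
  }
  set.seed(derive_seed(seed, "genotypes"))
  idx <- sample.int(nh, 2L * n, replace = replace)
  calls <- panel$haplotypes[idx[seq(1, 2 * n, by = 2)], , drop = FALSE] +
    panel$haplotypes[idx[seq(2, 2 * n, by = 2)], , drop = FALSE]
  storage.mode(calls) <- "integer"
  gp <- list(calls = calls, map = panel$map, line = rep(line, n))
  class(gp) <- "genotype_panel"
  gp
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$calls), "individuals x", ncol(x$calls),
      "SNPs on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}
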