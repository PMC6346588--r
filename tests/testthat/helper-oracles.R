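# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive implementation (double loops,
# dense inverses, repeat-scan) kept separate from the package's code
# paths.

# Build a genotype_panel from a bare call matrix.
make_panel <- function(calls, chrom = NULL, pos = NULL, ref = NULL, alt = NULL) {
  m <- ncol(calls)
  map <- data.frame(
    chrom = if (is.null(chrom)) rep(1L, m) else chrom,
    pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
    ref = if (is.null(ref)) rep("A", m) else ref,
    alt = if (is.null(alt)) rep("C", m) else alt,
    stringsAsFactors = FALSE)
  map$snp_id <- sprintf("snp_%d_%d", map$chrom, map$pos)
  structure(list(calls = calls, map = map, line = rep("A", nrow(calls))),
            class = "genotype_panel")
}

# Yang-estimator GRM by explicit per-element double loop.
naive_grm <- function(x, p) {
  n <- nrow(x); N <- ncol(x)
  G <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      s <- 0
      for (i in seq_len(N)) {
        xj <- x[j, i]; xk <- x[k, i]
        if (is.na(xj)) xj <- 2 * p[i]
        if (is.na(xk)) xk <- 2 * p[i]
        den <- 2 * p[i] * (1 - p[i])
        s <- s + if (j != k) {
          (xj - 2 * p[i]) * (xk - 2 * p[i]) / den
        } else {
          (xj^2 - (1 + 2 * p[i]) * xj + 2 * p[i]^2) / den
        }
      }
      G[j, k] <- s / N + if (j == k) 1 else 0
    }
  }
  G
}

# GLS of y on [1, x] through an explicit dense inverse of V.
dense_gls <- function(y, x, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  C <- solve(t(X) %*% Vi %*% X)
  b <- drop(C %*% t(X) %*% Vi %*% y)
  list(b = unname(b[2]), se = sqrt(C[2, 2]))
}

# Greedy QTL-region caller by literal repeat-scan over a shrinking set.
brute_qtl <- function(tab, thr, window) {
  pv <- if (!is.null(tab$p_adj)) tab$p_adj else tab$p
  nl <- -log10(pv)
  sig <- data.frame(i = seq_len(nrow(tab)), chr = tab$chr, bp = tab$bp, nl = nl)
  sig <- sig[sig$nl > thr, ]
  regions <- list()
  while (nrow(sig) > 0) {
    best <- sig[order(-sig$nl, sig$chr, sig$bp), ][1, ]
    mem <- sig[sig$chr == best$chr & abs(sig$bp - best$bp) <= window, ]
    regions[[length(regions) + 1L]] <- list(lead = best$i, members = sort(mem$i))
    sig <- sig[!(sig$i %in% mem$i), ]
  }
  regions
}

# Random association tables with duplicated p-values (ties) for the
# region-caller equivalence checks.
rand_assoc_table <- function(seed, n = 60) {
  set.seed(seed)
  chr <- sort(sample(1:3, n, replace = TRUE))
  bp <- unlist(lapply(split(seq_len(n), chr), function(i)
    sort(sample.int(5e6, length(i)))), use.names = FALSE)
  p <- 10^-stats::runif(n, 0, 8)
  ties <- sample.int(n, max(2L, n %/% 6))
  p[ties] <- p[ties[1]]
  data.frame(chr = chr, snp = sprintf("s%d", seq_len(n)), bp = bp,
             allele = "A", freq = stats::runif(n, 0.05, 0.5),
             b = 0, se = 1, chisq = stats::qchisq(p, 1, lower.tail = FALSE),
             p = p, var_explained_pct = stats::runif(n, 0, 3),
             score_type = "genotype", stringsAsFactors = FALSE)
}

# Compact two-chromosome simulated dataset reused by several files.
small_sim <- function(seed = 1, n = 150, m = 400, n_chr = 2, ...) {
  cfg <- sim_config(n_individuals = n, n_snps_sequence = m,
                    n_chromosomes = n_chr, n_causal = 10, seed = seed, ...)
  hap <- simulate_haplotypes(cfg)
  gp <- sample_genotypes(hap, n, seed = seed)
  list(cfg = cfg, hap = hap, gp = gp)
}
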