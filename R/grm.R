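#' Allele frequencies of a score matrix
#'
#' Frequency of the counted (alternate) allele: half the mean hard call
#' over non-missing individuals, or half the mean dosage for dosage
#' scores.
#'
#' @param x An individuals x SNPs matrix of hard calls (0/1/2, NA
#'   allowed) or dosages, or a `genotype_panel` / `dosage_panel`.
#' @return A numeric vector of per-SNP frequencies, with attribute
#'   `monomorphic` flagging SNPs at frequency 0 or 1.
#' @export
allele_freq <- function(x) {
  x <- score_matrix(x)
  if (ncol(x) == 0L) stop("empty panel", call. = FALSE)
  n_ok <- colSums(!is.na(x))
  if (any(n_ok == 0L)) {
    stop("SNP(s) with all calls missing: ",
         paste(utils::head(which(n_ok == 0L), 5), collapse = ", "), call. = FALSE)
  }
  p <- colMeans(x, na.rm = TRUE) / 2
  attr(p, "monomorphic") <- p <= 0 | p >= 1
  p
}

# Accept panels or raw matrices everywhere downstream.
score_matrix <- function(x) {
  if (inherits(x, "genotype_panel")) return(x$calls)
  if (inherits(x, "dosage_panel")) return(x$dosage)
  as.matrix(x)
}

#' Genomic relationship matrix (Yang estimator)
#'
#' Implements both branches of the estimator: for individuals j != k,
#' `G_jk = (1/N) sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1 - p_i))`,
#' and on the diagonal
#' `G_jj = 1 + (1/N) sum_i (x_ij^2 - (1 + 2p_i) x_ij + 2 p_i^2) / (2 p_i (1 - p_i))`.
#' Missing calls are imputed to `2p_i`, contributing zero to the
#' off-diagonal numerator. Works identically for hard calls and dosages.
#'
#' @param x Score matrix or panel (individuals x SNPs).
#' @param p Optional per-SNP counted-allele frequencies; computed with
#'   [allele_freq()] when omitted. All must lie strictly inside (0, 1).
#' @param excluded_chromosome Optional label recording which chromosome
#'   the SNP set excludes (for LOCO bookkeeping).
#' @return An object of class `grm`: `matrix` (n x n symmetric), `N`
#'   (number of SNPs), `snp_idx` (columns used), `excluded_chromosome`.
#' @export
compute_grm <- function(x, p = NULL, excluded_chromosome = NULL) {
  x <- score_matrix(x)
  if (is.null(p)) p <- allele_freq(x)
  if (length(p) != ncol(x)) stop("`p` must have one entry per SNP", call. = FALSE)
  bad <- which(p <= 0 | p >= 1)
  if (length(bad)) {
    stop("monomorphic SNP(s) (p in {0,1}) not allowed in GRM: column ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  n <- nrow(x); N <- ncol(x)
  het <- 2 * p * (1 - p)

  xc <- sweep(x, 2, 2 * p)          # x - 2p
  xc[is.na(xc)] <- 0                # mean imputation: contributes zero
  w <- sweep(xc, 2, sqrt(het), "/")
  G <- tcrossprod(w) / N

  # diagonal branch
  xi <- x
  miss <- is.na(xi)
  if (any(miss)) xi[miss] <- matrix(rep(2 * p, each = n), n)[miss]
  diag_terms <- xi * xi - sweep(xi, 2, 1 + 2 * p, "*")
  diag_terms <- sweep(diag_terms, 2, 2 * p^2, "+")
  diag(G) <- 1 + rowSums(sweep(diag_terms, 2, het, "/")) / N

  out <- list(matrix = (G + t(G)) / 2, N = N,
              snp_idx = seq_len(N),
              excluded_chromosome = excluded_chromosome)
  class(out) <- "grm"
  out
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$matrix), "individuals, N =", x$N, "SNPs")
  if (!is.null(x$excluded_chromosome)) {
    cat(" (excluding chromosome", x$excluded_chromosome, ")")
  }
  cat("\n  mean diagonal:", round(mean(diag(x$matrix)), 4), "\n")
  invisible(x)
}

#' Leave-one-chromosome-out GRMs
#'
#' One GRM per chromosome, each built from all SNPs except those mapped
#' to that chromosome, so a tested SNP never contributes to the
#' relationship matrix of its own model.
#'
#' The per-chromosome numerator contributions are accumulated once and
#' subtracted, so building all C leave-one-out matrices costs the same
#' as one full GRM; the result is numerically identical to calling
#' [compute_grm()] on each chromosome-excluded SNP subset.
#'
#' @param x Score matrix or panel.
#' @param map Variant map with a `chrom` column aligned to the columns
#'   of `x`.
#' @param p Optional per-SNP frequencies.
#' @return An object of class `loco_grm_set`: a named list of `grm`
#'   objects, one per chromosome; the whole-genome GRM is attached as
#'   `attr(, "full")`.
#' @export
loco_grms <- function(x, map, p = NULL) {
  x <- score_matrix(x)
  stopifnot(nrow(map) == ncol(x))
  if (is.null(p)) p <- allele_freq(x)
  chroms <- sort(unique(map$chrom))
  if (length(chroms) < 2) {
    stop("LOCO requires at least 2 chromosomes", call. = FALSE)
  }
  n <- nrow(x)

  # per-chromosome sums of the standardized cross products
  A <- vector("list", length(chroms))
  dg <- vector("list", length(chroms))
  N_c <- integer(length(chroms))
  for (i in seq_along(chroms)) {
    idx <- which(map$chrom == chroms[i])
    N_c[i] <- length(idx)
    pc <- p[idx]
    bad <- which(pc <= 0 | pc >= 1)
    if (length(bad)) {
      stop("monomorphic SNP(s) (p in {0,1}) not allowed in GRM: column ",
           paste(utils::head(idx[bad], 5), collapse = ", "), call. = FALSE)
    }
    xc <- x[, idx, drop = FALSE]
    het <- 2 * pc * (1 - pc)
    w <- sweep(sweep(xc, 2, 2 * pc), 2, sqrt(het), "/")
    w[is.na(w)] <- 0
    A[[i]] <- tcrossprod(w)
    xi <- xc
    miss <- is.na(xi)
    if (any(miss)) xi[miss] <- matrix(rep(2 * pc, each = n), n)[miss]
    dt <- xi * xi - sweep(xi, 2, 1 + 2 * pc, "*")
    dt <- sweep(dt, 2, 2 * pc^2, "+")
    dg[[i]] <- rowSums(sweep(dt, 2, het, "/"))
  }
  A_tot <- Reduce(`+`, A)
  d_tot <- Reduce(`+`, dg)
  N_tot <- sum(N_c)

  out <- lapply(seq_along(chroms), function(i) {
    N <- N_tot - N_c[i]
    if (N == 0L) stop("LOCO GRM for chromosome ", chroms[i],
                      " would use zero SNPs", call. = FALSE)
    G <- (A_tot - A[[i]]) / N
    diag(G) <- 1 + (d_tot - dg[[i]]) / N
    g <- list(matrix = (G + t(G)) / 2, N = N,
              snp_idx = which(map$chrom != chroms[i]),
              excluded_chromosome = chroms[i])
    class(g) <- "grm"
    g
  })
  names(out) <- as.character(chroms)

  Gf <- A_tot / N_tot
  diag(Gf) <- 1 + d_tot / N_tot
  full <- list(matrix = (Gf + t(Gf)) / 2, N = N_tot,
               snp_idx = seq_len(ncol(x)), excluded_chromosome = NULL)
  class(full) <- "grm"
  attr(out, "full") <- full
  class(out) <- "loco_grm_set"
  out
}

#' Effective number of independent chromosome segments
#'
#' The reciprocal of the sample variance of the off-diagonal GRM
#' entries (upper triangle). For K independent standardized loci the
#' off-diagonal variance is about 1/K, so the statistic recovers the
#' number of effectively independent segments; LD between SNPs lowers
#' the effective number below the SNP count.
#'
#' @param grm A `grm` (or bare symmetric matrix).
#' @return A positive scalar; `Inf` (with a warning) when the
#'   off-diagonal variance is zero.
#' @export
effective_segments <- function(grm) {
  G <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  n <- nrow(G)
  if (n < 3) stop("need at least 3 individuals", call. = FALSE)
  off <- G[upper.tri(G)]
  v <- stats::var(off)
  if (v == 0) {
    warning("zero off-diagonal variance; effective segment count is infinite",
            call. = FALSE)
    return(Inf)
  }
  1 / v
}

#' Export a GRM as plain text
#'
#' One line per pair, `i<TAB>j<TAB>N<TAB>value` with 1-based indices and
#' j <= i (lower triangle including the diagonal), plus an `.id` file
#' listing individual identifiers — the widespread text GRM convention.
#'
#' @param grm A `grm`.
#' @param path Output path for the pair file; ids are written to
#'   `paste0(path, ".id")`.
#' @param ids Optional individual identifiers.
#' @return Invisibly, `path`.
#' @export
write_grm_text <- function(grm, path, ids = NULL) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$matrix)
  idx <- which(lower.tri(grm$matrix, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], N = grm$N,
                   value = grm$matrix[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ids <- ids %||% sprintf("ind_%d", seq_len(n))
  writeLines(ids, paste0(path, ".id"))
  invisible(path)
}
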