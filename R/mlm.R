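#' REML variance components under a polygenic model
#'
#' Fits y = 1*mu + u + e with u ~ N(0, G sigma_g2) and
#' e ~ N(0, I sigma_e2) by restricted maximum likelihood. The GRM is
#' eigendecomposed once and the restricted log-likelihood is profiled
#' down to a one-dimensional search over the variance ratio
#' delta = sigma_g2 / sigma_e2 (bounded Brent search on log delta,
#' including the delta = 0 boundary), so the fit is deterministic.
#' Mildly negative eigenvalues, which the Yang diagonal introduces for
#' rare-allele-heavy SNP sets, are kept; the ratio search is bounded so
#' that V = G sigma_g2 + I sigma_e2 stays positive definite.
#'
#' When the GRM is (numerically) the identity, the two components are
#' exchangeable and only their sum is identified; the fit is flagged
#' `identifiable = FALSE` with the whole variance assigned to the
#' residual rather than split arbitrarily.
#'
#' @param y Phenotype vector.
#' @param grm A `grm` (or bare symmetric matrix) for the same
#'   individuals.
#' @param tol Convergence tolerance on the restricted log-likelihood.
#' @return An object of class `reml_fit`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `loglik` (restricted, up to an additive constant), `identifiable`,
#'   `excluded_chromosome`, and the cached eigendecomposition (`U`,
#'   `d`) plus rotated `Uty`, `Ut1` used by [snp_test()].
#' @export
reml_fit <- function(y, grm, tol = 1e-8) {
  G <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  n <- length(y)
  if (n < 10) stop("need at least 10 individuals", call. = FALSE)
  stopifnot(nrow(G) == n)

  eg <- eigen(G, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -0.25 * max(abs(d))) {
    stop("GRM is not positive semi-definite within tolerance", call. = FALSE)
  }
  U <- eg$vectors
  # keep V = delta*D + I positive definite despite negative eigenvalues
  log_delta_hi <- if (min(d) < 0) log(0.999 / abs(min(d))) else 25
  Uty <- drop(crossprod(U, y))
  Ut1 <- drop(crossprod(U, rep(1, n)))

  # profiled restricted log-likelihood at ratio delta = sg2/se2
  negloglik <- function(log_delta) {
    delta <- exp(log_delta)
    v <- delta * d + 1
    w <- 1 / v
    s11 <- sum(w * Ut1^2)
    beta <- sum(w * Ut1 * Uty) / s11
    r <- Uty - beta * Ut1
    rss <- sum(w * r^2)
    se2 <- rss / (n - 1)
    0.5 * (sum(log(v)) + log(s11) + (n - 1) * log(se2))
  }

  identifiable <- stats::sd(d) > 1e-10 * max(abs(d), 1)
  if (!identifiable) {
    v <- stats::var(y)
    fit <- list(sigma_g2 = 0, sigma_e2 = v, h2 = 0,
                loglik = -negloglik(-Inf), identifiable = FALSE)
  } else {
    opt <- stats::optimize(negloglik, c(-25, log_delta_hi), tol = 1e-9)
    # compare against the no-genetic-variance boundary
    boundary <- negloglik(-Inf)
    if (boundary <= opt$objective + tol) {
      delta <- 0; nll <- boundary
    } else {
      delta <- exp(opt$minimum); nll <- opt$objective
    }
    v <- delta * d + 1
    w <- 1 / v
    s11 <- sum(w * Ut1^2)
    beta <- sum(w * Ut1 * Uty) / s11
    r <- Uty - beta * Ut1
    se2 <- sum(w * r^2) / (n - 1)
    sg2 <- delta * se2
    fit <- list(sigma_g2 = sg2, sigma_e2 = se2,
                h2 = if (sg2 + se2 > 0) sg2 / (sg2 + se2) else 0,
                loglik = -nll, identifiable = TRUE)
  }

  fit$excluded_chromosome <-
    if (inherits(grm, "grm")) grm$excluded_chromosome else NULL
  fit$U <- U; fit$d <- d; fit$Uty <- Uty; fit$Ut1 <- Ut1
  fit$n <- n
  class(fit) <- "reml_fit"
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit: sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f%s\n",
              x$sigma_g2, x$sigma_e2, x$h2,
              if (x$identifiable) "" else " (not identifiable: GRM ~ identity)"))
  invisible(x)
}

#' Single-SNP generalized-least-squares test
#'
#' Tests one SNP by GLS of y on \[1, x\] with the covariance
#' V = G sigma_g2 + I sigma_e2 held fixed at the (LOCO) REML estimates.
#' The Wald chi-square is (b/se)^2 with a two-sided p-value from the
#' 1-df chi-square upper tail.
#'
#' @param y Phenotype vector.
#' @param x Genotype (0/1/2; NA mean-imputed to 2p) or dosage vector for
#'   the tested SNP.
#' @param fit A [reml_fit()] whose GRM excludes the tested SNP's
#'   chromosome.
#' @return A one-row data.frame: `freq`, `b`, `se`, `chisq`, `p`.
#' @export
snp_test <- function(y, x, fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (length(x) != fit$n) stop("dimension mismatch", call. = FALSE)
  p <- mean(x, na.rm = TRUE) / 2
  if (anyNA(x)) x[is.na(x)] <- 2 * p
  if (stats::var(x) == 0) stop("monomorphic SNP (zero variance)", call. = FALSE)

  w <- 1 / (fit$sigma_g2 * fit$d + fit$sigma_e2)
  Utx <- drop(crossprod(fit$U, x))
  stats <- gls_scan(fit$Uty, fit$Ut1, Utx, w)
  data.frame(freq = p, b = stats$b, se = stats$se,
             chisq = stats$chisq, p = stats$p)
}

# Closed-form GLS of y on [1, x] in the rotated basis; x may be a matrix
# with one column per SNP (vectorized scan).
gls_scan <- function(Uty, Ut1, Utx, w) {
  Utx <- as.matrix(Utx)
  s11 <- sum(w * Ut1^2)
  s1y <- sum(w * Ut1 * Uty)
  s1x <- drop(crossprod(Utx, w * Ut1))
  sxx <- drop(crossprod(Utx^2, w))
  sxy <- drop(crossprod(Utx, w * Uty))
  det <- s11 * sxx - s1x^2
  b <- (s11 * sxy - s1x * s1y) / det
  se <- sqrt(s11 / det)
  chisq <- (b / se)^2
  list(b = b, se = se, chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Percentage of phenotypic variance explained by one SNP
#'
#' `2 p (1 - p) b^2 / var_pheno * 100`, with p the counted-allele
#' frequency and b the estimated allele substitution effect.
#'
#' @param p Allele frequency in (0, 1).
#' @param beta Estimated allele substitution effect.
#' @param var_pheno Phenotypic variance (> 0).
#' @return Percentage of variance explained.
#' @export
#' @examples
#' variance_explained(0.5, 1, 1)  # 50
variance_explained <- function(p, beta, var_pheno) {
  if (any(var_pheno <= 0)) stop("`var_pheno` must be positive", call. = FALSE)
  if (any(p <= 0 | p >= 1)) stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  2 * p * (1 - p) * beta^2 / var_pheno * 100
}

#' Genome-wide single-SNP mixed-model scan
#'
#' For each chromosome: fit REML variance components once on that
#' chromosome's leave-one-chromosome-out GRM, then test every kept SNP
#' on the chromosome by GLS with those components held fixed. Hard-call
#' and dosage scores run through the identical code path; the score type
#' is recorded per record.
#'
#' @param x Score matrix or panel (individuals x SNPs).
#' @param map Variant map aligned with the columns of `x` (`chrom`,
#'   `pos`, `snp_id`, `alt`).
#' @param y Phenotype vector.
#' @param loco A [loco_grms()] set covering every chromosome in `map`.
#' @param score_type `"genotype"` or `"dosage"`, recorded in the output.
#' @param keep Optional logical/integer subset of SNPs to test.
#' @param var_pheno Phenotypic variance used for variance explained;
#'   defaults to `var(y)`.
#' @return An `assoc_table`: a data.frame with one row per tested SNP
#'   (`chr`, `snp`, `bp`, `allele`, `freq`, `b`, `se`, `chisq`, `p`,
#'   `var_explained_pct`, `score_type`), sorted by (chr, bp), with the
#'   per-chromosome variance components in `attr(, "vc")` and the number
#'   of REML fits in `attr(, "n_reml_fits")`.
#' @export
run_gwas <- function(x, map, y, loco, score_type = c("genotype", "dosage"),
                     keep = NULL, var_pheno = NULL) {
  score_type <- match.arg(score_type)
  x <- score_matrix(x)
  stopifnot(nrow(map) == ncol(x), length(y) == nrow(x))
  if (is.null(keep)) keep <- seq_len(ncol(x))
  if (is.logical(keep)) keep <- which(keep)
  if (length(keep) == 0L) stop("empty kept SNP set", call. = FALSE)
  var_pheno <- var_pheno %||% stats::var(y)

  chroms <- sort(unique(map$chrom[keep]))
  missing_grm <- setdiff(as.character(chroms), names(loco))
  if (length(missing_grm)) {
    stop("no LOCO GRM for chromosome(s): ",
         paste(missing_grm, collapse = ", "), call. = FALSE)
  }

  res <- vector("list", length(chroms))
  vc <- vector("list", length(chroms))
  names(vc) <- as.character(chroms)
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    fit <- reml_fit(y, loco[[as.character(ch)]])
    vc[[i]] <- fit[c("sigma_g2", "sigma_e2", "h2", "loglik", "identifiable")]
    idx <- keep[map$chrom[keep] == ch]

    xs <- x[, idx, drop = FALSE]
    p <- colMeans(xs, na.rm = TRUE) / 2
    if (anyNA(xs)) {
      imp <- matrix(rep(2 * p, each = nrow(xs)), nrow(xs))
      xs[is.na(xs)] <- imp[is.na(xs)]
    }
    mono <- col_vars(xs) == 0
    if (any(mono)) {
      idx <- idx[!mono]; xs <- xs[, !mono, drop = FALSE]; p <- p[!mono]
    }
    if (length(idx) == 0L) next

    w <- 1 / (fit$sigma_g2 * fit$d + fit$sigma_e2)
    Utx <- crossprod(fit$U, xs)
    stats <- gls_scan(fit$Uty, fit$Ut1, Utx, w)
    res[[i]] <- data.frame(
      chr = map$chrom[idx], snp = map$snp_id[idx], bp = map$pos[idx],
      allele = map$alt[idx], freq = p, b = stats$b, se = stats$se,
      chisq = stats$chisq, p = stats$p,
      var_explained_pct = variance_explained(pmin(pmax(p, 1e-12), 1 - 1e-12),
                                             stats$b, var_pheno),
      score_type = score_type, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chr, out$bp), ]
  rownames(out) <- NULL
  attr(out, "vc") <- vc
  attr(out, "n_reml_fits") <- length(chroms)
  attr(out, "var_pheno") <- var_pheno
  class(out) <- c("assoc_table", "data.frame")
  out
}
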