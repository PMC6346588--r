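#' Target imputation accuracy as a function of MAF
#'
#' Saturating-exponential accuracy curve
#' `r2(maf) = plateau * (1 - exp(-maf / scale))`: accuracy rises steeply
#' over low MAF (most of the gain happens below MAF 0.15 at the default
#' scale) and levels off at a line-specific plateau. The functional form
#' is a modelling choice; only the rise-then-plateau shape is prescribed
#' by the data the generator emulates.
#'
#' @param maf Minor allele frequency, in \[0, 0.5\].
#' @param plateau Asymptotic R2, in (0, 1\].
#' @param scale MAF at which the curve reaches about 63\% of the plateau.
#'
#' @return Target squared-correlation accuracy, same length as `maf`.
#' @export
#' @examples
#' target_accuracy(0.05, plateau = 0.9, scale = 0.05)  # 0.9 * (1 - exp(-1))
target_accuracy <- function(maf, plateau = 0.9, scale = 0.05) {
  if (plateau <= 0 || plateau > 1) stop("`plateau` must be in (0, 1]", call. = FALSE)
  if (any(maf < 0 | maf > 0.5)) stop("`maf` must lie in [0, 0.5]", call. = FALSE)
  plateau * (1 - exp(-maf / scale))
}

#' Simulate imputation of genotypes with known per-SNP accuracy
#'
#' Emulates the uncertainty left by statistical imputation through a
#' posterior-mixture mechanism calibrated against the squared-correlation
#' accuracy measure. For SNP s with target accuracy r2, let
#' `pi = sqrt(r2)`. Each individual's observed genotype is the true
#' genotype with probability `pi` and otherwise a fresh Hardy-Weinberg
#' draw at the SNP's allele frequency. The reported genotype-probability
#' triplet is `pi * onehot(g_obs) + (1 - pi) * HWE(p)`, the dosage is its
#' expectation, and the hard call its argmax. Under this mechanism the
#' expected realized R2 (squared correlation of dosage with truth) equals
#' `pi^2 = r2`, so the generator is analytically calibrated.
#'
#' The GP triplets never use the true genotype directly, only the
#' resampled one, so the emitted tracks do not leak ground truth.
#'
#' @param gp A `genotype_panel` holding the true genotypes.
#' @param r2_target Per-SNP target accuracies in \[0, 1\] (recycled if
#'   scalar).
#' @param seed Integer seed.
#'
#' @return An object of class `dosage_panel`: `dosage` (n x m numeric in
#'   \[0, 2\]), `hard_call` (argmax-GP genotypes), `g_obs` (the resampled
#'   genotypes the GP tracks are built from), `pi`, `freq` (allele
#'   frequency used for the HWE component), `target_r2`, `realized_r2`,
#'   `estimated_r2` (truth-free allelic R2), and `map`. GP triplets are
#'   stored in this factored form; [gp_triplets()] reconstructs them
#'   exactly.
#' @export
simulate_imputation <- function(gp, r2_target, seed = 1) {
  stopifnot(inherits(gp, "genotype_panel"))
  n <- nrow(gp$calls); m <- ncol(gp$calls)
  r2_target <- rep_len(r2_target, m)
  if (any(r2_target < 0 | r2_target > 1)) {
    stop("`r2_target` must lie in [0, 1]", call. = FALSE)
  }
  set.seed(derive_seed(seed, "imputation"))

  p <- colMeans(gp$calls, na.rm = TRUE) / 2
  p[is.na(p)] <- 0  # fully missing column: treat as monomorphic reference
  pi_s <- sqrt(r2_target)

  g_obs <- matrix(0L, n, m)
  dosage <- matrix(0, n, m)
  for (s in seq_len(m)) {
    keep <- stats::runif(n) < pi_s[s]
    hwe <- stats::rbinom(n, 2L, p[s])
    truth <- gp$calls[, s]
    truth[is.na(truth)] <- hwe[is.na(truth)]  # missing truth: resampled call
    g_obs[, s] <- ifelse(keep, truth, hwe)
    # dosage = 0*GP0 + 1*GP1 + 2*GP2 with the factored GP
    dosage[, s] <- pi_s[s] * g_obs[, s] + (1 - pi_s[s]) * 2 * p[s]
  }

  dp <- list(dosage = dosage, g_obs = g_obs, pi = pi_s, freq = p,
             target_r2 = r2_target, map = gp$map)
  dp$hard_call <- hard_calls_from_gp(dp)
  dp$realized_r2 <- vapply(seq_len(m), function(s) {
    realized_r2(dosage[, s], gp$calls[, s])
  }, numeric(1))
  dp$estimated_r2 <- panel_estimated_r2(dp)
  class(dp) <- "dosage_panel"
  dp
}

#' Reconstruct genotype-probability triplets for one SNP
#'
#' @param dp A `dosage_panel`.
#' @param snp Column index of the SNP.
#' @return An n x 3 matrix of genotype probabilities (classes 0, 1, 2);
#'   rows sum to 1 and `GP %*% c(0, 1, 2)` reproduces the dosage exactly.
#' @export
gp_triplets <- function(dp, snp) {
  stopifnot(inherits(dp, "dosage_panel"))
  pi_s <- dp$pi[snp]; p <- dp$freq[snp]
  g <- dp$g_obs[, snp]
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  gp <- matrix(rep(hwe * (1 - pi_s), each = length(g)), ncol = 3)
  gp[cbind(seq_along(g), g + 1L)] <- gp[cbind(seq_along(g), g + 1L)] + pi_s
  colnames(gp) <- c("GP0", "GP1", "GP2")
  gp
}

# Hard call = argmax of the GP triplet (first maximum on ties, i.e. the
# lower genotype class; deterministic).
hard_calls_from_gp <- function(dp) {
  n <- nrow(dp$g_obs); m <- ncol(dp$g_obs)
  out <- matrix(0L, n, m)
  for (s in seq_len(m)) {
    pi_s <- dp$pi[s]; p <- dp$freq[s]
    hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    gp <- matrix(rep(hwe * (1 - pi_s), each = n), ncol = 3)
    idx <- cbind(seq_len(n), dp$g_obs[, s] + 1L)
    gp[idx] <- gp[idx] + pi_s
    out[, s] <- max.col(gp, ties.method = "first") - 1L
  }
  out
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat("dosage_panel:", nrow(x$dosage), "individuals x", ncol(x$dosage), "SNPs;",
      "mean target R2 =", round(mean(x$target_r2), 3),
      " mean realized R2 =", round(mean(x$realized_r2, na.rm = TRUE), 3), "\n")
  invisible(x)
}
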