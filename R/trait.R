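#' Simulate a heritable quantitative trait
#'
#' The trait follows the additive model y = sum_c x_c b_c + e. Causal
#' SNPs are sampled from `candidates` (all polymorphic SNPs by default).
#' Under the default `effect_model = "standardized"`, effects are drawn
#' as z_c / sqrt(2 p_c (1 - p_c)) with z i.i.d. standard normal, i.e.
#' every causal SNP explains the same expected variance regardless of
#' frequency — the architecture implicit in the standardized (Yang)
#' relationship matrix used by the association model, so that REML
#' variance components are estimands the generator actually realizes.
#' `effect_model = "iid"` draws the allele-count-scale effects i.i.d.
#' normal instead (rare causal variants then contribute little
#' variance).
#'
#' Genetic values and residuals are rescaled (the residual is first
#' orthogonalized against the genetic value) so that the realized
#' variance ratio equals `h2` and the total phenotypic variance equals
#' `pheno_var` exactly. Phenotypes are "pre-corrected" in the sense that
#' no fixed effects other than the intercept enter the model.
#'
#' @param gp A `genotype_panel`.
#' @param n_causal Number of causal SNPs, or `"all"` for every
#'   candidate (a fully polygenic trait).
#' @param h2 Narrow-sense heritability in \[0, 1\].
#' @param pheno_var Target phenotypic variance.
#' @param seed Integer seed.
#' @param intercept Trait mean; default 0 (phenotypes are deviations).
#' @param effect_model `"standardized"` (default) or `"iid"`; see
#'   Details.
#' @param candidates Optional column indices causal SNPs are drawn
#'   from; defaults to all polymorphic SNPs.
#'
#' @return An object of class `trait_model`: `phenotype` (numeric
#'   vector), `causal_idx` (column indices into `gp$calls`), `effects`
#'   (rescaled allele substitution effects), `intercept`,
#'   `realized_h2`.
#' @export
simulate_trait <- function(gp, n_causal, h2, pheno_var = 1, seed = 1,
                           intercept = 0,
                           effect_model = c("standardized", "iid"),
                           candidates = NULL) {
  stopifnot(inherits(gp, "genotype_panel"))
  effect_model <- match.arg(effect_model)
  if (h2 < 0 || h2 > 1) stop("`h2` must lie in [0, 1]", call. = FALSE)
  n <- nrow(gp$calls)
  set.seed(derive_seed(seed, "trait"))

  if (is.null(candidates)) candidates <- which(col_vars(gp$calls) > 0)
  if (identical(n_causal, "all")) n_causal <- length(candidates)
  n_causal <- as.integer(n_causal)
  if (n_causal == 0L && h2 > 0) {
    stop("`n_causal` must be positive when h2 > 0", call. = FALSE)
  }
  if (n_causal > length(candidates)) {
    stop("more causal SNPs requested than candidate SNPs available",
         call. = FALSE)
  }

  e <- stats::rnorm(n)
  if (n_causal > 0L) {
    causal <- if (n_causal == length(candidates)) sort(candidates) else
      sort(candidates[sample.int(length(candidates), n_causal)])
    b <- stats::rnorm(n_causal)
    if (effect_model == "standardized") {
      p <- colMeans(gp$calls[, causal, drop = FALSE], na.rm = TRUE) / 2
      if (any(p <= 0 | p >= 1)) {
        stop("candidate causal SNPs must be polymorphic", call. = FALSE)
      }
      b <- b / sqrt(2 * p * (1 - p))
    }
    g <- drop(gp$calls[, causal, drop = FALSE] %*% b)
  } else {
    causal <- integer(0)
    b <- numeric(0)
    g <- numeric(n)
  }

  # orthogonalize the residual against the genetic value so the realized
  # variance ratio is exactly h2 and Var(y) exactly pheno_var
  if (h2 > 0 && h2 < 1 && stats::var(g) > 0) {
    e <- unname(stats::resid(stats::lm(e ~ g)))
  }
  vg <- stats::var(g)
  if (h2 > 0 && vg == 0) {
    stop("causal genotypes carry no variance; cannot realize h2 > 0", call. = FALSE)
  }
  sg <- if (h2 > 0) sqrt(h2 * pheno_var / vg) else 0
  se <- if (h2 < 1) sqrt((1 - h2) * pheno_var / stats::var(e)) else 0
  g <- g * sg
  e <- e * se
  y <- intercept + g + e

  out <- list(phenotype = y, causal_idx = causal, effects = b * sg,
              intercept = intercept,
              realized_h2 = if (stats::var(y) > 0) stats::var(g) / stats::var(y) else 0,
              h2 = h2, pheno_var = pheno_var, effect_model = effect_model)
  class(out) <- "trait_model"
  out
}

# Column sample variances, NA-tolerant.
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x, na.rm = TRUE)
  (colMeans(x * x, na.rm = TRUE) - mu^2) * n / (n - 1)
}
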