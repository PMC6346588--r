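#' Simulate sequencing-derived annotations
#'
#' Generates the per-call and per-site fields that sequence-variant
#' filters act on: per-individual read depth (Poisson with the
#' configured mean), a Phred-scaled site quality (shifted gamma, so a
#' tunable fraction of sites falls below 20), and a missingness mask.
#' Only the filter thresholds downstream matter, not the exact noise
#' law, so simple count/quality distributions are used.
#'
#' @param gp A `genotype_panel`.
#' @param mean_depth Mean read depth per individual per site.
#' @param seed Integer seed.
#' @param qual_shift,qual_shape,qual_scale QUAL = `qual_shift +
#'   rgamma(shape = qual_shape, scale = qual_scale)`.
#' @param missing_rate Probability that a call is missing (independent of
#'   depth).
#'
#' @return An object of class `seq_annotations`: `depth` (n x m integer),
#'   `qual` (length-m numeric), `missing` (n x m logical).
#' @export
simulate_sequencing <- function(gp, mean_depth = 11.6, seed = 1,
                                qual_shift = 5, qual_shape = 2,
                                qual_scale = 30, missing_rate = 0.03) {
  stopifnot(inherits(gp, "genotype_panel"))
  if (mean_depth <= 0) stop("`mean_depth` must be positive", call. = FALSE)
  n <- nrow(gp$calls); m <- ncol(gp$calls)
  set.seed(derive_seed(seed, "sequencing"))
  depth <- matrix(stats::rpois(n * m, mean_depth), n, m)
  qual <- qual_shift + stats::rgamma(m, shape = qual_shape, scale = qual_scale)
  miss <- if (missing_rate > 0) {
    matrix(stats::runif(n * m) < missing_rate, n, m)
  } else {
    matrix(FALSE, n, m)
  }
  ann <- list(depth = depth, qual = qual, missing = miss)
  class(ann) <- "seq_annotations"
  ann
}
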