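#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a base seed and a stage label.
# Keeps results independent across stages while remaining a pure function
# of (seed, label). Result stays well below .Machine$integer.max.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483L + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
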