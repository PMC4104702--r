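#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Grid runs and replicates need many independent, named random streams
#' (effect-allele frequencies, perturbation masks, per-cohort genotypes,
#' residuals) that are all reproducible from one master seed. This folds the
#' master seed together with arbitrary labels through a multiplicative string
#' hash modulo the Mersenne prime 2^31 - 1, so derived seeds stay valid R
#' integer seeds and differ between any two distinct label paths.
#'
#' @param seed Master integer seed.
#' @param ... Labels (strings or numbers) identifying the substream, e.g.
#'   `derive_seed(1, "cohort", "genotypes")`.
#' @return A positive integer seed, strictly below 2^31.
#' @examples
#' derive_seed(1, "eaf")
#' derive_seed(1, "eaf") == derive_seed(1, "eaf")
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  labels <- paste(
    vapply(list(...), function(x) paste(format(x, digits = 15), collapse = ","),
           character(1)),
    collapse = "/"
  )
  h <- abs(as.double(seed)) %% 2147483647
  for (ch in utf8ToInt(labels)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h) + 1L
}

# Run `expr` under a derived seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched; otherwise use the ambient RNG stream.
with_substream <- function(seed, labels, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(do.call(derive_seed, c(list(seed), as.list(labels))), expr)
  }
}
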