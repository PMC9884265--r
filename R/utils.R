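#' Derive a reproducible sub-seed from a master seed and a label
#'
#' One master seed expands into independent per-component substreams keyed by
#' fixed labels, so adding a component to a workflow never perturbs the draws
#' of existing components. The result is a 31-bit non-negative integer
#' suitable for [set.seed()].
#'
#' @param seed Integer master seed.
#' @param label Character label of the substream (e.g. `"contacts"`).
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
substreamSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(label)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Round half away from zero to a fixed number of decimals
#'
#' Unlike [round()] (banker's rounding), 0.05 rounds to 0.1. Used for
#' percentage reporting.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## mean that returns NA (not NaN warning spam) on empty input
.safeMean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  mean(x)
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(abs(x - round(x)) < tol)
}
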