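#' @useDynLib coevoring, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd rmultinom runif rnorm
NULL

## The 20 canonical amino acids, alphabetical one-letter order.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
GAP <- "-"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr with a locally seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)
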