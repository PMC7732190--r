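# Internal helpers shared across modules.

#' @useDynLib lbazone, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize pgamma qgamma rgamma runif setNames sd cor
#' @importFrom utils read.table write.table head tail
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic stream derivation for replicate r of a run seeded with
# `seed`; keeps results independent of replicate execution order.
derive_seed <- function(seed, r) {
  as.integer((as.double(seed) * 48271 + as.double(r) * 16807) %% 2147483587L + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
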