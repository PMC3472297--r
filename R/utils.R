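#' @keywords internal
"_PACKAGE"

# Run `code` under a temporarily fixed RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL runs in the ambient RNG stream (used
# internally so one sample-level seed drives all draws).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-replicate seed stream; kept strictly below 2^31.
derive_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) %% 2147483629 + 10007 * as.numeric(i)) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
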