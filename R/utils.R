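#' Derive a reproducible substream seed from a master seed
#'
#' Each simulation concern (behavior, neural noise, plasticity, movie jitter)
#' draws from its own RNG stream so that changing one facet of a simulated
#' study leaves the others bit-identical. Streams are named; the substream
#' seed is a deterministic 31-bit hash of the master seed and the name.
#'
#' @param master_seed integer master seed.
#' @param stream character stream name, e.g. `"behavior"`.
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(master_seed, stream) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stream), length(stream) == 1L)
  h <- as.double(master_seed) %% 2147483647
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_prob <- function(x) is_number(x) && x >= 0 && x <= 1
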