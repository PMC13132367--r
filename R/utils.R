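# Internal helpers: argument checking and seed fan-out.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_(sprintf("'%s' must be a single finite number in [%s, %s]", name, lower, upper))
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_(sprintf("'%s' must be TRUE or FALSE", name))
  x
}

#' Derive a per-stream substream seed from one global seed
#'
#' All generators and seeded algorithms in the package draw their randomness
#' from a single integer seed fanned out to named substreams, so that each
#' stage is individually reproducible while stages stay decorrelated.
#'
#' @param seed integer global seed.
#' @param stream character stream name (e.g. \code{"bulk"}, \code{"tissue"}).
#' @return An integer seed below 2^31 suitable for \code{set.seed()}.
#' @export
substream_seed <- function(seed, stream) {
  seed <- check_number(seed, "seed")
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 7919 + 12345) %% 2147483629)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Row-wise minima of a dense matrix without matrixStats.
row_mins <- function(m) {
  out <- m[, 1L]
  if (ncol(m) > 1L) for (j in 2L:ncol(m)) out <- pmin(out, m[, j])
  out
}
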