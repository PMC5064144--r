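#' Derive a reproducible substream seed
#'
#' Fans a master seed out into per-stage or per-subject substreams so that a
#' stage (or a subset of subjects) can be regenerated in isolation without
#' replaying the whole random sequence.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer identifying the substream.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
substream_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- (abs(as.numeric(seed)) %% m) * 48271 + as.numeric(offset) * 69621
  as.integer(s %% (m - 1)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}
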