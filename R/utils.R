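# Internal helpers: classed conditions and reproducible seed substreams.

mn_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "myconet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

mn_warn <- function(msg) warning(msg, call. = FALSE)

#' Derive a reproducible substream seed
#'
#' Maps a root seed and a replicate index to an integer seed below 2^31,
#' so that replicate i always sees the same random stream regardless of
#' the order in which replicates are evaluated.
#'
#' @param seed integer root seed.
#' @param i replicate index (>= 0).
#' @return a single integer seed.
#' @keywords internal
substream_seed <- function(seed, i) {
  # splitmix-style integer mixing, kept in [0, 2^31 - 1]
  x <- (as.double(seed) %% 2147483647) + 1
  y <- (x * 48271 + as.double(i) * 1299709) %% 2147483647
  as.integer(y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# binarize a weight matrix
binarize <- function(w) {
  b <- (w > 0) * 1
  dimnames(b) <- dimnames(w)
  b
}

# stable decreasing order (original order breaks ties)
order_dec <- function(x) order(-x, seq_along(x))
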