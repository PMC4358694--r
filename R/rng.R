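#' Derive a reproducible RNG substream seed
#'
#' Hashes a master seed together with an arbitrary set of labels (scheme kind,
#' variable id, subsample size, replicate index, ...) into a 31-bit integer
#' seed, so that every replicate of every sweep draws from an independently
#' reproducible stream. The hash is a 32-bit FNV-1a variant reduced mod 2^31,
#' computed in exact double arithmetic.
#'
#' @param master integer master seed.
#' @param ... further labels (coerced to character) identifying the substream.
#' @return A single integer in `[0, 2^31)`, suitable for [set.seed()].
#' @examples
#' substream_seed(1, "random", "var7", 10, 1)
#' @export
substream_seed <- function(master, ...) {
  stopifnot(length(master) == 1, is.finite(master))
  key <- paste(c(format(master, scientific = FALSE), vapply(list(...),
    function(x) paste(as.character(x), collapse = ","), character(1))),
    collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 2166136261 %% 2^31
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    # h * 16777619 mod 2^31, split so every intermediate is exact in a double
    h <- (h * 403 + (h %% 128) * 16777216) %% 2^31
  }
  as.integer(h)
}

#' Seed of one sweep replicate
#'
#' The RNG substream contract for [run_sweep()]: the `(master seed, scheme,
#' variable, n)` tuple is hashed once with [substream_seed()], then replicate
#' `r` gets an affine step from that base (Knuth multiplicative constant mod
#' 2^31), so individual replicates are reproducible without rehashing.
#'
#' @param seed master seed.
#' @param scheme,variable_id,n sweep coordinates.
#' @param r replicate index (1-based).
#' @return Integer seed in `[0, 2^31)`.
#' @export
replicate_seed <- function(seed, scheme, variable_id, n, r) {
  base <- substream_seed(seed, scheme, variable_id, n)
  as.integer((base + (r %% 65536) * 40503 + r %% 32749 * 7) %% 2^31)
}

#' Evaluate an expression under a local RNG substream
#'
#' Sets the seed derived from `substream_seed(master, ...)`, evaluates `expr`,
#' and restores the caller's RNG state afterwards.
#'
#' @param expr expression to evaluate.
#' @param master,... passed to [substream_seed()].
#' @return The value of `expr`.
#' @keywords internal
with_substream <- function(expr, master, ...) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(master, ...))
  expr
}
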