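# Small shared utilities.

#' Derive a reproducible sub-seed from a master seed
#'
#' Every source of randomness in the package (weight initialization,
#' noise corruption, restart streams) draws its seed from the master
#' seed through a named substream, so that full runs are reproducible
#' and independent of execution order. The derivation is a simple
#' integer hash kept strictly below 2^31.
#'
#' @param master integer master seed.
#' @param stream substream name (character).
#' @param index integer index within the substream.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream, index = 1L) {
  h <- sum(utf8ToInt(as.character(stream)) * (31^(seq_along(utf8ToInt(as.character(stream))) %% 7)))
  s <- (as.numeric(master) %% 50021) * 40503 +
    (h %% 65521) * 17 + as.numeric(index) * 7919
  as.integer(s %% 2147483562) + 1L
}

# Evaluate an expression with a temporary RNG seed, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
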