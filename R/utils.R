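# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic entry points route through this so that a given seed gives
# bit-identical output regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic child seed from a master seed and a stage/iteration offset.
# A multiplicative mix (Lehmer-style, modulus 2^31 - 1) keeps the streams of
# nearby master seeds or offsets from colliding; plain seed + offset would
# make run (seed, i+1) reuse run (seed+1, i)'s stream. Exact in doubles:
# operands stay far below 2^53.
derive_seed <- function(seed, offset) {
  x <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(offset) * 16807
  as.integer(x %% 2147483647)
}

# Canonical unordered pair key "a|b" with a < b lexicographically.
edge_key <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste(lo, hi, sep = "|")
}
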