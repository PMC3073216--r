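# evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL uses the current
# RNG stream untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# clamp numeric values into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# row-major key for block-set operations
block_key <- function(blocks) {
  if (nrow(blocks) == 0L) return(character(0))
  paste(blocks$row, blocks$col, sep = ",")
}
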