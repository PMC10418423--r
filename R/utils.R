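# Run expr with a local RNG seed, restoring the caller's RNG state.
# All stochastic code in the package funnels through this, so seeds are
# explicit arguments and never mutate global state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a 32-bit hash of a character scalar; used for config fingerprints
# in run logs (stable across platforms, no external dependency).
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s) %% 256L
  h <- 2166136261
  for (b in bytes) {
    lb <- h %% 256
    h <- h - lb + bitwXor(as.integer(lb), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
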