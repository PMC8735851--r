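# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library randomness never leaks into user sessions.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-unit seed from a master seed, kept within 32-bit range.
derive_seed <- function(master, index, stream = 0L) {
  (as.integer(master) * 7919L + as.integer(index) * 104729L +
     as.integer(stream) * 13L) %% 2147483587L
}
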