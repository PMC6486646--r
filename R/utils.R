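`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-task seed derived from a master seed: replicate i is
# reproducible regardless of how many replicates are run, and the result
# stays inside the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) * 1000003 + as.double(i) * 7919
  as.integer(s %% 2147483646) + 1L
}
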