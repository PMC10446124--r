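# deterministic per-repetition seed stream: keeps every repetition
# independently reproducible from (master seed, index) and within the 32-bit
# integer range R's RNG accepts
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(i)) %% 2147483647L) + 1L
}

expit <- function(x) stats::plogis(x)

# n_reps x 3 table of RNG-scrambled seeds (data, simex, bootstrap streams),
# fully determined by the master seed
rep_seed_table <- function(seed, n_reps) {
  set.seed(seed)
  matrix(sample.int(2147483646L, 3L * n_reps), nrow = n_reps, ncol = 3L)
}
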