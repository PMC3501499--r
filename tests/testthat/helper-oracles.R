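# independently coded brute-force re-implementation of the subsampling
# count procedure, used as the oracle for bootstrap_min_sample_size();
# consumes the same documented per-(n_sub, repeat) substream seeds
brute_force_counts <- function(values, n_replicates, n_repeats, seed) {
  n <- length(values)
  m <- mean(values)
  s <- sd(values)
  out <- numeric(0)
  for (k in 2:(n - 1)) {
    tot <- 0
    for (r in seq_len(n_repeats)) {
      set.seed(rodiso:::substream_seed(seed, k, r))
      inside <- 0
      for (j in seq_len(n_replicates)) {
        sub <- sample(values, k)
        if (abs(mean(sub) - m) <= s) inside <- inside + 1
      }
      tot <- tot + inside
    }
    out[as.character(k)] <- tot / n_repeats
  }
  out
}
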