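# Fixture blocks built in code: the two worked examples plus random-block
# helpers used by the property suites.

# 4 patterns x 5 SNPs worked example; {S1, S2} is a minimal tag set.
block_4x5 <- function() {
  read_block(textConnection(c("00101", "01100", "10000", "11011")))
}

# 6 patterns x 8 SNPs greedy-initialization example with per-SNP
# distinguishability [9, 8, 8, 8, 9, 5, 9, 8].
block_6x8 <- function() {
  read_block(textConnection(c(
    "00101001", "01100011", "10000100",
    "11011011", "00111000", "10100011"
  )))
}

# Small founder-structured random block for property tests.
random_block <- function(seed, m = 6L, n = 10L) {
  generate_block(synthetic_block_spec(
    m = m, n = n, n_founders = 3L, recomb_rate = 0.1, noise_rate = 0.05,
    seed = seed
  ))
}

# Random chromosome under a local seed.
random_chrom <- function(n, seed) {
  set.seed(seed)
  sample(0:1, n, replace = TRUE)
}

# Brute-force pair-differ count: independent of the package's
# matrix-multiplication path (used as the oracle side of identities).
brute_pair_counts <- function(block, chrom) {
  pairs <- utils::combn(block$m, 2L)
  sel <- which(chrom == 1L)
  vapply(seq_len(ncol(pairs)), function(q) {
    sum(block$matrix[pairs[1L, q], sel] != block$matrix[pairs[2L, q], sel])
  }, numeric(1))
}
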