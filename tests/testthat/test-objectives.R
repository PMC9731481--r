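chrom_s1s2 <- c(1, 1, 0, 0, 0)

test_that("pairwise distinguish counts match hand counts on the 4x5 block", {
  b <- block_4x5()
  expect_equal(pairwise_distinguish_counts(b, rep(1, 5)), c(2L, 3L, 4L, 3L, 4L, 3L))
  expect_equal(pairwise_distinguish_counts(b, chrom_s1s2), c(1L, 1L, 2L, 2L, 1L, 1L))
  expect_equal(pairwise_distinguish_counts(b, rep(0, 5)), rep(0L, 6))
  expect_error(pairwise_distinguish_counts(b, c(1, 0)),
               class = "tagsnp_contract_error")
})

test_that("compactness counts selected SNPs", {
  expect_equal(compactness(c(1, 0, 1, 0, 0)), 2L)
  expect_equal(compactness(rep(0, 7)), 0L)
  expect_equal(compactness(rep(1, 5)), 5L)
})

test_that("tolerance is the minimum pairwise distinguish count", {
  b <- block_4x5()
  expect_equal(tolerance(b, rep(1, 5)), 2L)
  expect_equal(tolerance(b, chrom_s1s2), 1L)
  expect_equal(tolerance(b, rep(0, 5)), 0L)
})

test_that("hamming distance and distinguish-count paths agree entrywise", {
  b <- block_4x5()
  expect_equal(hamming_distances(b, chrom_s1s2), c(1L, 1L, 2L, 2L, 1L, 1L))
  expect_equal(hamming_distances(b, rep(0, 5)), rep(0L, 6))
  for (s in 1:10) {
    blk <- random_block(s)
    ch <- random_chrom(blk$n, 1000 + s)
    expect_equal(hamming_distances(blk, ch),
                 pairwise_distinguish_counts(blk, ch))
    expect_equal(pairwise_distinguish_counts(blk, ch),
                 as.integer(brute_pair_counts(blk, ch)))
  }
})

test_that("avg and variance of Hamming distances match hand-derived values", {
  b <- block_4x5()
  expect_equal(avg_hamming(b, chrom_s1s2), 4 / 3)
  expect_equal(avg_hamming(b, rep(1, 5)), 19 / 6)
  expect_equal(avg_hamming(b, rep(0, 5)), 0)
  expect_equal(variance_hamming(b, chrom_s1s2), 2 / 9)
  expect_equal(variance_hamming(b, rep(1, 5)), 17 / 36)
  b2 <- haplotype_block(rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L)))
  expect_equal(variance_hamming(b2, c(1, 1)), 2 / 9) # distances 1,1,2
  expect_equal(variance_hamming(b2, c(1, 0)), mean((c(0, 1, 1) - 2 / 3)^2))
  # equal pairwise distances -> zero variance
  b3 <- haplotype_block(rbind(c(0L, 0L), c(1L, 1L)))
  expect_equal(variance_hamming(b3, c(1, 1)), 0)
})

test_that("evaluate_chromosome composes the four objectives with directions", {
  b <- block_4x5()
  v <- evaluate_chromosome(b, rep(1, 5))
  expect_equal(as.numeric(v), c(5, 2, 19 / 6, 17 / 36))
  expect_equal(attr(v, "directions"),
               c(f1 = "min", f2 = "max", f3 = "max", f4 = "min"))
  expect_equal(as.numeric(evaluate_chromosome(b, chrom_s1s2)), c(2, 1, 4 / 3, 2 / 9))
  expect_equal(as.numeric(evaluate_chromosome(b, rep(0, 5))), c(0, 0, 0, 0))
})

test_that("objective bounds and monotonicity hold on random blocks", {
  for (s in 1:10) {
    blk <- random_block(s, m = 7L, n = 9L)
    ch <- random_chrom(blk$n, 2000 + s)
    v <- evaluate_chromosome(blk, ch)
    expect_lte(v[["f2"]], v[["f1"]])
    expect_lte(v[["f3"]], v[["f1"]])
    expect_gte(v[["f4"]], 0)
    expect_lte(v[["f2"]], tolerance(blk, rep(1, blk$n)))
    # flipping any gene 0 -> 1 never decreases D_ij, f1 or f2
    zero <- which(ch == 0)
    if (length(zero) > 0) {
      k <- zero[1]
      ch2 <- ch
      ch2[k] <- 1
      expect_true(all(pairwise_distinguish_counts(blk, ch2) >=
                        pairwise_distinguish_counts(blk, ch)))
      v2 <- evaluate_chromosome(blk, ch2)
      expect_gte(v2[["f2"]], v[["f2"]])
      expect_gte(v2[["f1"]], v[["f1"]])
    }
  }
})

test_that("full-selection f2 equals the brute-force minimum pair difference", {
  for (s in 1:5) {
    blk <- random_block(s)
    expect_equal(tolerance(blk, rep(1, blk$n)),
                 as.integer(min(brute_pair_counts(blk, rep(1, blk$n)))))
  }
})

test_that("rank_sum_fitness implements competition ranking over directions", {
  # single solution: rank 1 on each of four objectives
  expect_equal(rank_sum_fitness(matrix(c(3, 1, 2, 0.5), 1)), 4L)
  # a strictly better on every objective (respecting direction)
  objs <- rbind(c(2, 2, 2.5, 0.1), c(4, 1, 1.5, 0.3))
  expect_equal(rank_sum_fitness(objs), c(4L, 8L))
  # tie handling: brute-force ranks with ties.method = "min"
  o3 <- rbind(c(1, 1, 1, 1), c(2, 2, 2, 2), c(1, 3, 1, 3))
  # min-sense columns: f1, -f2, -f3, f4
  manual <- rowSums(apply(cbind(o3[, 1], -o3[, 2], -o3[, 3], o3[, 4]), 2,
                          rank, ties.method = "min"))
  expect_equal(rank_sum_fitness(o3), as.integer(manual))
  expect_error(rank_sum_fitness(matrix(numeric(0), 0, 4)),
               class = "tagsnp_contract_error")
})

test_that("a dominating solution never has larger rank-sum fitness", {
  for (s in 1:10) {
    set.seed(3000 + s)
    objs <- cbind(sample(0:10, 8, TRUE), sample(0:5, 8, TRUE),
                  runif(8, 0, 5), runif(8, 0, 2))
    fit <- rank_sum_fitness(objs)
    for (i in 1:7) for (j in (i + 1):8) {
      if (dominates(objs[i, ], objs[j, ])) expect_lte(fit[i], fit[j])
      if (dominates(objs[j, ], objs[i, ])) expect_lte(fit[j], fit[i])
    }
  }
})
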