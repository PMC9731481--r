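test_that("random_population is deterministic, Bernoulli(0.5), right shape", {
  p1 <- random_population(50, 10, seed = 7)
  p2 <- random_population(50, 10, seed = 7)
  expect_identical(p1$members, p2$members)
  expect_equal(dim(p1$members), c(10L, 50L))
  expect_equal(p1$provenance, "random")
  expect_equal(nrow(random_population(5, 1, seed = 1)$members), 1L)
  big <- random_population(1000, 200, seed = 3)
  expect_gt(mean(big$members), 0.45)
  expect_lt(mean(big$members), 0.55)
})

test_that("greedy_cover replays the printed 6x8 example at coverage 1", {
  b <- block_6x8()
  ch <- greedy_cover(b, 1)
  expect_equal(which(ch == 1), c(1L, 4L, 5L, 7L))
  # consideration order: distinguishability descending, index ascending ties
  expect_equal(attr(ch, "considered"), c(1L, 5L, 7L, 2L, 3L, 4L, 8L, 6L))
  expect_false(attr(ch, "saturated"))
  expect_gte(tolerance(b, ch), 1L)
})

test_that("greedy_cover meets coverage up to c_max and flags saturation beyond", {
  for (blk in list(block_4x5(), block_6x8(), random_block(5))) {
    c_max <- tolerance(blk, rep(1, blk$n))
    for (cv in seq_len(c_max)) {
      ch <- greedy_cover(blk, cv)
      expect_false(attr(ch, "saturated"))
      expect_gte(tolerance(blk, ch), cv)
    }
    over <- greedy_cover(blk, c_max + 1L)
    expect_true(attr(over, "saturated"))
    # best effort: every pair still reaches min(c, D_ij(all-ones))
    full <- pairwise_distinguish_counts(blk, rep(1, blk$n))
    got <- pairwise_distinguish_counts(blk, over)
    expect_true(all(got >= pmin(c_max + 1L, full)))
  }
})

test_that("greedy_cover compactness is non-decreasing in coverage", {
  for (blk in list(block_6x8(), random_block(9))) {
    c_max <- tolerance(blk, rep(1, blk$n))
    sizes <- vapply(seq_len(c_max), function(cv) compactness(greedy_cover(blk, cv)),
                    integer(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("the non-skipping variant adds every visited SNP until covered", {
  b <- block_6x8()
  ch <- greedy_cover(b, 1, skip_noncontributing = FALSE)
  # S2 and S3 are visited before coverage completes, so they are included
  expect_equal(which(ch == 1), c(1L, 2L, 3L, 4L, 5L, 7L))
  expect_gte(tolerance(b, ch), 1L)
})

test_that("greedy_population spans coverage targets and fills with mutants", {
  b <- block_6x8()
  c_max <- tolerance(b, rep(1, b$n))
  p <- greedy_population(b, 3, seed = 1)
  expect_equal(p$coverage_targets[seq_len(min(3, c_max))], seq_len(min(3, c_max)))
  sizes <- rowSums(p$members[seq_len(min(3, c_max)), , drop = FALSE])
  expect_true(all(diff(sizes) >= 0))
  expect_equal(nrow(greedy_population(b, 1, seed = 1)$members), 1L)
  # fillers: mutated copies, same length, deterministic
  big1 <- greedy_population(b, 20, seed = 5)
  big2 <- greedy_population(b, 20, seed = 5)
  expect_identical(big1$members, big2$members)
  expect_equal(dim(big1$members), c(20L, b$n))
  for (cv in seq_len(c_max)) {
    expect_gte(tolerance(b, greedy_population(b, c_max, seed = 2)$members[cv, ]), cv)
  }
})

test_that("greedy_population errors on blocks with an indistinguishable pair", {
  # two identical-after-constant-column rows cannot happen (validation), so
  # force an indistinguishable pair via a column that no selection separates:
  # impossible for distinct rows; instead check the c_max = 0 guard directly
  # with a mocked two-row block differing nowhere is invalid, so the error
  # path is exercised through a block whose duplicate rows are caught at
  # construction time.
  expect_error(haplotype_block(rbind(c(0L, 1L), c(0L, 1L))),
               class = "tagsnp_validation_error")
})

test_that("greedy populations spread f1 wider than random ones on structured blocks", {
  # statistical echo of the diversity motivation for greedy initialization:
  # median over seeds of the f1-range, founder-structured blocks
  n_seeds <- 20L
  g_range <- r_range <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    blk <- generate_block(synthetic_block_spec(
      m = 20, n = 200, n_founders = 3, recomb_rate = 0.01, noise_rate = 0.01,
      seed = 5000 + s
    ))
    gp <- greedy_population(blk, 200, seed = s)
    rp <- random_population(blk$n, 200, seed = s)
    g_range[s] <- diff(range(rowSums(gp$members)))
    r_range[s] <- diff(range(rowSums(rp$members)))
  }
  expect_gte(stats::median(g_range), stats::median(r_range))
})
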