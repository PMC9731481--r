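# Fronts used below are raw objective matrices (f1 min, f2 max, f3 max,
# f4 min) unless explicitly described as normalized.

test_that("normalize_fronts pools bounds and maps to [0,1]", {
  f1 <- rbind(c(2, 1, 1.5, 0.2), c(5, 2, 3.0, 0.1))
  f2 <- rbind(c(3, 0, 1.0, 0.4))
  nm <- normalize_fronts(list(f1, f2))
  all_vals <- do.call(rbind, nm$fronts)
  expect_true(all(all_vals >= 0 & all_vals <= 1))
  # pooled bounds equal elementwise min/max of per-front bounds
  nm1 <- normalize_fronts(f1)
  nm2 <- normalize_fronts(f2)
  expect_equal(nm$lower, pmin(nm1$lower, nm2$lower))
  expect_equal(nm$upper, pmax(nm1$upper, nm2$upper))
  # f1 endpoints map to 0 and 1
  expect_equal(nm$fronts[[1]][, "f1"], c(0, 1))
  # single solution: degenerate bounds map to all zeros
  single <- normalize_fronts(rbind(c(4, 2, 2.5, 0.3)))
  expect_equal(unname(single$fronts[[1]][1, ]), rep(0, 4))
  expect_error(normalize_fronts(list()), class = "tagsnp_contract_error")
})

test_that("range, summin and minsum match hand-computed examples", {
  expect_equal(range_metric(rbind(c(0.3, 0.3, 0.3, 0.3))), 0)
  expect_equal(range_metric(rbind(rep(0, 4), rep(1, 4))), 4)
  expect_equal(range_metric(rbind(c(0, 0, 0, 0), c(0.5, 0.25, 0, 1),
                                  c(1, 0.5, 0, 0))), 2.5)
  expect_equal(summin(rbind(rep(0, 4), rep(1, 4))), 0)
  expect_equal(summin(rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))), 0)
  expect_equal(summin(rbind(c(0.2, 0.3, 0.1, 0.4))), 1.0)
  expect_equal(minsum(rbind(rep(0, 4), rep(1, 4))), 0)
  expect_equal(minsum(rbind(c(1, 0, 1, 0), c(0, 1, 0, 1))), 2)
})

test_that("summin <= minsum and duplication invariance on random fronts", {
  for (s in 1:20) {
    set.seed(s)
    front <- matrix(runif(4 * 6), ncol = 4)
    expect_lte(summin(front), minsum(front))
    dup <- rbind(front, front[3, ])
    expect_equal(range_metric(dup), range_metric(front))
    expect_equal(summin(dup), summin(front))
    expect_equal(minsum(dup), minsum(front))
  }
})

test_that("tolerance rates divide f2 by f1 with a guarded zero", {
  expect_equal(tolerance_rates(rbind(c(5, 2, 1, 0))),
               c(max_rate = 0.4, avg_rate = 0.4))
  expect_equal(tolerance_rates(rbind(c(0, 0, 0, 0))),
               c(max_rate = 0, avg_rate = 0))
  got <- tolerance_rates(rbind(c(2, 1, 1, 0), c(4, 1, 1, 0)))
  expect_equal(got[["max_rate"]], 0.5)
  expect_equal(got[["avg_rate"]], 0.375)
})

test_that("avg_hamming_metric averages raw f3 over the front", {
  expect_equal(avg_hamming_metric(rbind(c(2, 1, 4 / 3, 0.2))), 4 / 3)
  expect_equal(avg_hamming_metric(rbind(c(1, 1, 2, 0), c(3, 1, 2, 0))), 2)
  expect_equal(avg_hamming_metric(rbind(c(1, 1, 1, 0), c(3, 1, 3, 0))), 2)
})

test_that("hypervolume handles the unit-box and two-box cases exactly", {
  # single member at the ideal corner
  expect_equal(as.numeric(hypervolume(rbind(rep(0, 4)), reference = rep(1, 4))), 1)
  # member equal to the reference contributes nothing
  expect_equal(as.numeric(hypervolume(rbind(rep(1, 4)), reference = rep(1, 4))), 0)
  # two boxes, inclusion-exclusion by hand:
  # vol(a) = 1*0.5^3 = 0.125, vol(b) = 0.5*1*1*1 = 0.5,
  # intersection corner = (0.5,0.5,0.5,0.5) -> 0.5^4 = 0.0625
  a <- c(0, 0.5, 0.5, 0.5)
  b <- c(0.5, 0, 0, 0)
  expect_equal(as.numeric(hypervolume(rbind(a, b), reference = rep(1, 4))),
               0.125 + 0.5 - 0.0625)
  expect_error(hypervolume(rbind(c(2, 0, 0, 0)), reference = rep(1, 4)),
               class = "tagsnp_contract_error")
})

test_that("hypervolume is monotone under nondominated additions", {
  for (s in 1:10) {
    set.seed(s)
    front <- matrix(runif(4 * 5), ncol = 4)
    hv <- as.numeric(hypervolume(front))
    extra <- rbind(front, runif(4))
    hv2 <- as.numeric(hypervolume(extra))
    expect_gte(hv2 + 1e-12, hv)
    # removing a dominated point changes nothing
    dominated <- pmin(front[1, ] + 0.05, 1)
    expect_equal(as.numeric(hypervolume(rbind(front, dominated))), hv)
  }
})

test_that("exact and Monte-Carlo hypervolume agree within 3 SE", {
  for (s in 1:8) {
    set.seed(100 + s)
    front <- matrix(runif(4 * sample(3:10, 1)), ncol = 4)
    exact <- as.numeric(hypervolume(front, reference = rep(1.1, 4)))
    mc <- hv_monte_carlo(front, reference = rep(1.1, 4),
                         samples = 20000L, seed = s)
    expect_lt(abs(exact - as.numeric(mc)), 3 * attr(mc, "se") + 1e-9)
  }
})

test_that("metric_report assembles the suite under pooled bounds", {
  b <- block_4x5()
  pf <- exhaustive_pareto_front(b)
  rep1 <- metric_report(pf$objectives)
  expect_s3_class(rep1, "tagsnp_metric_report")
  expect_equal(nrow(rep1$table), 1L)
  expect_true(all(c("range", "summin", "minsum", "hypervolume",
                    "max_tolerance_rate", "avg_tolerance_rate",
                    "avg_hamming") %in% names(rep1$table)))
  expect_lte(rep1$table$summin, rep1$table$minsum)
  expect_gte(rep1$table$hypervolume, 0)
  # the front contains (f1=3, f2=2): max tolerance rate 2/3
  expect_equal(rep1$table$max_tolerance_rate, 2 / 3)
})
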