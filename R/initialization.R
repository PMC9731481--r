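#' Random initial population
#'
#' Each gene is drawn i.i.d. Bernoulli(0.5). Deterministic for a fixed seed.
#'
#' @param n Chromosome length (the block's SNP count).
#' @param size Population size (>= 1).
#' @param seed RNG seed.
#' @return An object of class `tagsnp_population`: list with `members`
#'   (size x n binary matrix), `size`, `provenance = "random"`, `seed`.
#' @export
random_population <- function(n, size, seed = 1L) {
  stopifnot(n >= 1L, size >= 1L)
  members <- with_seed(seed, {
    matrix(sample(0:1, size * n, replace = TRUE), nrow = size, ncol = n)
  })
  storage.mode(members) <- "integer"
  structure(
    list(members = members, size = as.integer(size),
         provenance = "random", seed = as.integer(seed)),
    class = "tagsnp_population"
  )
}

#' Greedy set-cover chromosome at a coverage target
#'
#' SNPs are visited in decreasing order of [distinguishability()] (ties
#' broken by ascending SNP index). A SNP is added iff it distinguishes at
#' least one pattern pair whose current count of selected distinguishing
#' SNPs is below `coverage`; iteration stops when every pair is covered
#' `coverage` times or SNPs are exhausted (best-effort chromosome returned
#' with `saturated = TRUE`). With `skip_noncontributing = FALSE` every
#' visited SNP is added until all pairs are covered, the more literal
#' reading of sorted greedy selection.
#'
#' @param block A [haplotype_block].
#' @param coverage Required minimum `D_ij` across all pairs (>= 1).
#' @param skip_noncontributing Add only SNPs that raise a deficient pair's
#'   coverage (default TRUE; true greedy set-cover behavior).
#' @return Integer chromosome of length `block$n` with attributes
#'   `coverage`, `saturated`, `considered` (SNP visit order, 1-based).
#' @examples
#' b <- read_block(textConnection(c(
#'   "00101001", "01100011", "10000100",
#'   "11011011", "00111000", "10100011"
#' )))
#' ch <- greedy_cover(b, 1)
#' which(ch == 1) # SNPs 1, 4, 5, 7
#' @export
greedy_cover <- function(block, coverage = 1L, skip_noncontributing = TRUE) {
  stopifnot(inherits(block, "haplotype_block"), coverage >= 1L)
  d <- distinguishability(block)
  visit <- order(-d, seq_along(d))
  pdm <- pair_diff_matrix(block)
  cov <- integer(nrow(pdm))
  chrom <- integer(block$n)
  for (k in visit) {
    if (all(cov >= coverage)) break
    helps <- pdm[, k] == 1L & cov < coverage
    if (any(helps) || !skip_noncontributing) {
      chrom[k] <- 1L
      cov <- cov + pdm[, k]
    }
  }
  structure(chrom, coverage = as.integer(coverage),
            saturated = any(cov < coverage), considered = visit)
}

#' Greedy initial population over a range of coverage targets
#'
#' Members `1..min(size, c_max)` are [greedy_cover()] chromosomes at
#' coverage `1..c_max`, where `c_max = tolerance(block, all-ones)` is the
#' largest coverage any selection can reach. Remaining slots are filled
#' with bit-flip-mutated copies (rate `1/n`, seeded) of the coverage
#' chromosomes cycled in order, preserving the structured spread the greedy
#' scheme exists to provide.
#'
#' @inheritParams greedy_cover
#' @param size Population size (>= 1).
#' @param seed RNG seed for the mutated fillers.
#' @return A `tagsnp_population` with `provenance = "greedy"` and a
#'   `coverage_targets` field giving each greedy member's coverage.
#' @export
greedy_population <- function(block, size, seed = 1L, skip_noncontributing = TRUE) {
  stopifnot(inherits(block, "haplotype_block"), size >= 1L)
  c_max <- tolerance(block, rep(1L, block$n))
  if (c_max == 0L) {
    d <- pairwise_distinguish_counts(block, rep(1L, block$n))
    pp <- pattern_pairs(block$m)
    bad <- which(d == 0L)[1L]
    abort_tagsnp(
      sprintf("patterns %d and %d are identical across all SNPs; no tag set can distinguish them",
              pp[1L, bad], pp[2L, bad]),
      "tagsnp_init_error"
    )
  }
  n_greedy <- min(size, c_max)
  base <- do.call(rbind, lapply(seq_len(n_greedy), function(cv) {
    as.integer(greedy_cover(block, cv, skip_noncontributing))
  }))
  members <- base
  if (size > n_greedy) {
    fill_seeds <- derive_seeds(seed, size - n_greedy)
    fillers <- do.call(rbind, lapply(seq_len(size - n_greedy), function(q) {
      src <- base[((q - 1L) %% n_greedy) + 1L, ]
      bitflip_mutation(src, p_m = 1 / block$n, seed = fill_seeds[q])
    }))
    members <- rbind(base, fillers)
  }
  storage.mode(members) <- "integer"
  structure(
    list(members = members, size = as.integer(size), provenance = "greedy",
         seed = as.integer(seed),
         coverage_targets = c(seq_len(n_greedy),
                              ((seq_len(size - n_greedy) - 1L) %% n_greedy) + 1L)[seq_len(size)],
         c_max = c_max),
    class = "tagsnp_population"
  )
}

#' @export
print.tagsnp_population <- function(x, ...) {
  cat(sprintf("<tagsnp_population> %d members x %d genes (%s init, seed %d)\n",
              x$size, ncol(x$members), x$provenance, x$seed))
  invisible(x)
}
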