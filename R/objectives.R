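#' @name objectives
#' @title The four tag SNP selection objectives
#'
#' @description A candidate tag SNP set is encoded as a binary chromosome
#' `c = (c_1, ..., c_n)` over the block's `n` SNPs, `c_k = 1` meaning SNP
#' `S_k` is selected. Four objectives are evaluated jointly:
#'
#' * **f1 compactness** (minimize): the number of selected SNPs, `|S_T|`.
#' * **f2 tolerance** (maximize): `min_{i<j} D_ij(S_T)`, the minimum over
#'   pattern pairs of the number of selected SNPs distinguishing the pair.
#'   A value `v >= 1` means every pair is distinguished and the set
#'   tolerates `v - 1` missing SNPs; `v = 0` flags a selection that fails
#'   to separate some pair (a legal objective value, handled by dominance
#'   rather than a constraint).
#' * **f3 dissimilarity** (maximize): the average pairwise Hamming distance
#'   between patterns restricted to the selected SNPs.
#' * **f4 balance** (minimize): the population variance (divisor `C(m,2)`)
#'   of those pairwise Hamming distances.
#'
#' For binary alleles the pairwise Hamming distances coincide entrywise with
#' the pairwise distinguish counts `D_ij`; both entry points are provided
#' and the identity is asserted in the test suite via independent
#' implementations.
NULL

check_chrom <- function(block, chrom) {
  chrom <- as.integer(chrom)
  if (length(chrom) != block$n) {
    abort_tagsnp(
      sprintf("chromosome length %d != block SNP count %d", length(chrom), block$n),
      "tagsnp_contract_error"
    )
  }
  if (anyNA(chrom) || !all(chrom == 0L | chrom == 1L)) {
    abort_tagsnp("chromosome genes must all be 0 or 1", "tagsnp_contract_error")
  }
  chrom
}

# C(m,2) x n binary matrix: row (i,j) marks the SNPs at which patterns i and
# j differ. Computed once per block and reused by every evaluation.
pair_diff_matrix <- function(block) {
  pp <- pattern_pairs(block$m)
  mat <- block$matrix
  diffs <- abs(mat[pp[1L, ], , drop = FALSE] - mat[pp[2L, ], , drop = FALSE])
  storage.mode(diffs) <- "integer"
  diffs
}

#' Pairwise distinguish counts D_ij
#'
#' For every unordered pattern pair `(i, j)`, `i < j` (lexicographic order),
#' the number of selected SNPs at which the two patterns carry different
#' alleles.
#'
#' @param block A [haplotype_block].
#' @param chrom Binary vector of length `block$n`.
#' @return Integer vector of length `C(m, 2)`.
#' @export
pairwise_distinguish_counts <- function(block, chrom) {
  chrom <- check_chrom(block, chrom)
  as.integer(pair_diff_matrix(block) %*% chrom)
}

#' Compactness: number of selected tag SNPs
#'
#' @param chrom Binary vector.
#' @return Integer count of 1-genes.
#' @export
compactness <- function(chrom) {
  chrom <- as.integer(chrom)
  stopifnot(all(chrom == 0L | chrom == 1L))
  sum(chrom)
}

#' Tolerance: minimum pairwise distinguish count
#'
#' `min_{i<j} D_ij`; a value `v >= 1` tolerates `v - 1` missing SNPs, 0
#' flags a selection that leaves some pattern pair indistinguishable.
#'
#' @inheritParams pairwise_distinguish_counts
#' @return Integer.
#' @export
tolerance <- function(block, chrom) {
  min(pairwise_distinguish_counts(block, chrom))
}

#' Pairwise Hamming distances on the selected SNPs
#'
#' `H(P_i, P_j) = sum_{k selected} |P_(i,k) - P_(j,k)|`, in the same pair
#' order as [pairwise_distinguish_counts()]. Implemented by direct summation
#' of absolute allele differences (independent of the distinguish-count
#' path, so the binary-allele identity between the two can be asserted).
#'
#' @inheritParams pairwise_distinguish_counts
#' @return Integer vector of length `C(m, 2)`.
#' @export
hamming_distances <- function(block, chrom) {
  chrom <- check_chrom(block, chrom)
  sel <- which(chrom == 1L)
  pp <- pattern_pairs(block$m)
  sub <- block$matrix[, sel, drop = FALSE]
  as.integer(vapply(
    seq_len(ncol(pp)),
    function(q) sum(abs(sub[pp[1L, q], ] - sub[pp[2L, q], ])),
    numeric(1)
  ))
}

#' Average pairwise Hamming distance (dissimilarity, f3)
#'
#' @inheritParams pairwise_distinguish_counts
#' @return Mean of the `C(m,2)` pairwise distances; 0 for the empty
#'   selection.
#' @export
avg_hamming <- function(block, chrom) {
  mean(pairwise_distinguish_counts(block, chrom))
}

#' Variance of pairwise Hamming distances (balance, f4)
#'
#' Population variance with divisor `C(m,2)` (not `C(m,2) - 1`).
#'
#' @inheritParams pairwise_distinguish_counts
#' @return Non-negative real; 0 for the empty selection.
#' @export
variance_hamming <- function(block, chrom) {
  d <- pairwise_distinguish_counts(block, chrom)
  mean((d - mean(d))^2)
}

#' Objective directions
#'
#' Optimization direction of each objective on its original scale:
#' `c(f1 = "min", f2 = "max", f3 = "max", f4 = "min")`.
#' @return Named character vector.
#' @export
objective_directions <- function() {
  c(f1 = "min", f2 = "max", f3 = "max", f4 = "min")
}

#' Evaluate a chromosome against a block
#'
#' Computes all four objectives from a single pass over the pairwise
#' distinguish counts.
#'
#' @inheritParams pairwise_distinguish_counts
#' @return Named numeric vector `c(f1, f2, f3, f4)` with a `directions`
#'   attribute.
#' @examples
#' b <- read_block(textConnection(c("00101", "01100", "10000", "11011")))
#' evaluate_chromosome(b, c(1, 1, 0, 0, 0)) # the {S1, S2} tag set
#' @export
evaluate_chromosome <- function(block, chrom) {
  chrom <- check_chrom(block, chrom)
  d <- pairwise_distinguish_counts(block, chrom)
  structure(
    c(f1 = sum(chrom), f2 = min(d), f3 = mean(d), f4 = mean((d - mean(d))^2)),
    directions = objective_directions()
  )
}

# Vectorized evaluation of a population matrix (rows = chromosomes).
# Returns a size x 4 matrix on the original (paper) scales.
evaluate_population <- function(block, pop, pdm = pair_diff_matrix(block)) {
  stopifnot(is.matrix(pop), ncol(pop) == block$n)
  d <- pdm %*% t(pop) # C(m,2) x size
  means <- colMeans(d)
  cbind(
    f1 = rowSums(pop),
    f2 = apply(d, 2L, min),
    f3 = means,
    f4 = pmax(colMeans(d^2) - means^2, 0) # clamp float residue
  )
}

# Objectives in all-minimization sense (f2, f3 negated), used internally by
# every search strategy. Reported values are always on the original scales.
to_min_sense <- function(objs) {
  objs <- rbind(objs)
  cbind(objs[, 1L], -objs[, 2L], -objs[, 3L], objs[, 4L])
}

#' Rank-sum dominance fitness
#'
#' Each solution is ranked per objective from 1 (best, respecting that
#' objective's direction) to N (worst); a solution's fitness is the sum of
#' its four ranks, lower being better. Ties receive the same (minimum)
#' rank, i.e. standard competition ranking. Used as a secondary comparison
#' key in binary tournaments, not as a replacement for Pareto dominance.
#'
#' @param objs Matrix (or list of vectors) of objective values on the
#'   original scales, one row per solution, columns `f1..f4`.
#' @return Integer vector of fitness values (length = number of solutions).
#' @export
rank_sum_fitness <- function(objs) {
  if (is.list(objs)) objs <- do.call(rbind, objs)
  objs <- rbind(objs)
  if (nrow(objs) == 0L) {
    abort_tagsnp("rank_sum_fitness needs at least one solution", "tagsnp_contract_error")
  }
  fmin <- to_min_sense(objs)
  ranks <- apply(fmin, 2L, function(v) rank(v, ties.method = "min"))
  ranks <- rbind(ranks) # keep matrix shape for a single solution
  as.integer(rowSums(ranks))
}
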