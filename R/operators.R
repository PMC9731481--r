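#' Binary tournament selection
#'
#' Compares two evaluated candidates: the Pareto-dominating one wins; among
#' mutually nondominated candidates the lower rank-sum fitness (see
#' [rank_sum_fitness()], computed within the current population) wins;
#' remaining ties are broken uniformly at random.
#'
#' @param chrom_a,chrom_b The two candidate chromosomes.
#' @param obj_a,obj_b Their objective vectors (original scales).
#' @param fit_a,fit_b Their rank-sum fitness within the current population;
#'   if omitted, computed from the two candidates alone.
#' @param seed Optional seed for the random tie-break; if NULL the current
#'   RNG stream is used (the optimizers call it inside their own stream).
#' @return The winning chromosome.
#' @export
binary_tournament <- function(chrom_a, chrom_b, obj_a, obj_b,
                              fit_a = NULL, fit_b = NULL, seed = NULL) {
  if (dominates(obj_a, obj_b)) return(chrom_a)
  if (dominates(obj_b, obj_a)) return(chrom_b)
  if (is.null(fit_a) || is.null(fit_b)) {
    f <- rank_sum_fitness(rbind(obj_a, obj_b))
    fit_a <- f[1L]; fit_b <- f[2L]
  }
  if (fit_a < fit_b) return(chrom_a)
  if (fit_b < fit_a) return(chrom_b)
  pick <- if (is.null(seed)) stats::runif(1) < 0.5 else with_seed(seed, stats::runif(1) < 0.5)
  if (pick) chrom_a else chrom_b
}

#' Uniform crossover
#'
#' With probability `1 - p_c` returns copies of the parents; otherwise each
#' gene position independently swaps between the two offspring with
#' probability 0.5, so the offspring gene multiset at every position equals
#' the parents' multiset there.
#'
#' @param parent_a,parent_b Equal-length binary chromosomes.
#' @param p_c Crossover probability (default 0.7).
#' @param seed Optional seed; if NULL the current RNG stream is used.
#' @return List of two offspring chromosomes.
#' @export
uniform_crossover <- function(parent_a, parent_b, p_c = 0.7, seed = NULL) {
  if (length(parent_a) != length(parent_b)) {
    abort_tagsnp("parents must have equal length", "tagsnp_contract_error")
  }
  do_cross <- function() {
    if (stats::runif(1) >= p_c) return(list(parent_a, parent_b))
    swap <- stats::runif(length(parent_a)) < 0.5
    child_a <- parent_a; child_b <- parent_b
    child_a[swap] <- parent_b[swap]
    child_b[swap] <- parent_a[swap]
    list(child_a, child_b)
  }
  if (is.null(seed)) do_cross() else with_seed(seed, do_cross())
}

#' Bit-flip mutation
#'
#' Each gene is independently flipped (0 -> 1, 1 -> 0) with probability
#' `p_m` (the paper's setting: `1/l` for chromosome length `l`).
#'
#' @param chrom Binary chromosome.
#' @param p_m Per-gene flip probability in `[0, 1]`.
#' @param seed Optional seed; if NULL the current RNG stream is used.
#' @return Mutated chromosome (integer vector).
#' @export
bitflip_mutation <- function(chrom, p_m, seed = NULL) {
  stopifnot(p_m >= 0, p_m <= 1)
  do_mut <- function() {
    flips <- stats::runif(length(chrom)) < p_m
    out <- as.integer(chrom)
    out[flips] <- 1L - out[flips]
    out
  }
  if (is.null(seed)) do_mut() else with_seed(seed, do_mut())
}
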