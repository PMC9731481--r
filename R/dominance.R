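#' Pareto dominance between two objective vectors
#'
#' Solution `a` dominates `b` when `a` is at least as good on every
#' objective (respecting each objective's direction) and strictly better on
#' at least one.
#'
#' @param a,b Numeric objective vectors `c(f1, f2, f3, f4)` on the original
#'   scales.
#' @return TRUE iff `a` dominates `b`.
#' @export
dominates <- function(a, b) {
  am <- to_min_sense(a)[1L, ]
  bm <- to_min_sense(b)[1L, ]
  all(am <= bm) && any(am < bm)
}

# N x N logical matrix, [i, j] TRUE iff row i dominates row j.
# `fmin` is an objective matrix already in minimization sense.
dominance_matrix <- function(fmin) {
  n <- nrow(fmin)
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (j in seq_len(ncol(fmin))) {
    v <- fmin[, j]
    le <- le & outer(v, v, "<=")
    lt <- lt | outer(v, v, "<")
  }
  le & lt
}

#' Indices of the nondominated solutions
#'
#' @param objs Objective matrix on the original scales, one row per
#'   solution.
#' @return Integer indices of the rows not dominated by any other row.
#' @export
nondominated <- function(objs) {
  objs <- rbind(objs)
  dm <- dominance_matrix(to_min_sense(objs))
  which(colSums(dm) == 0L)
}

# Fast nondominated sorting: list of integer index vectors, front 1 first.
nondominated_sort <- function(fmin) {
  dm <- dominance_matrix(fmin)
  n_dominators <- colSums(dm)
  fronts <- list()
  remaining <- seq_len(nrow(fmin))
  while (length(remaining) > 0L) {
    cur <- remaining[n_dominators[remaining] == 0L]
    fronts[[length(fronts) + 1L]] <- cur
    remaining <- setdiff(remaining, cur)
    if (length(remaining) > 0L) {
      # discount dominators that just left
      n_dominators[remaining] <- n_dominators[remaining] -
        colSums(dm[cur, remaining, drop = FALSE])
    }
  }
  fronts
}

#' Exhaustively enumerate the Pareto front of a block
#'
#' Evaluates all `2^n` chromosomes and returns the globally nondominated
#' ones. Intended as a brute-force oracle for small `n` (<= ~16).
#'
#' @param block A [haplotype_block] with `n <= 20`.
#' @return List with `chromosomes` (matrix, one Pareto-optimal chromosome
#'   per row), `objectives` (matching objective matrix) and
#'   `front` (the unique objective vectors of the front, row-sorted).
#' @export
exhaustive_pareto_front <- function(block) {
  stopifnot(inherits(block, "haplotype_block"))
  if (block$n > 20L) {
    abort_tagsnp("exhaustive enumeration is limited to n <= 20", "tagsnp_contract_error")
  }
  n <- block$n
  chroms <- as.matrix(expand.grid(rep(list(0:1), n), KEEP.OUT.ATTRS = FALSE))
  colnames(chroms) <- NULL
  storage.mode(chroms) <- "integer"
  objs <- evaluate_population(block, chroms)
  idx <- nondominated(objs)
  list(
    chromosomes = chroms[idx, , drop = FALSE],
    objectives = objs[idx, , drop = FALSE],
    front = sort_rows(unique(round(objs[idx, , drop = FALSE], 12L)))
  )
}

# Deterministic row ordering for set-wise front comparison.
sort_rows <- function(x) {
  x <- rbind(x)
  x[do.call(order, as.data.frame(x)), , drop = FALSE]
}

# Unique objective vectors of a front, row-sorted, rounded to kill float fuzz.
canonical_front <- function(objs) {
  sort_rows(unique(round(rbind(objs), 12L)))
}
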