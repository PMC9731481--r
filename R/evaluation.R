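#' @name metrics
#' @title Front quality measures
#' @description Measures for comparing nondominated fronts across
#' algorithms and initializations. Range, SumMin, MinSum and hypervolume
#' operate on normalized minimization-sense objectives with bounds pooled
#' over all fronts under comparison (so compared algorithms share one
#' frame); tolerance rates and the average Hamming measure use raw
#' objective values, where ratios and means keep their meaning.
NULL

check_front <- function(front) {
  front <- rbind(front)
  if (nrow(front) == 0L) {
    abort_tagsnp("front must be non-empty", "tagsnp_contract_error")
  }
  front
}

#' Normalize one or more fronts to a shared [0, 1] frame
#'
#' Maximization objectives (f2, f3) are negated to minimization sense, then
#' every objective is min-max scaled with bounds pooled over all supplied
#' fronts. A degenerate objective (pooled max = min) maps to 0.
#'
#' @param fronts A single objective matrix (original scales, columns
#'   f1..f4) or a list of them.
#' @return List with `fronts` (list of normalized matrices, values in
#'   `[0, 1]`), `lower` and `upper` (the pooled minimization-sense bounds).
#' @export
normalize_fronts <- function(fronts) {
  if (!is.list(fronts)) fronts <- list(fronts)
  if (length(fronts) == 0L) {
    abort_tagsnp("need at least one front", "tagsnp_contract_error")
  }
  fmins <- lapply(fronts, function(fr) to_min_sense(check_front(fr)))
  pooled <- do.call(rbind, fmins)
  lower <- apply(pooled, 2L, min)
  upper <- apply(pooled, 2L, max)
  span <- upper - lower
  norm <- lapply(fmins, function(fm) {
    out <- sweep(sweep(fm, 2L, lower), 2L, ifelse(span > 0, span, 1), "/")
    out[, span == 0] <- 0
    colnames(out) <- c("f1", "f2", "f3", "f4")
    out
  })
  list(fronts = norm, lower = lower, upper = upper)
}

#' Range: summed per-objective spread of a normalized front
#'
#' Sum over the four objectives of (max - min) of the normalized values;
#' lies in `[0, 4]`. Measures diversity of the front in objective space.
#'
#' @param front Normalized objective matrix (rows = solutions).
#' @return Real in `[0, 4]`.
#' @export
range_metric <- function(front) {
  front <- check_front(front)
  sum(apply(front, 2L, max) - apply(front, 2L, min))
}

#' SumMin: sum of per-objective minima of a normalized front
#'
#' Lower is better: measures convergence toward the front's marginal
#' regions. The minima may come from different solutions, so
#' `summin(front) <= minsum(front)` always.
#'
#' @inheritParams range_metric
#' @return Real in `[0, 4]`.
#' @export
summin <- function(front) {
  front <- check_front(front)
  sum(apply(front, 2L, min))
}

#' MinSum: minimum solution-wise sum of a normalized front
#'
#' The smallest sum of the four normalized objectives over solutions;
#' measures convergence toward the central region of the front.
#'
#' @inheritParams range_metric
#' @return Real in `[0, 4]`.
#' @export
minsum <- function(front) {
  front <- check_front(front)
  min(rowSums(front))
}

#' Maximum and average tolerance rate of a front
#'
#' The tolerance rate of a solution is `f2 / f1` (tolerance per selected
#' SNP), defined as 0 when `f1 = 0`; since `f2 <= f1` it lies in `[0, 1]`.
#' Computed on raw objective values.
#'
#' @param front Raw objective matrix (original scales, columns f1..f4).
#' @return Named vector `c(max_rate, avg_rate)`.
#' @export
tolerance_rates <- function(front) {
  front <- check_front(front)
  rate <- ifelse(front[, 1L] > 0, front[, 2L] / front[, 1L], 0)
  c(max_rate = max(rate), avg_rate = mean(rate))
}

#' Average Hamming distance of a front
#'
#' Mean of the raw f3 (average pairwise Hamming distance) over the front's
#' solutions.
#'
#' @inheritParams tolerance_rates
#' @return Real >= 0.
#' @export
avg_hamming_metric <- function(front) {
  front <- check_front(front)
  mean(front[, 3L])
}

#' Hypervolume of a normalized front
#'
#' Lebesgue measure of the region dominated by the front up to a reference
#' point (minimization sense). Exact by inclusion-exclusion over the
#' nondominated members for fronts of up to `exact_threshold` points;
#' larger fronts are estimated by Monte Carlo with a reported standard
#' error.
#'
#' @param front Normalized minimization-sense objective matrix.
#' @param reference Reference point, componentwise >= every member
#'   (default `rep(1.1, 4)` for `[0, 1]`-normalized fronts).
#' @param exact_threshold Largest nondominated-front size computed exactly
#'   (default 14; inclusion-exclusion enumerates `2^k` subsets).
#' @param mc_samples Monte Carlo sample count above the threshold.
#' @param seed Seed for the Monte Carlo estimate.
#' @return Number with attributes `method` ("exact" or "monte_carlo") and,
#'   for Monte Carlo, `se` (standard error).
#' @export
hypervolume <- function(front, reference = rep(1.1, 4L),
                        exact_threshold = 14L, mc_samples = 1e5L,
                        seed = 1L) {
  front <- check_front(front)
  if (any(t(front) > reference + 1e-12)) {
    abort_tagsnp("reference point must weakly dominate no front member",
                 "tagsnp_contract_error")
  }
  nd <- front[nondominated_min(front), , drop = FALSE]
  if (nrow(nd) <= exact_threshold) {
    structure(hv_exact(nd, reference), method = "exact")
  } else {
    hv_monte_carlo(nd, reference, mc_samples, seed)
  }
}

# nondominated() works on original-scale objectives; this variant is for
# matrices already in minimization sense.
nondominated_min <- function(fmin) {
  which(colSums(dominance_matrix(rbind(fmin))) == 0L)
}

# Inclusion-exclusion over boxes [point, reference]: intersections of k
# boxes are boxes with lower corner = componentwise max.
hv_exact <- function(pts, reference) {
  n <- nrow(pts)
  if (n == 0L) return(0)
  total <- 0
  for (mask in seq_len(2^n - 1L)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    corner <- apply(pts[members, , drop = FALSE], 2L, max)
    vol <- prod(pmax(reference - corner, 0))
    total <- total + (-1)^(length(members) + 1L) * vol
  }
  total
}

#' Monte Carlo hypervolume estimate
#'
#' Uniform sampling in the box spanned by the front's ideal corner and the
#' reference point; the dominated fraction times the box volume estimates
#' the hypervolume. Exposed separately so it can serve as an independent
#' cross-check of the exact computation.
#'
#' @inheritParams hypervolume
#' @param samples Number of uniform samples.
#' @return Number with attributes `se` (binomial standard error, volume
#'   scale) and `method = "monte_carlo"`.
#' @export
hv_monte_carlo <- function(front, reference = rep(1.1, 4L),
                           samples = 1e5L, seed = 1L) {
  front <- check_front(front)
  lo <- apply(front, 2L, min)
  box <- prod(reference - lo)
  if (box <= 0) return(structure(0, se = 0, method = "monte_carlo"))
  hits <- with_seed(seed, {
    pts <- matrix(stats::runif(samples * length(lo)), ncol = length(lo))
    pts <- sweep(sweep(pts, 2L, reference - lo, "*"), 2L, lo, "+")
    # a sample counts when some front member weakly dominates it
    dominated <- rep(FALSE, samples)
    for (q in seq_len(nrow(front))) {
      covered <- rowSums(sweep(pts, 2L, front[q, ], "<")) == 0L
      dominated <- dominated | covered
    }
    sum(dominated)
  })
  p <- hits / samples
  structure(p * box, se = box * sqrt(p * (1 - p) / samples),
            method = "monte_carlo")
}

#' Metric report over a set of fronts
#'
#' Computes the full measure suite for each supplied front under pooled
#' normalization bounds: range, SumMin, MinSum and hypervolume on the
#' normalized fronts; max/average tolerance rate and average Hamming
#' distance on the raw fronts.
#'
#' @param fronts Raw objective matrix or list of them (e.g. one final
#'   front per run).
#' @param reference Hypervolume reference point per normalized axis
#'   (default 1.1).
#' @param hv_seed Seed for any Monte Carlo hypervolume fallback.
#' @return Object of class `tagsnp_metric_report`: list with `table` (one
#'   row per front: range, summin, minsum, hypervolume, max/avg tolerance
#'   rate, avg hamming, front size) and `bounds` (pooled normalization
#'   bounds).
#' @export
metric_report <- function(fronts, reference = rep(1.1, 4L), hv_seed = 1L) {
  if (!is.list(fronts)) fronts <- list(fronts)
  nm <- normalize_fronts(fronts)
  rows <- lapply(seq_along(fronts), function(q) {
    raw <- rbind(fronts[[q]])
    nf <- nm$fronts[[q]]
    tr <- tolerance_rates(raw)
    data.frame(
      front = q,
      size = nrow(raw),
      range = range_metric(nf),
      summin = summin(nf),
      minsum = minsum(nf),
      hypervolume = as.numeric(hypervolume(nf, reference, seed = hv_seed)),
      max_tolerance_rate = tr[["max_rate"]],
      avg_tolerance_rate = tr[["avg_rate"]],
      avg_hamming = avg_hamming_metric(raw)
    )
  })
  structure(
    list(table = do.call(rbind, rows),
         bounds = list(lower = nm$lower, upper = nm$upper),
         reference = reference),
    class = "tagsnp_metric_report"
  )
}

#' @export
print.tagsnp_metric_report <- function(x, ...) {
  cat(sprintf("<tagsnp_metric_report> %d front(s)\n", nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-generation metric traces for a finished run
#'
#' Recomputes the normalized measures along a run's per-generation fronts
#' using a fixed set of pooled bounds (by default the bounds of the run's
#' own generations; pass `bounds` from [normalize_fronts()] over several
#' runs to put traces of different algorithms on a common frame).
#'
#' @param run A `tagsnp_run`.
#' @param bounds Optional list with `lower`/`upper` minimization-sense
#'   bounds to reuse.
#' @return data.frame with one row per generation: front size, range,
#'   summin, minsum, max/avg tolerance rate, avg hamming.
#' @export
run_metric_traces <- function(run, bounds = NULL) {
  stopifnot(inherits(run, "tagsnp_run"))
  gens <- run$per_generation$front_objectives
  if (is.null(bounds)) {
    nm <- normalize_fronts(gens)
    lower <- nm$lower; upper <- nm$upper
  } else {
    lower <- bounds$lower; upper <- bounds$upper
  }
  span <- ifelse(upper - lower > 0, upper - lower, 1)
  rows <- lapply(seq_along(gens), function(g) {
    raw <- gens[[g]]
    nf <- sweep(sweep(to_min_sense(raw), 2L, lower), 2L, span, "/")
    nf[, upper - lower == 0] <- 0
    tr <- tolerance_rates(raw)
    data.frame(
      generation = g, size = nrow(raw),
      range = range_metric(nf), summin = summin(nf), minsum = minsum(nf),
      max_tolerance_rate = tr[["max_rate"]],
      avg_tolerance_rate = tr[["avg_rate"]],
      avg_hamming = avg_hamming_metric(raw)
    )
  })
  do.call(rbind, rows)
}
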