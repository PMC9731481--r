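# NSGA-III: nondominated sorting with reference-direction niching
# (Deb & Jain 2014). Reference directions are a Das-Dennis simplex lattice
# on the 4 objectives with the smallest partition count whose lattice size
# reaches the population size.

# All compositions of `total` into `parts` non-negative integers.
compositions <- function(total, parts) {
  if (parts == 1L) return(matrix(total, 1L, 1L))
  do.call(rbind, lapply(0:total, function(i) {
    cbind(i, compositions(total - i, parts - 1L))
  }))
}

#' Das-Dennis reference directions
#'
#' Uniform simplex-lattice weight vectors for `n_obj` objectives with `p`
#' partitions (`choose(p + n_obj - 1, n_obj - 1)` directions summing to 1).
#'
#' @param n_obj Number of objectives.
#' @param p Number of partitions.
#' @return Matrix of directions, one per row.
#' @export
das_dennis <- function(n_obj, p) {
  unname(compositions(p, n_obj)) / p
}

# Smallest p whose lattice size reaches `size`.
partitions_for <- function(size, n_obj = 4L) {
  p <- 1L
  while (choose(p + n_obj - 1L, n_obj - 1L) < size) p <- p + 1L
  p
}

# Achievement-scalarizing normalization of St (Deb & Jain 2014, simplified
# intercept handling with a nadir fallback on degenerate hyperplanes).
nsga3_normalize <- function(fmin, first_front) {
  ideal <- apply(fmin, 2L, min)
  tr <- sweep(fmin, 2L, ideal)
  n_obj <- ncol(fmin)
  extremes <- integer(n_obj)
  for (j in seq_len(n_obj)) {
    w <- rep(1e-6, n_obj)
    w[j] <- 1
    asf <- apply(sweep(tr, 2L, w, "/"), 1L, max)
    extremes[j] <- which.min(asf)
  }
  intercepts <- NULL
  E <- tr[extremes, , drop = FALSE]
  if (!anyDuplicated(extremes) && abs(det(E)) > 1e-12) {
    b <- tryCatch(solve(E, rep(1, n_obj)), error = function(e) NULL)
    if (!is.null(b) && all(b > 1e-12)) intercepts <- 1 / b
  }
  if (is.null(intercepts)) {
    intercepts <- apply(tr[first_front, , drop = FALSE], 2L, max)
  }
  intercepts[intercepts < 1e-12] <- 1
  sweep(tr, 2L, intercepts, "/")
}

# Associate each row with its nearest reference line (through the origin);
# returns list(dir = index, dist = perpendicular distance).
nsga3_associate <- function(fnorm, dirs) {
  dn <- dirs / sqrt(rowSums(dirs^2))
  proj <- fnorm %*% t(dn)                        # N x R projections
  sq <- rowSums(fnorm^2)
  d2 <- pmax(outer(sq, rep(1, nrow(dn))) - proj^2, 0)
  dir <- max.col(-d2, ties.method = "first")
  list(dir = dir, dist = sqrt(d2[cbind(seq_len(nrow(fnorm)), dir)]))
}

nsga3_survival <- function(fmin, size, dirs) {
  fronts <- nondominated_sort(fmin)
  chosen <- integer(0)
  l <- 0L
  repeat {
    l <- l + 1L
    if (length(chosen) + length(fronts[[l]]) > size) break
    chosen <- c(chosen, fronts[[l]])
    if (length(chosen) == size) return(chosen)
  }
  last <- fronts[[l]]
  st <- c(chosen, last)
  fnorm <- nsga3_normalize(fmin[st, , drop = FALSE],
                           match(fronts[[1L]], st))
  assoc <- nsga3_associate(fnorm, dirs)
  in_chosen <- seq_along(chosen)
  in_last <- length(chosen) + seq_along(last)
  niche <- tabulate(assoc$dir[in_chosen], nbins = nrow(dirs))
  cand_by_dir <- split(in_last, assoc$dir[in_last])
  active <- as.integer(names(cand_by_dir))
  need <- size - length(chosen)
  picked <- integer(0)
  while (need > 0L && length(active) > 0L) {
    jmin <- active[niche[active] == min(niche[active])]
    j <- if (length(jmin) == 1L) jmin else jmin[sample.int(length(jmin), 1L)]
    key <- as.character(j)
    cands <- cand_by_dir[[key]]
    if (length(cands) == 0L) {
      active <- setdiff(active, j)
      next
    }
    pick <- if (niche[j] == 0L) {
      cands[which.min(assoc$dist[cands])]
    } else if (length(cands) == 1L) {
      cands
    } else {
      cands[sample.int(length(cands), 1L)]
    }
    picked <- c(picked, pick)
    cand_by_dir[[key]] <- setdiff(cands, pick)
    niche[j] <- niche[j] + 1L
    need <- need - 1L
  }
  st[c(in_chosen, picked)]
}

run_nsga3 <- function(block, config, pop, pdm, p_m) {
  dirs <- das_dennis(4L, partitions_for(config$pop_size))
  objs <- evaluate_population(block, pop, pdm)
  trace <- new_trace()
  for (gen in seq_len(config$generations)) {
    kids <- make_offspring(pop, objs, config$offspring_size, config$p_c, p_m)
    kobjs <- evaluate_population(block, kids, pdm)
    all_pop <- rbind(pop, kids)
    all_objs <- rbind(objs, kobjs)
    keep <- nsga3_survival(to_min_sense(all_objs), config$pop_size, dirs)
    pop <- all_pop[keep, , drop = FALSE]
    objs <- all_objs[keep, , drop = FALSE]
    trace <- trace_record(trace, objs)
  }
  list(pop = pop, objs = objs, trace = trace)
}
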