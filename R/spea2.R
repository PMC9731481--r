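# SPEA2: strength/raw-fitness + k-NN density, fixed-size archive with
# truncation (Zitzler, Laumanns & Thiele 2001). The archive is the mating
# pool and the reporting set.

spea2_fitness <- function(fmin) {
  n <- nrow(fmin)
  dm <- dominance_matrix(fmin)
  strength <- rowSums(dm)
  raw <- as.numeric(t(dm) %*% strength) # sum of strengths of dominators
  d <- as.matrix(stats::dist(fmin))
  k <- max(1L, floor(sqrt(n)))
  sigma_k <- apply(d, 1L, function(row) sort(row)[k + 1L]) # skip self (0)
  raw + 1 / (sigma_k + 2)
}

# Iterative nearest-neighbor truncation of the nondominated set down to
# `size`, removing at each step the point with lexicographically smallest
# sorted distance vector to the others. Sorted distance vectors are only
# materialized for candidates tied on the nearest-neighbor distance, which
# keeps the common case O(N^2) per removal.
spea2_truncate <- function(fmin, size) {
  alive <- seq_len(nrow(fmin))
  d <- as.matrix(stats::dist(fmin))
  diag(d) <- Inf
  while (length(alive) > size) {
    sub <- d[alive, alive, drop = FALSE]
    nn1 <- apply(sub, 1L, min)
    cands <- which(nn1 == min(nn1))
    if (length(cands) > 1L) {
      sorted <- apply(sub[cands, , drop = FALSE], 1L, sort) # cols = candidates
      lvl <- 1L
      while (length(cands) > 1L && lvl < nrow(sorted)) {
        lvl <- lvl + 1L
        keep <- which(sorted[lvl, ] == min(sorted[lvl, ]))
        sorted <- sorted[, keep, drop = FALSE]
        cands <- cands[keep]
      }
    }
    alive <- alive[-cands[1L]]
  }
  alive
}

# Environmental selection: indices of the next archive within the combined
# set. Exact duplicates in objective space sit at nearest-neighbor distance
# zero, so the lexicographic truncation rule always removes them first;
# they are collapsed directly (keeping the earliest copy) before the
# distance-based truncation runs on the remaining distinct points.
spea2_survival <- function(fmin, size) {
  fit <- spea2_fitness(fmin)
  nd <- which(fit < 1)
  if (length(nd) > size) {
    keys <- apply(fmin[nd, , drop = FALSE], 1L, paste, collapse = "|")
    dup <- which(duplicated(keys))
    excess <- length(nd) - size
    if (length(dup) >= excess) {
      nd <- nd[-rev(dup)[seq_len(excess)]]
    } else {
      if (length(dup) > 0L) nd <- nd[-dup]
      nd <- nd[spea2_truncate(fmin[nd, , drop = FALSE], size)]
    }
    nd
  } else if (length(nd) < size) {
    dominated <- setdiff(order(fit), nd)
    c(nd, dominated[seq_len(size - length(nd))])
  } else {
    nd
  }
}

run_spea2 <- function(block, config, pop, pdm, p_m) {
  objs <- evaluate_population(block, pop, pdm)
  archive <- pop[integer(0), , drop = FALSE]
  arch_objs <- objs[integer(0), , drop = FALSE]
  trace <- new_trace()
  for (gen in seq_len(config$generations)) {
    all_pop <- rbind(pop, archive)
    all_objs <- rbind(objs, arch_objs)
    keep <- spea2_survival(to_min_sense(all_objs), config$pop_size)
    archive <- all_pop[keep, , drop = FALSE]
    arch_objs <- all_objs[keep, , drop = FALSE]
    trace <- trace_record(trace, arch_objs)
    if (gen < config$generations) {
      pop <- make_offspring(archive, arch_objs, config$offspring_size,
                            config$p_c, p_m)
      objs <- evaluate_population(block, pop, pdm)
    }
  }
  list(pop = archive, objs = arch_objs, trace = trace)
}
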