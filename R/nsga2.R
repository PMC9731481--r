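# NSGA-II: fast nondominated sorting + crowding-distance survival
# (Deb et al. 2002), binary encoding.

# Crowding distance on a minimization-sense objective matrix.
crowding_distance <- function(fmin) {
  n <- nrow(fmin)
  if (n <= 2L) return(rep(Inf, n))
  cd <- numeric(n)
  for (j in seq_len(ncol(fmin))) {
    o <- order(fmin[, j])
    v <- fmin[o, j]
    cd[o[c(1L, n)]] <- Inf
    rng <- v[n] - v[1L]
    if (rng > 0) {
      mid <- o[2:(n - 1L)]
      cd[mid] <- cd[mid] + (v[3:n] - v[1:(n - 2L)]) / rng
    }
  }
  cd
}

# Select `size` survivors from combined pop by rank, crowding on the split
# front. Returns integer indices.
nsga2_survival <- function(fmin, size) {
  fronts <- nondominated_sort(fmin)
  chosen <- integer(0)
  for (fr in fronts) {
    if (length(chosen) + length(fr) <= size) {
      chosen <- c(chosen, fr)
      if (length(chosen) == size) break
    } else {
      need <- size - length(chosen)
      cd <- crowding_distance(fmin[fr, , drop = FALSE])
      # stable order: larger crowding first, index as deterministic tie-break
      chosen <- c(chosen, fr[order(-cd, fr)][seq_len(need)])
      break
    }
  }
  chosen
}

run_nsga2 <- function(block, config, pop, pdm, p_m) {
  objs <- evaluate_population(block, pop, pdm)
  trace <- new_trace()
  for (gen in seq_len(config$generations)) {
    kids <- make_offspring(pop, objs, config$offspring_size, config$p_c, p_m)
    kobjs <- evaluate_population(block, kids, pdm)
    all_pop <- rbind(pop, kids)
    all_objs <- rbind(objs, kobjs)
    keep <- nsga2_survival(to_min_sense(all_objs), config$pop_size)
    pop <- all_pop[keep, , drop = FALSE]
    objs <- all_objs[keep, , drop = FALSE]
    trace <- trace_record(trace, objs)
  }
  list(pop = pop, objs = objs, trace = trace)
}
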