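# MOEA/D: Tchebycheff decomposition with weight-vector neighborhoods and
# steady-state replacement (Zhang & Li 2007). One "generation" is pop_size
# single-offspring updates, so evaluation budgets match the generational
# strategies. No external archive: the final front is extracted from the
# final population.

# Exactly `size` weight vectors: the smallest Das-Dennis lattice holding
# `size` directions, thinned deterministically (evenly spaced in lattice
# order) when larger.
moead_weights <- function(size, n_obj = 4L) {
  W <- das_dennis(n_obj, partitions_for(size, n_obj))
  if (nrow(W) > size) {
    W <- W[round(seq(1L, nrow(W), length.out = size)), , drop = FALSE]
  }
  W
}

# Tchebycheff aggregation, minimization sense; zero weights floored so every
# objective keeps some influence.
tchebycheff <- function(fmin, w, z) {
  w <- pmax(w, 1e-6)
  if (is.matrix(fmin)) {
    apply(sweep(abs(sweep(fmin, 2L, z)), 2L, w, "*"), 1L, max)
  } else {
    max(w * abs(fmin - z))
  }
}

run_moead <- function(block, config, pop, pdm, p_m) {
  N <- config$pop_size
  W <- moead_weights(N)
  T_size <- min(config$neighborhood, N)
  dw <- as.matrix(stats::dist(W))
  B <- t(apply(dw, 1L, function(row) order(row)[seq_len(T_size)]))
  objs <- evaluate_population(block, pop, pdm)
  fmin <- to_min_sense(objs)
  z <- apply(fmin, 2L, min) # ideal point, updated as better values appear
  trace <- new_trace()
  for (gen in seq_len(config$generations)) {
    for (i in seq_len(N)) {
      mates <- B[i, sample.int(T_size, 2L, replace = FALSE)]
      off <- uniform_crossover(pop[mates[1L], ], pop[mates[2L], ], config$p_c)
      y <- bitflip_mutation(off[[1L]], p_m) # steady state: one offspring
      y_obj <- evaluate_population(block, matrix(y, 1L), pdm)[1L, ]
      y_min <- to_min_sense(y_obj)[1L, ]
      z <- pmin(z, y_min)
      for (j in B[i, ]) {
        if (tchebycheff(y_min, W[j, ], z) <= tchebycheff(fmin[j, ], W[j, ], z)) {
          pop[j, ] <- y
          objs[j, ] <- y_obj
          fmin[j, ] <- y_min
        }
      }
    }
    trace <- trace_record(trace, objs)
  }
  list(pop = pop, objs = objs, trace = trace)
}
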