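#' Configure an evolutionary tag SNP search
#'
#' Defaults follow the published protocol for this problem: population 200,
#' offspring 200, 500 generations, uniform crossover with `p_c = 0.7`,
#' bit-flip mutation with `p_m = 1/l` (`l` = chromosome length),
#' neighborhood size 15 for MOEA/D.
#'
#' @param algorithm One of `"NSGA2"`, `"SPEA2"`, `"NSGA3"`, `"MOEAD"`
#'   (case-insensitive).
#' @param pop_size Population size (>= 2, default 200).
#' @param offspring_size Offspring per generation (default = `pop_size`).
#'   MOEA/D is steady-state: one generation is defined as `pop_size`
#'   single-offspring updates so evaluation budgets match across
#'   algorithms.
#' @param generations Number of generations (default 500).
#' @param p_c Crossover probability (default 0.7).
#' @param p_m Per-gene mutation probability; NULL (default) means `1/n`
#'   for an n-SNP block.
#' @param neighborhood MOEA/D neighborhood size (default 15, clamped to
#'   `pop_size`).
#' @param init Initialization method, `"random"` or `"greedy"`.
#' @param seed Run seed; the whole run is a pure function of
#'   (block, config).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(algorithm = c("NSGA2", "SPEA2", "NSGA3", "MOEAD"),
                      pop_size = 200L, offspring_size = NULL,
                      generations = 500L, p_c = 0.7, p_m = NULL,
                      neighborhood = 15L, init = c("random", "greedy"),
                      seed = 1L) {
  algorithm <- toupper(algorithm)
  algorithm <- match.arg(algorithm, c("NSGA2", "SPEA2", "NSGA3", "MOEAD"))
  init <- match.arg(init)
  pop_size <- as.integer(pop_size)
  offspring_size <- as.integer(offspring_size %||% pop_size)
  generations <- as.integer(generations)
  neighborhood <- as.integer(neighborhood)
  if (pop_size < 2L || generations < 1L) {
    abort_tagsnp("need pop_size >= 2 and generations >= 1", "tagsnp_config_error")
  }
  if (p_c < 0 || p_c > 1 || (!is.null(p_m) && (p_m < 0 || p_m > 1))) {
    abort_tagsnp("p_c and p_m must lie in [0, 1]", "tagsnp_config_error")
  }
  if (neighborhood < 2L) {
    abort_tagsnp("neighborhood must be >= 2", "tagsnp_config_error")
  }
  structure(
    list(algorithm = algorithm, pop_size = pop_size,
         offspring_size = offspring_size, generations = generations,
         p_c = p_c, p_m = p_m, neighborhood = min(neighborhood, pop_size),
         init = init, seed = as.integer(seed)),
    class = "ga_config"
  )
}

# Tournament by index against precomputed objectives and rank-sum fitness.
tournament_pick <- function(pool_objs, fit, a, b) {
  if (dominates(pool_objs[a, ], pool_objs[b, ])) return(a)
  if (dominates(pool_objs[b, ], pool_objs[a, ])) return(b)
  if (fit[a] < fit[b]) return(a)
  if (fit[b] < fit[a]) return(b)
  if (stats::runif(1) < 0.5) a else b
}

# Generational variation shared by NSGA-II, SPEA2 and NSGA-III: binary
# tournaments (dominance, then rank-sum fitness) over the mating pool, then
# uniform crossover and bit-flip mutation. Uses the current RNG stream.
make_offspring <- function(pool, pool_objs, count, p_c, p_m) {
  fit <- rank_sum_fitness(pool_objs)
  kids <- matrix(0L, count, ncol(pool))
  q <- 1L
  while (q <= count) {
    c1 <- sample.int(nrow(pool), 2L, replace = TRUE)
    c2 <- sample.int(nrow(pool), 2L, replace = TRUE)
    p1 <- tournament_pick(pool_objs, fit, c1[1L], c1[2L])
    p2 <- tournament_pick(pool_objs, fit, c2[1L], c2[2L])
    off <- uniform_crossover(pool[p1, ], pool[p2, ], p_c)
    kids[q, ] <- bitflip_mutation(off[[1L]], p_m)
    q <- q + 1L
    if (q <= count) {
      kids[q, ] <- bitflip_mutation(off[[2L]], p_m)
      q <- q + 1L
    }
  }
  kids
}

initial_population <- function(block, config, init_seed) {
  if (config$init == "greedy") {
    greedy_population(block, config$pop_size, seed = init_seed)$members
  } else {
    random_population(block$n, config$pop_size, seed = init_seed)$members
  }
}

# Nondominated front of a set, deduplicated by chromosome, deterministically
# ordered (by f1, then f2, ...).
extract_front <- function(pop, objs) {
  keep <- !duplicated(apply(pop, 1L, paste, collapse = ""))
  pop <- pop[keep, , drop = FALSE]
  objs <- objs[keep, , drop = FALSE]
  idx <- nondominated(objs)
  ord <- idx[do.call(order, as.data.frame(objs[idx, , drop = FALSE]))]
  list(chromosomes = pop[ord, , drop = FALSE],
       objectives = objs[ord, , drop = FALSE])
}

#' Run one evolutionary tag SNP selection
#'
#' Executes the configured search strategy on a block and returns the final
#' deduplicated nondominated front plus per-generation traces. Maximization
#' objectives (f2, f3) are negated internally so every strategy minimizes;
#' all reported objective values are on the original scales and directions.
#'
#' @param block A [haplotype_block].
#' @param config A [ga_config].
#' @return An object of class `tagsnp_run`: list with `config`,
#'   `block_dim`, `final_front` (list of `chromosomes` and `objectives`),
#'   `per_generation` (list with `front_size` and `front_objectives`, one
#'   objective matrix per generation), `seed`, `elapsed` (seconds,
#'   informational).
#' @examples
#' b <- read_block(textConnection(c("00101", "01100", "10000", "11011")))
#' r <- run_ga(b, ga_config("NSGA2", pop_size = 20, generations = 30, seed = 1))
#' r$final_front$objectives
#' @export
run_ga <- function(block, config) {
  stopifnot(inherits(block, "haplotype_block"), inherits(config, "ga_config"))
  t0 <- proc.time()[["elapsed"]]
  p_m <- config$p_m %||% (1 / block$n)
  pdm <- pair_diff_matrix(block)
  seeds <- derive_seeds(config$seed, 2L)
  pop <- initial_population(block, config, seeds[1L])
  state <- with_seed(seeds[2L], {
    switch(config$algorithm,
      NSGA2 = run_nsga2(block, config, pop, pdm, p_m),
      SPEA2 = run_spea2(block, config, pop, pdm, p_m),
      NSGA3 = run_nsga3(block, config, pop, pdm, p_m),
      MOEAD = run_moead(block, config, pop, pdm, p_m)
    )
  })
  front <- extract_front(state$pop, state$objs)
  structure(
    list(config = config, block_dim = c(m = block$m, n = block$n),
         final_front = front,
         per_generation = state$trace,
         seed = config$seed,
         elapsed = proc.time()[["elapsed"]] - t0),
    class = "tagsnp_run"
  )
}

#' @export
print.tagsnp_run <- function(x, ...) {
  cat(sprintf("<tagsnp_run> %s/%s init, %d generations, pop %d, seed %d\n",
              x$config$algorithm, x$config$init, x$config$generations,
              x$config$pop_size, x$seed))
  cat(sprintf("  block %d patterns x %d SNPs; final front: %d solutions\n",
              x$block_dim[["m"]], x$block_dim[["n"]],
              nrow(x$final_front$objectives)))
  cat(sprintf("  f1 range [%g, %g], best f2 %g\n",
              min(x$final_front$objectives[, "f1"]),
              max(x$final_front$objectives[, "f1"]),
              max(x$final_front$objectives[, "f2"])))
  invisible(x)
}

# Shared trace recorder: nondominated front of the current reporting set.
trace_record <- function(trace, objs) {
  idx <- nondominated(objs)
  trace$front_size <- c(trace$front_size, length(idx))
  trace$front_objectives[[length(trace$front_objectives) + 1L]] <-
    objs[idx, , drop = FALSE]
  trace
}

new_trace <- function() list(front_size = integer(0), front_objectives = list())
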