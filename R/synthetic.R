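#' Specification for a synthetic haplotype block
#'
#' The generator emulates the shape of real haplotype blocks (tens of
#' distinct patterns over up to ~1000+ SNPs) using a founder/recombination
#' scheme: a small set of founder haplotypes is drawn, each pattern is a
#' mosaic of founders (switching founder with probability `recomb_rate` at
#' each SNP) with per-allele noise flips. This induces the column correlation
#' (LD-like structure) that makes greedy, distinguishability-driven
#' initialization meaningful; i.i.d. Bernoulli columns are recovered with
#' `n_founders = m`, `recomb_rate = 1`.
#'
#' @param m Number of distinct haplotype patterns (>= 2).
#' @param n Number of SNPs (>= 1).
#' @param n_founders Number of founder haplotypes, in `[1, m]` (default 3).
#' @param recomb_rate Per-SNP probability of switching founder while copying
#'   (default 0.01).
#' @param noise_rate Per-allele flip probability after copying (default 0.01).
#' @param seed RNG seed; generation is a pure function of the spec.
#' @param forbid_constant_columns If TRUE, constant columns are re-randomized
#'   so every SNP is polymorphic within the block (default TRUE).
#' @return An object of class `synthetic_block_spec`.
#' @export
synthetic_block_spec <- function(m, n, n_founders = 3L, recomb_rate = 0.01,
                                 noise_rate = 0.01, seed = 1L,
                                 forbid_constant_columns = TRUE) {
  m <- as.integer(m); n <- as.integer(n); n_founders <- as.integer(n_founders)
  if (m < 2L || n < 1L) {
    abort_tagsnp("need m >= 2 and n >= 1", "tagsnp_validation_error")
  }
  if (n_founders < 1L || n_founders > m) {
    abort_tagsnp("n_founders must lie in [1, m]", "tagsnp_validation_error")
  }
  if (recomb_rate < 0 || recomb_rate > 1 || noise_rate < 0 || noise_rate > 1) {
    abort_tagsnp("recomb_rate and noise_rate must lie in [0, 1]", "tagsnp_validation_error")
  }
  structure(
    list(m = m, n = n, n_founders = n_founders, recomb_rate = recomb_rate,
         noise_rate = noise_rate, seed = as.integer(seed),
         forbid_constant_columns = isTRUE(forbid_constant_columns)),
    class = "synthetic_block_spec"
  )
}

# One pattern: a founder mosaic plus noise flips.
derive_pattern <- function(founders, recomb_rate, noise_rate, n) {
  k <- nrow(founders)
  if (k == 1L) {
    src <- rep(1L, n)
  } else {
    switches <- stats::runif(n) < recomb_rate
    src <- integer(n)
    cur <- sample.int(k, 1L)
    for (j in seq_len(n)) {
      if (switches[j]) cur <- sample.int(k, 1L)
      src[j] <- cur
    }
  }
  row <- founders[cbind(src, seq_len(n))]
  flips <- stats::runif(n) < noise_rate
  row[flips] <- 1L - row[flips]
  row
}

#' Generate a synthetic haplotype block
#'
#' Deterministic for a fixed spec (seed included). Rows duplicating an
#' earlier row are resampled with a bounded retry budget; if
#' `forbid_constant_columns` is set, constant columns are re-randomized
#' (keeping rows distinct) before the block is returned.
#'
#' @param spec A [synthetic_block_spec].
#' @return A validated [haplotype_block] with `spec$m` distinct rows.
#' @export
generate_block <- function(spec) {
  stopifnot(inherits(spec, "synthetic_block_spec"))
  if (spec$n < 63 && spec$m > 2^spec$n) {
    abort_tagsnp(
      sprintf("cannot place %d distinct patterns in {0,1}^%d", spec$m, spec$n),
      "tagsnp_generation_error"
    )
  }
  with_seed(spec$seed, {
    founders <- matrix(
      sample(0:1, spec$n_founders * spec$n, replace = TRUE),
      nrow = spec$n_founders
    )
    mat <- matrix(0L, spec$m, spec$n)
    seen <- character(0)
    retries_per_row <- 200L
    for (i in seq_len(spec$m)) {
      ok <- FALSE
      for (attempt in seq_len(retries_per_row)) {
        row <- derive_pattern(founders, spec$recomb_rate, spec$noise_rate, spec$n)
        key <- paste(row, collapse = "")
        if (!(key %in% seen)) {
          mat[i, ] <- row
          seen <- c(seen, key)
          ok <- TRUE
          break
        }
        # duplicates mean the mosaic alone cannot separate rows; force one
        # extra flip so the retry budget is not wasted on near-zero noise
        j <- sample.int(spec$n, 1L)
        row[j] <- 1L - row[j]
        key <- paste(row, collapse = "")
        if (!(key %in% seen)) {
          mat[i, ] <- row
          seen <- c(seen, key)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort_tagsnp(
          sprintf("could not generate %d distinct patterns within the retry budget", spec$m),
          "tagsnp_generation_error"
        )
      }
    }
    if (spec$forbid_constant_columns) {
      for (j in which(apply(mat, 2L, function(col) length(unique(col)) == 1L))) {
        for (attempt in seq_len(200L)) {
          cand <- mat[, j]
          flip <- sample.int(spec$m, max(1L, stats::rbinom(1L, spec$m - 1L, 0.5)))
          cand[flip] <- 1L - cand[flip]
          mat2 <- mat
          mat2[, j] <- cand
          if (!anyDuplicated(apply(mat2, 1L, paste, collapse = ""))) {
            mat <- mat2
            break
          }
        }
      }
    }
    haplotype_block(mat)
  })
}
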