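# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded operations do not perturb the
# global stream.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(expr)
}

# Draw k sub-seeds from the stream seeded by `seed`. Keeps every derived seed
# a valid 32-bit integer.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Index pairs (i, j), i < j, in lexicographic order, as a 2 x C(m,2) matrix.
pattern_pairs <- function(m) {
  utils::combn(m, 2L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_tagsnp <- function(msg, class) {
  stop(structure(
    class = c(class, "tagsnp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
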