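#' Construct a haplotype block
#'
#' A haplotype block is an `m x n` binary matrix: `m` distinct haplotype
#' patterns (allele classes) over `n` biallelic SNPs, with the two alleles at
#' each SNP coded 0/1. It is the universe over which tag SNP selection runs.
#'
#' @param matrix An `m x n` matrix whose entries are all 0 or 1.
#' @param snp_ids Optional character vector of `n` SNP labels
#'   (default `S1..Sn`).
#' @param pattern_ids Optional character vector of `m` pattern labels
#'   (default `P1..Pm`).
#'
#' @return An object of class `haplotype_block` with fields `matrix`, `m`,
#'   `n`, `snp_ids`, `pattern_ids`.
#'
#' @details Invariants enforced: every entry is 0 or 1; `m >= 2`, `n >= 1`;
#' all rows are pairwise distinct (each row is a distinct allele class —
#' duplicated patterns are a hard error, not merged). Patterns and SNPs are
#' indexed 1-based throughout the user-facing API.
#'
#' @examples
#' b <- haplotype_block(rbind(c(0, 0, 1), c(1, 1, 0)))
#' b$m
#' @export
haplotype_block <- function(matrix, snp_ids = NULL, pattern_ids = NULL) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  m <- nrow(matrix)
  n <- ncol(matrix)
  if (n < 1L || m < 2L) {
    abort_tagsnp(
      sprintf("a haplotype block needs m >= 2 patterns and n >= 1 SNPs (got %d x %d)", m, n),
      "tagsnp_validation_error"
    )
  }
  if (anyNA(matrix) || !all(matrix == 0L | matrix == 1L)) {
    abort_tagsnp("block entries must all be 0 or 1", "tagsnp_validation_error")
  }
  keys <- apply(matrix, 1L, paste, collapse = "")
  if (anyDuplicated(keys)) {
    d <- which(duplicated(keys))[1L]
    first <- match(keys[d], keys)
    abort_tagsnp(
      sprintf("duplicate haplotype patterns: rows %d and %d are identical", first, d),
      "tagsnp_validation_error"
    )
  }
  if (is.null(snp_ids)) snp_ids <- paste0("S", seq_len(n))
  if (is.null(pattern_ids)) pattern_ids <- paste0("P", seq_len(m))
  stopifnot(length(snp_ids) == n, length(pattern_ids) == m)
  structure(
    list(matrix = unname(matrix), m = m, n = n,
         snp_ids = as.character(snp_ids), pattern_ids = as.character(pattern_ids)),
    class = "haplotype_block"
  )
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf("<haplotype_block> %d patterns x %d SNPs\n", x$m, x$n))
  shown <- min(x$m, 10L)
  for (i in seq_len(shown)) {
    cat(sprintf("  %s %s\n", format(x$pattern_ids[i], width = 4L),
                paste(x$matrix[i, seq_len(min(x$n, 60L))], collapse = "")))
  }
  if (x$m > shown) cat(sprintf("  ... %d more patterns\n", x$m - shown))
  invisible(x)
}

#' Read a haplotype block from a plain-text matrix file
#'
#' The on-disk format is one haplotype pattern per line as a string over
#' `{0,1}` (no delimiters); blank lines are ignored and lines starting with
#' `#` are comments. A comment line of the form `# snp_ids: S1 S2 ...` is
#' recognized as SNP labels; `# pattern_ids: ...` likewise for patterns.
#'
#' @param source A file path or connection.
#' @param format Only `"matrix"` is supported.
#' @return A validated [haplotype_block].
#' @export
read_block <- function(source, format = "matrix") {
  format <- match.arg(format, "matrix")
  lines <- readLines(source, warn = FALSE)
  snp_ids <- pattern_ids <- NULL
  is_comment <- startsWith(trimws(lines), "#")
  for (cl in lines[is_comment]) {
    body <- sub("^\\s*#\\s*", "", cl)
    if (startsWith(body, "snp_ids:")) {
      snp_ids <- strsplit(trimws(sub("^snp_ids:", "", body)), "\\s+")[[1]]
    } else if (startsWith(body, "pattern_ids:")) {
      pattern_ids <- strsplit(trimws(sub("^pattern_ids:", "", body)), "\\s+")[[1]]
    }
  }
  data <- trimws(lines[!is_comment])
  data <- data[nzchar(data)]
  if (length(data) == 0L) {
    abort_tagsnp("no data lines found", "tagsnp_format_error")
  }
  if (any(grepl("[^01]", data))) {
    bad <- which(grepl("[^01]", data))[1L]
    abort_tagsnp(
      sprintf("line %d contains characters outside {0,1}", bad),
      "tagsnp_format_error"
    )
  }
  widths <- nchar(data)
  if (length(unique(widths)) != 1L) {
    abort_tagsnp(
      sprintf("ragged matrix: line lengths %s", paste(unique(widths), collapse = ", ")),
      "tagsnp_format_error"
    )
  }
  mat <- do.call(rbind, lapply(strsplit(data, ""), as.integer))
  haplotype_block(mat, snp_ids = snp_ids, pattern_ids = pattern_ids)
}

#' Write a haplotype block to the plain-text matrix format
#'
#' Emits the exact format accepted by [read_block()]: optional `#`-prefixed
#' label header lines, then one `{0,1}` string per pattern.
#' `read_block(write_block(b))` reproduces `b`'s matrix and labels.
#'
#' @param block A [haplotype_block].
#' @param sink A file path or connection.
#' @param ids Emit label header lines (default TRUE).
#' @export
write_block <- function(block, sink, ids = TRUE) {
  stopifnot(inherits(block, "haplotype_block"))
  lines <- character(0)
  if (isTRUE(ids)) {
    lines <- c(
      paste("# snp_ids:", paste(block$snp_ids, collapse = " ")),
      paste("# pattern_ids:", paste(block$pattern_ids, collapse = " "))
    )
  }
  lines <- c(lines, apply(block$matrix, 1L, paste, collapse = ""))
  writeLines(lines, sink)
  invisible(NULL)
}

#' Per-SNP distinguishability
#'
#' For each SNP, the number of unordered pattern pairs `(i, j)`, `i < j`,
#' whose alleles differ at that SNP — i.e. the number of allele-class pairs
#' the SNP alone can distinguish. Equals `z * (m - z)` where `z` is the count
#' of zeros in the column.
#'
#' @param block A [haplotype_block].
#' @return Integer vector of length `n`, each element in
#'   `[0, floor(m/2) * ceiling(m/2)]`.
#' @examples
#' b <- haplotype_block(rbind(c(0, 1), c(1, 1), c(0, 0)))
#' distinguishability(b) # column 1 splits 1 vs 2 patterns -> 2; column 2 -> 2
#' @export
distinguishability <- function(block) {
  stopifnot(inherits(block, "haplotype_block"))
  z <- colSums(block$matrix == 0L)
  as.integer(z * (block$m - z))
}
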