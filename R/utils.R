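#' @importFrom rlang .data
#' @importFrom stats optim pgamma rgamma rpois rnorm plogis sd cor median
#'   quantile t.test runif setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Extract a subsequence in 0-based half-open coordinates
#'
#' All interval arithmetic in this package uses 0-based half-open
#' coordinates, with position 0 the first base downstream of the stop codon.
#' This helper centralizes the conversion to R's 1-based `substr()`.
#'
#' @param seq A nucleotide string.
#' @param start,end Half-open interval `[start, end)`, 0-based.
#' @return The subsequence as a character scalar.
#' @export
subseq0 <- function(seq, start, end) {
  stopifnot(start >= 0, end >= start, end <= nchar(seq))
  substr(seq, start + 1L, end)
}

#' Replace a subsequence in 0-based coordinates
#' @param seq A nucleotide string.
#' @param start 0-based offset at which `replacement` is written.
#' @param replacement The replacement string; the region
#'   `[start, start + nchar(replacement))` is overwritten.
#' @return The modified sequence (same length as `seq`).
#' @export
replace_at0 <- function(seq, start, replacement) {
  w <- nchar(replacement)
  stopifnot(start >= 0, start + w <= nchar(seq))
  paste0(substr(seq, 1L, start), replacement, substr(seq, start + w + 1L, nchar(seq)))
}

#' Generate a random DNA sequence
#' @param n Length in bases.
#' @param prob Base probabilities for A, C, G, T (default uniform).
#' @return A nucleotide string of length `n`.
#' @export
random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

assert_dna <- function(seq, what = "sequence") {
  if (grepl("[^ACGT]", seq)) {
    stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  }
  invisible(seq)
}

#' Hamming distance between equal-length strings
#' @param a,b Strings of equal length.
#' @return Integer count of differing positions.
#' @export
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Count overlapping occurrences of a k-mer
#' @param seq A nucleotide string.
#' @param kmer The k-mer to count; occurrences may overlap.
#' @return Integer count.
#' @export
count_kmer <- function(seq, kmer) {
  k <- nchar(kmer)
  n <- nchar(seq)
  if (n < k) return(0L)
  starts <- 1:(n - k + 1)
  sum(substring(seq, starts, starts + k - 1L) == kmer)
}

#' A/T fraction of a sequence
#' @param seq A nucleotide string.
#' @return Fraction of positions that are A or T, in `[0, 1]`.
#' @export
at_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0) return(NA_real_)
  ch <- strsplit(seq, "")[[1]]
  mean(ch %in% c("A", "T"))
}

# Deterministic 32-bit string hash (polynomial rolling hash). Used to derive
# per-variant random draws that depend only on (seed, variant_id), not on the
# order variants are processed in.
string_hash <- function(x) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
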