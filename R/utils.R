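#' Reverse complement of a DNA string
#'
#' @param x single character string over A/C/G/T/N.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## split a string into a character vector of single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## longest common prefix length of two strings
lcp_len <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(0L)
  cx <- seq_chars(substr(x, 1L, n))
  cy <- seq_chars(substr(y, 1L, n))
  neq <- which(cx != cy)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic sub-seeds derived from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
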