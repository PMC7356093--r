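## Typing of differential long inserts: pairwise global alignment,
## p-distances, and single-linkage clustering on percent identity.

#' Global pairwise alignment
#'
#' End-gap penalised Needleman-Wunsch with match 1 / mismatch -1 / gap -2
#' and deterministic traceback (diagonal preferred over a gap in the second
#' sequence, over a gap in the first).
#'
#' @param seq_x,seq_y non-empty DNA strings.
#' @return list with `aligned_x`, `aligned_y` (equal-length strings with
#'   `-` gaps) and `score`.
#' @export
align_pair <- function(seq_x, seq_y) {
  stopifnot(nchar(seq_x) > 0L, nchar(seq_y) > 0L)
  nw <- .nw_align_cpp(seq_x, seq_y, 1L, -1L, -2L)
  list(aligned_x = nw$aligned_a, aligned_y = nw$aligned_b,
       score = nw$score)
}

#' p-distance between two aligned sequences
#'
#' Proportion of mismatched columns among compared columns; any column
#' containing a gap in either sequence is excluded from both numerator and
#' denominator.
#'
#' @param aligned_x,aligned_y equal-length aligned strings.
#' @return numeric in `[0, 1]`.
#' @export
p_distance <- function(aligned_x, aligned_y) {
  if (nchar(aligned_x) != nchar(aligned_y))
    stop("aligned sequences must have equal length")
  cx <- seq_chars(aligned_x)
  cy <- seq_chars(aligned_y)
  keep <- cx != "-" & cy != "-"
  n <- sum(keep)
  if (n == 0L) stop("p-distance undefined: no gap-free columns")
  sum(cx[keep] != cy[keep]) / n
}

#' Percent identity of two (unaligned) sequences
#'
#' `100 * (1 - p_distance)` after global alignment with [align_pair()].
#'
#' @param seq_x,seq_y DNA strings.
#' @return percent identity in `[0, 100]`.
#' @export
pair_identity <- function(seq_x, seq_y) {
  al <- align_pair(seq_x, seq_y)
  100 * (1 - p_distance(al$aligned_x, al$aligned_y))
}

## percent of matched columns over the full global alignment (gap columns
## count as differences). Unlike the gap-excluding p-distance this cannot
## call two unrelated sequences of unequal length similar, which is what
## family assignment needs; trees keep the canonical p-distance.
alignment_identity <- function(seq_x, seq_y) {
  al <- align_pair(seq_x, seq_y)
  cx <- seq_chars(al$aligned_x)
  cy <- seq_chars(al$aligned_y)
  100 * sum(cx == cy) / length(cx)
}

#' Pairwise identity matrix for a set of sequences
#'
#' Identities are percent matched columns over the full global alignment,
#' with gap columns counted as differences (see [cluster_inserts()] for
#' why typing does not use the gap-excluding p-distance).
#'
#' @param seqs named character vector of sequences.
#' @param both_strands when `TRUE`, each pair is scored in both relative
#'   orientations and the better identity kept; mobile-element copies
#'   insert on either strand, so typing uses this mode.
#' @return symmetric matrix of percent identities (diagonal 100).
#' @export
identity_matrix <- function(seqs, both_strands = FALSE) {
  n <- length(seqs)
  ids <- names(seqs) %||% paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    rc <- if (both_strands) vapply(seqs, revcomp, character(1)) else NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ident <- alignment_identity(seqs[[i]], seqs[[j]])
        if (both_strands)
          ident <- max(ident, alignment_identity(seqs[[i]], rc[[j]]))
        m[i, j] <- m[j, i] <- ident
      }
    }
  }
  m
}

#' Cluster long inserts into types by single-linkage identity
#'
#' Two inserts share a type iff they are connected by pairs of sequences
#' with percent identity at or above `identity_threshold` (single linkage).
#' Types are numbered by decreasing member count, ties broken by first
#' occurrence in the input. The realised minimum within-type identity is
#' reported per type so a permissive linkage threshold can still verify a
#' much tighter observed identity.
#'
#' Identity here is percent matched columns over the whole global
#' alignment, counting gap columns as differences. The gap-excluding
#' p-distance, appropriate inside an alignment of homologous sequences,
#' rates two unrelated sequences of very different length as spuriously
#' similar (the aligner concentrates the length difference into excluded
#' gap columns), which under single linkage can chain separate families
#' together; the gap-inclusive measure cannot.
#'
#' @param inserts named character vector of insert sequences (>= 1).
#' @param identity_threshold linkage threshold in percent (default 90).
#' @param both_strands score pairs in both relative orientations (default
#'   `TRUE`; element copies insert on either strand).
#' @return data.frame with columns `insert_id`, `type_id`,
#'   `within_type_min_identity`; the pairwise identity matrix is attached as
#'   attribute `"identity"`.
#' @export
cluster_inserts <- function(inserts, identity_threshold = 90,
                            both_strands = TRUE) {
  stopifnot(length(inserts) >= 1L)
  ids <- names(inserts) %||% paste0("insert", seq_along(inserts))
  names(inserts) <- ids
  n <- length(inserts)
  m <- identity_matrix(inserts, both_strands = both_strands)
  # union-find on edges >= threshold
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (m[i, j] >= identity_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  # number types by decreasing size, then first occurrence
  sizes <- table(comp)
  first <- vapply(as.integer(names(sizes)), function(r) min(which(comp == r)),
                  integer(1))
  ord <- order(-as.integer(sizes), first)
  type_of <- setNames(seq_along(ord), names(sizes)[ord])
  type_id <- as.integer(type_of[as.character(comp)])
  min_ident <- vapply(seq_len(n), function(i) {
    members <- which(type_id == type_id[i])
    if (length(members) == 1L) 100 else min(m[members, members])
  }, numeric(1))
  out <- data.frame(insert_id = ids, type_id = type_id,
                    within_type_min_identity = min_ident,
                    stringsAsFactors = FALSE)
  attr(out, "identity") <- m
  out
}
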