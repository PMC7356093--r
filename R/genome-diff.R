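## Whole-genome comparison of two near-identical assemblies:
## unique-k-mer anchoring, collinear chaining (LIS), and per-gap
## classification of discrepancies into substitutions, one-letter indels
## and long inserts.

#' Find unique shared k-mer anchors between two genomes
#'
#' An anchor is a k-mer that occurs exactly once in each genome; repeated
#' sequence (notably dispersed transposon copies) can therefore never
#' anchor, which is what makes the chain robust on genomes that share
#' mobile-element families. k-mers containing N never anchor.
#'
#' @param genome_a,genome_b [genome_seq] objects or bare sequences.
#' @param k anchor length in bp (>= 15; default 21).
#' @return data.frame with 0-based columns `pos_a`, `pos_b` and `k`,
#'   sorted by `pos_a`.
#' @export
index_anchors <- function(genome_a, genome_b, k = 21L) {
  a <- as_genome_seq(genome_a, "a")$sequence
  b <- as_genome_seq(genome_b, "b")$sequence
  k <- as.integer(k)
  if (k < 15L) stop("k must be >= 15")
  if (k > nchar(a) || k > nchar(b)) stop("k larger than a genome")
  kmers <- function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }
  ka <- kmers(a)
  kb <- kmers(b)
  uniq <- function(x) !(duplicated(x) | duplicated(x, fromLast = TRUE))
  ok_a <- uniq(ka) & !grepl("N", ka, fixed = TRUE)
  ok_b <- uniq(kb) & !grepl("N", kb, fixed = TRUE)
  m <- match(ka, kb)
  keep <- ok_a & !is.na(m) & ok_b[ifelse(is.na(m), 1L, m)]
  pos <- which(keep)
  data.frame(pos_a = pos - 1L, pos_b = m[keep] - 1L,
             k = rep(k, length(pos)))
}

#' Select a collinear anchor chain (longest increasing subsequence)
#'
#' Keeps a maximum-cardinality subset of anchors strictly increasing in both
#' coordinates (patience-sorting LIS on `pos_b`), then trims overlapping
#' neighbours so consecutive anchors never overlap in either genome. The
#' LIS is deterministic: at every chain length the smallest feasible ending
#' `pos_b` is kept.
#'
#' @param anchors data.frame from [index_anchors()], sorted by `pos_a`.
#' @return data.frame of chained anchors (`pos_a`, `pos_b`, `k`), where `k`
#'   may have been reduced by overlap trimming.
#' @export
chain_anchors <- function(anchors) {
  n <- nrow(anchors)
  if (n == 0L) return(anchors)
  if (is.unsorted(anchors$pos_a, strictly = TRUE))
    stop("anchors must be strictly sorted by pos_a")
  sel <- .lis_cpp(as.integer(anchors$pos_b))
  out <- anchors[sel, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 1L) {
    # trim each anchor's start so it clears its predecessor in both genomes;
    # ends are untouched, so a single forward pass suffices
    end_a <- out$pos_a + out$k
    end_b <- out$pos_b + out$k
    da <- c(0L, pmax(0L, end_a[-nrow(out)] - out$pos_a[-1L]))
    db <- c(0L, pmax(0L, end_b[-nrow(out)] - out$pos_b[-1L]))
    d <- pmax(da, db)
    out$pos_a <- out$pos_a + d
    out$pos_b <- out$pos_b + d
    out$k <- out$k - d
    out <- out[out$k > 0L, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

## classify the discrepancy between two inter-anchor segments.
## Returns list(frags = data.frame, cols, matches) where frags uses
## segment-relative coordinates: substitutions carry 1-based rel_a/rel_b;
## an inserted run carries rel_* = 1-based start in the carrier segment and
## the number of consumed bases (0-based "after" offset) on the other side.
align_gap <- function(seg_a, seg_b, substitution_ceiling = 5L,
                      min_long_insert = 2L) {
  la <- nchar(seg_a)
  lb <- nchar(seg_b)
  frag <- function(kind, carrier, rel_a, rel_b, ref, alt, length) {
    data.frame(kind = kind, carrier = carrier, rel_a = rel_a, rel_b = rel_b,
               ref = ref, alt = alt, length = length,
               stringsAsFactors = FALSE)
  }
  empty <- frag(character(), character(), integer(), integer(),
                character(), character(), integer())[0, ]
  if (la == 0L && lb == 0L)
    return(list(frags = empty, cols = 0L, matches = 0L))
  if (la == 0L) {
    kind <- if (lb >= min_long_insert) "long_insert" else "indel_1bp"
    return(list(frags = frag(kind, "b", 0L, 1L, "", seg_b, lb),
                cols = lb, matches = 0L))
  }
  if (lb == 0L) {
    kind <- if (la >= min_long_insert) "long_insert" else "indel_1bp"
    return(list(frags = frag(kind, "a", 1L, 0L, seg_a, "", la),
                cols = la, matches = 0L))
  }
  if (la == lb) {
    ca <- seq_chars(seg_a)
    cb <- seq_chars(seg_b)
    mism <- which(ca != cb)
    if (length(mism) <= substitution_ceiling) {
      frs <- if (length(mism)) {
        frag("substitution", "", mism, mism, ca[mism], cb[mism], 1L)
      } else empty
      return(list(frags = frs, cols = la, matches = la - length(mism)))
    }
  }
  nw <- .nw_align_cpp(seg_a, seg_b, 1L, -1L, -2L)
  ca <- seq_chars(nw$aligned_a)
  cb <- seq_chars(nw$aligned_b)
  type <- ifelse(ca == "-", "I", ifelse(cb == "-", "D",
                 ifelse(ca == cb, "M", "X")))
  r <- rle(type)
  frs <- list()
  ia <- 0L
  ib <- 0L
  pos <- 0L
  for (q in seq_along(r$lengths)) {
    L <- r$lengths[q]
    t <- r$values[q]
    idx <- pos + seq_len(L)
    if (t == "M") {
      ia <- ia + L; ib <- ib + L
    } else if (t == "X") {
      frs[[length(frs) + 1L]] <-
        frag("substitution", "", ia + seq_len(L), ib + seq_len(L),
             ca[idx], cb[idx], 1L)
      ia <- ia + L; ib <- ib + L
    } else if (t == "I") {          # gap in a: run inserted in b
      kind <- if (L >= min_long_insert) "long_insert" else "indel_1bp"
      frs[[length(frs) + 1L]] <-
        frag(kind, "b", ia, ib + 1L, "", paste(cb[idx], collapse = ""), L)
      ib <- ib + L
    } else {                        # gap in b: run carried by a
      kind <- if (L >= min_long_insert) "long_insert" else "indel_1bp"
      frs[[length(frs) + 1L]] <-
        frag(kind, "a", ia + 1L, ib, paste(ca[idx], collapse = ""), "", L)
      ia <- ia + L
    }
    pos <- pos + L
  }
  frags <- if (length(frs)) do.call(rbind, frs) else empty
  list(frags = frags, cols = length(type), matches = sum(type == "M"))
}

## left-normalise an inserted run: while the base immediately before the
## insertion equals the run's last base, shift the run one position left.
## `pos` is the 1-based start of the run in the carrier sequence. Returns
## list(pos, seq, shift).
normalize_insertion <- function(carrier_seq, pos, seq) {
  L <- nchar(seq)
  shift <- 0L
  while (pos > 1L &&
         substr(carrier_seq, pos - 1L, pos - 1L) == substr(seq, L, L)) {
    seq <- paste0(substr(carrier_seq, pos - 1L, pos - 1L),
                  substr(seq, 1L, L - 1L))
    pos <- pos - 1L
    shift <- shift + 1L
  }
  list(pos = pos, seq = seq, shift = shift)
}

#' Diff two near-identical genomes
#'
#' Runs the full anchor-index / chain / per-gap alignment pipeline and
#' returns every discrepancy as a substitution, one-letter indel or long
#' insert (inserted run of length >= `min_long_insert`, default 2 bp).
#' Inserted runs are left-normalised so their coordinates are canonical even
#' inside repeated target sequence. For insertions, `carrier` names the
#' genome bearing the extra sequence; `ref` is always the allele in genome A
#' and `alt` the allele in genome B. `pos_a`/`pos_b` are 1-based: for an
#' insertion they are the start of the inserted run in the carrier and the
#' base after which it sits in the other genome.
#'
#' @param genome_a,genome_b [genome_seq] objects or bare sequences.
#' @param k anchor length (default 21).
#' @param substitution_ceiling maximum Hamming distance for which an
#'   equal-length gap is reported as plain substitutions without running the
#'   full alignment (default 5).
#' @param min_long_insert inserted runs at least this long are
#'   `long_insert`, shorter ones `indel_1bp` (default 2).
#' @param min_chain_coverage hard floor on the fraction of either genome
#'   covered by chained anchors; below it the genomes are declared not
#'   near-identical (default 0.5).
#' @param circular when both genomes are circular, rotate genome B so the
#'   first chained anchor starts both genomes; the rotation is reported.
#' @return object of class `diff_report`: list with `variants` (sorted by
#'   `pos_a`), `aligned_identity` (percent), `chain_coverage` (named
#'   fraction per genome), `n_anchors`, `rotation_b` and `params`.
#' @export
diff_genomes <- function(genome_a, genome_b, k = 21L,
                         substitution_ceiling = 5L, min_long_insert = 2L,
                         min_chain_coverage = 0.5, circular = FALSE) {
  ga <- as_genome_seq(genome_a, "a")
  gb <- as_genome_seq(genome_b, "b")
  a <- ga$sequence
  b <- gb$sequence
  rotation_b <- 0L
  if (circular || (ga$topology == "circular" && gb$topology == "circular")) {
    ch0 <- chain_anchors(index_anchors(a, b, k))
    if (nrow(ch0) > 0L) {
      rotation_b <- ch0$pos_b[1L] - ch0$pos_a[1L]
      if (rotation_b < 0L) rotation_b <- rotation_b + nchar(b)
      if (rotation_b > 0L) {
        b <- paste0(substr(b, rotation_b + 1L, nchar(b)),
                    substr(b, 1L, rotation_b))
      }
    }
  }
  chain <- chain_anchors(index_anchors(a, b, k))
  n_anchors <- nrow(chain)
  # merge abutting same-diagonal anchors into maximal collinear blocks so
  # the gap loop scales with the number of discrepancies, not anchors
  if (nrow(chain) > 1L) {
    diag_ <- chain$pos_b - chain$pos_a
    abut <- c(FALSE, diag_[-1L] == diag_[-nrow(chain)] &
                chain$pos_a[-1L] == chain$pos_a[-nrow(chain)] +
                  chain$k[-nrow(chain)])
    grp <- cumsum(!abut)
    ends <- chain$pos_a + chain$k
    first_a <- as.integer(tapply(chain$pos_a, grp, `[`, 1L))
    chain <- data.frame(
      pos_a = first_a,
      pos_b = as.integer(tapply(chain$pos_b, grp, `[`, 1L)),
      k = as.integer(tapply(ends, grp, max)) - first_a)
  }
  cov <- c(a = sum(chain$k) / nchar(a), b = sum(chain$k) / nchar(b))
  if (nrow(chain) == 0L || min(cov) < min_chain_coverage) {
    stop(sprintf(
      "genomes not near-identical: anchor chain covers %.1f%% of '%s', %.1f%% of '%s'",
      100 * cov[["a"]], ga$id, 100 * cov[["b"]], gb$id))
  }
  bounds_a <- c(chain$pos_a, nchar(a))
  bounds_b <- c(chain$pos_b, nchar(b))
  prev_a <- 0L
  prev_b <- 0L
  cols <- sum(chain$k)
  matches <- sum(chain$k)
  vars <- list()
  for (i in seq_along(bounds_a)) {
    seg_a <- substr(a, prev_a + 1L, bounds_a[i])
    seg_b <- substr(b, prev_b + 1L, bounds_b[i])
    g <- align_gap(seg_a, seg_b, substitution_ceiling, min_long_insert)
    cols <- cols + g$cols
    matches <- matches + g$matches
    if (nrow(g$frags) > 0L) {
      f <- g$frags
      f$pos_a <- prev_a + f$rel_a
      f$pos_b <- prev_b + f$rel_b
      vars[[length(vars) + 1L]] <- f
    }
    if (i <= nrow(chain)) {
      prev_a <- chain$pos_a[i] + chain$k[i]
      prev_b <- chain$pos_b[i] + chain$k[i]
    }
  }
  variants <- if (length(vars)) do.call(rbind, vars) else
    data.frame(kind = character(), carrier = character(),
               rel_a = integer(), rel_b = integer(),
               ref = character(), alt = character(), length = integer(),
               pos_a = integer(), pos_b = integer(),
               stringsAsFactors = FALSE)
  variants$rel_a <- NULL
  variants$rel_b <- NULL
  # map carrier tags to genome ids and left-normalise inserted runs
  if (nrow(variants) > 0L) {
    for (i in seq_len(nrow(variants))) {
      if (variants$kind[i] == "substitution") next
      if (variants$carrier[i] == "a") {
        nm <- normalize_insertion(a, variants$pos_a[i], variants$ref[i])
        variants$pos_a[i] <- nm$pos
        variants$pos_b[i] <- variants$pos_b[i] - nm$shift
        variants$ref[i] <- nm$seq
      } else {
        nm <- normalize_insertion(b, variants$pos_b[i], variants$alt[i])
        variants$pos_b[i] <- nm$pos
        variants$pos_a[i] <- variants$pos_a[i] - nm$shift
        variants$alt[i] <- nm$seq
      }
    }
    variants$carrier <- ifelse(variants$kind == "substitution", "",
                               ifelse(variants$carrier == "a",
                                      ga$id, gb$id))
    variants <- variants[order(variants$pos_a, variants$pos_b), ,
                         drop = FALSE]
    rownames(variants) <- NULL
  }
  structure(list(
    variants = variants,
    aligned_identity = 100 * matches / cols,
    chain_coverage = cov,
    n_anchors = n_anchors,
    rotation_b = rotation_b,
    genome_ids = c(a = ga$id, b = gb$id),
    params = list(k = k, substitution_ceiling = substitution_ceiling,
                  min_long_insert = min_long_insert)
  ), class = "diff_report")
}

#' @export
print.diff_report <- function(x, ...) {
  cat(sprintf("<diff_report> %s vs %s\n", x$genome_ids[["a"]],
              x$genome_ids[["b"]]))
  cat(sprintf("  aligned identity: %.4f%%  anchors: %d  coverage: %.3f/%.3f\n",
              x$aligned_identity, x$n_anchors,
              x$chain_coverage[["a"]], x$chain_coverage[["b"]]))
  if (nrow(x$variants)) print(table(x$variants$kind)) else
    cat("  no variants\n")
  invisible(x)
}

#' Apply a diff's variants to genome A, reconstructing genome B
#'
#' The round-trip `apply_variants(a, diff_genomes(a, b)$variants)` must
#' reproduce `b` exactly; this is the package's core self-consistency check.
#'
#' @param genome_a [genome_seq] or bare sequence (the "A" side of the diff).
#' @param variants the `variants` data.frame of a `diff_report`.
#' @param genome_b_id id of the B genome (used to recognise which insertions
#'   belong to B); defaults to the single non-A carrier present.
#' @return the reconstructed B sequence as a character string.
#' @export
apply_variants <- function(genome_a, variants, genome_b_id = NULL) {
  ga <- as_genome_seq(genome_a, "a")
  a <- ga$sequence
  if (nrow(variants) == 0L) return(a)
  if (is.null(genome_b_id)) {
    carriers <- setdiff(unique(variants$carrier), c("", ga$id))
    if (length(carriers) > 1L)
      stop("ambiguous carrier ids; supply genome_b_id")
    genome_b_id <- if (length(carriers)) carriers else "b"
  }
  v <- variants[order(variants$pos_a, variants$pos_b), , drop = FALSE]
  pieces <- character()
  cursor <- 1L
  for (i in seq_len(nrow(v))) {
    if (v$kind[i] == "substitution") {
      pieces <- c(pieces, substr(a, cursor, v$pos_a[i] - 1L), v$alt[i])
      cursor <- v$pos_a[i] + 1L
    } else if (v$carrier[i] == genome_b_id) {
      # extra sequence in B, inserted after pos_a
      pieces <- c(pieces, substr(a, cursor, v$pos_a[i]), v$alt[i])
      cursor <- v$pos_a[i] + 1L
    } else {
      # extra sequence in A: skip it
      pieces <- c(pieces, substr(a, cursor, v$pos_a[i] - 1L))
      cursor <- v$pos_a[i] + v$length[i]
    }
  }
  pieces <- c(pieces, substr(a, cursor, nchar(a)))
  paste(pieces, collapse = "")
}
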