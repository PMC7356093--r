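## Transposon identification by terminal inverted repeats (TIR), target-site
## duplication (TSD) detection, genome-wide copy census by exact TIR match,
## full-length/truncated classification, and excision-scar search.

## longest t such that left ends with t and right starts with t
## (non-monotone in t, so scan downward from the cap)
longest_suffix_prefix <- function(left, right, cap = Inf) {
  n <- min(nchar(left), nchar(right), cap)
  cl <- seq_chars(left)
  cr <- seq_chars(right)
  nl <- length(cl)
  for (t in rev(seq_len(n))) {
    if (all(cl[(nl - t + 1L):nl] == cr[seq_len(t)])) return(t)
  }
  0L
}

#' Detect terminal repeats of a candidate element
#'
#' The terminal inverted repeat (TIR) is the longest exact prefix of the
#' element equal to the reverse complement of its suffix; it is the
#' diagnostic transposon signature used by the census. Because insert calls
#' are left-normalised, the target-site duplication (TSD, the flanking
#' direct repeat) travels inside the inserted run and the run itself may be
#' rotated relative to the element when the insertion context is repetitive;
#' any rotation of the run is an equivalent placement of the same insertion.
#' The detector therefore scans left-rotations of the run combined with a
#' trailing TSD strip and keeps the `(rotation, strip)` pair maximising the
#' TIR (ties: least rotated, longest TSD). A plain un-rotated element with a
#' TSD visible as suffix-of-left-flank / prefix-of-right-flank is the
#' `(0, 0)` case of the same search, with the flank-based TSD reported. An
#' element-terminal direct repeat (prefix of the element equal to its
#' suffix) is reported separately as `term_dr`.
#'
#' @param insert_seq inserted sequence as called by the diff.
#' @param left_flank,right_flank carrier-genome sequence immediately before
#'   and after the inserted run (>= 25 bp recommended).
#' @param min_tir_len minimum TIR length to call a repeat (default 10).
#' @param min_dr_len minimum TSD length to report one (default 3).
#' @param max_rotation,max_dr search caps in bp.
#' @return `NULL` when no TIR of at least `min_tir_len` is found, else a
#'   list with `tir_seq`, `tir_len`, `dr_seq`, `dr_len`, `term_dr_seq`,
#'   `term_dr_len`, and `element_seq` (the recovered element).
#' @export
find_terminal_repeats <- function(insert_seq, left_flank, right_flank,
                                  min_tir_len = 10L, min_dr_len = 3L,
                                  max_rotation = 40L, max_dr = 25L) {
  L <- nchar(insert_seq)
  if (L < 2L * min_tir_len) return(NULL)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  cv <- seq_chars(insert_seq)
  tir_of_chars <- function(x) {
    # longest prefix equal to revcomp of suffix, capped at half length;
    # N is ambiguity and never counts as an exact match
    y <- rev(unname(comp[x]))
    n2 <- length(x) %/% 2L
    xs <- x[seq_len(n2)]
    neq <- which(xs != y[seq_len(n2)] | xs == "N")
    if (length(neq)) neq[1L] - 1L else n2
  }
  best <- list(tir = -1L, score = -1L, j = 0L, d = 0L)
  # a left-rotation by j is an equivalent placement of the same insertion
  # only while the run's prefix matches the sequence that follows it
  j_max <- min(max_rotation, lcp_len(insert_seq, right_flank),
               L - 2L * min_tir_len)
  lf <- seq_chars(left_flank)
  for (j in 0L:j_max) {
    rot <- if (j == 0L) cv else c(cv[(j + 1L):L], cv[seq_len(j)])
    for (d in 0L:min(max_dr, L - 2L * min_tir_len, L - 1L)) {
      el <- if (d == 0L) rot else rot[seq_len(L - d)]
      t <- tir_of_chars(el)
      # a stripped TSD is only evidence when the same word immediately
      # precedes the element at this placement; a validated TSD then
      # counts towards the candidate's score, which resolves rotation
      # ambiguity inside self-complementary targets
      dr_ok <- FALSE
      if (d > 0L) {
        tsd <- rot[(L - d + 1L):L]
        prec <- if (j >= d) cv[(j - d + 1L):j] else {
          need <- d - j
          if (length(lf) >= need) {
            c(lf[(length(lf) - need + 1L):length(lf)],
              if (j > 0L) cv[seq_len(j)])
          } else NULL
        }
        dr_ok <- !is.null(prec) && all(prec == tsd)
      }
      score <- t + if (dr_ok) d else 0L
      if (score > best$score) {
        best <- list(tir = t, score = score, j = j, d = d, el = el,
                     dr = if (dr_ok) paste(rot[(L - d + 1L):L],
                                           collapse = "") else "")
      }
    }
  }
  if (best$tir < min_tir_len) return(NULL)
  el <- paste(best$el, collapse = "")
  tl <- best$tir
  dr_len <- if (nzchar(best$dr)) best$d else 0L
  dr_seq <- best$dr
  if (dr_len == 0L) {
    # TSD may still be visible in the flanks (un-normalised coordinates)
    dr1 <- longest_suffix_prefix(left_flank, right_flank, cap = max_dr)
    if (dr1 >= min_dr_len) {
      dr_len <- dr1
      dr_seq <- substr(left_flank, nchar(left_flank) - dr1 + 1L,
                       nchar(left_flank))
    }
  }
  if (dr_len < min_dr_len) {
    dr_len <- 0L
    dr_seq <- ""
  }
  # element-terminal direct repeat, reported separately
  n2 <- nchar(el) %/% 2L
  ce <- seq_chars(el)
  tdr <- 0L
  for (t in rev(seq_len(n2))) {
    if (all(ce[seq_len(t)] == ce[(length(ce) - t + 1L):length(ce)])) {
      tdr <- t
      break
    }
  }
  list(tir_seq = substr(el, 1L, tl), tir_len = tl,
       dr_seq = dr_seq, dr_len = dr_len,
       term_dr_seq = if (tdr >= min_dr_len) substr(el, 1L, tdr) else "",
       term_dr_len = if (tdr >= min_dr_len) tdr else 0L,
       element_seq = el)
}

#' Build element types from typed inserts
#'
#' Runs [find_terminal_repeats()] on every member of each insert type with
#' its genomic flanks, then fixes the type's TIR by cross-member support:
#' among the member-level TIR candidates, the one found (as exact prefix
#' pattern and reverse-complement suffix pattern) in the largest number of
#' members wins, ties broken by length then lexicographically. A single
#' member's insertion context can extend its own terminal palindrome by a
#' base or two by chance; requiring support across independent insertion
#' sites removes that noise. The consensus is the element recovered from
#' the longest member carrying the winning TIR, and the type is a
#' transposon iff a TIR of at least `min_tir_len` is supported.
#'
#' @param inserts named character vector of insert sequences.
#' @param typing data.frame from [cluster_inserts()].
#' @param flanks data.frame with columns `insert_id`, `left`, `right`
#'   holding carrier-genome flanking sequence for each insert.
#' @param min_tir_len,min_dr_len see [find_terminal_repeats()].
#' @return list of element types, each a list with `type_id`, `consensus`,
#'   `repeat_pair` (or `NULL`), `is_transposon`, `members`.
#' @export
build_element_types <- function(inserts, typing, flanks,
                                min_tir_len = 10L, min_dr_len = 3L) {
  lapply(sort(unique(typing$type_id)), function(tid) {
    members <- typing$insert_id[typing$type_id == tid]
    rps <- lapply(members, function(id) {
      fl <- flanks[flanks$insert_id == id, , drop = FALSE]
      find_terminal_repeats(inserts[[id]], fl$left[1L], fl$right[1L],
                            min_tir_len, min_dr_len)
    })
    names(rps) <- members
    cand <- unique(unlist(lapply(rps, function(r) {
      if (is.null(r)) NULL else r$tir_seq
    })))
    if (length(cand) == 0L) {
      rep_i <- members[order(-nchar(inserts[members]),
                             inserts[members])][1L]
      return(list(type_id = tid, consensus = inserts[[rep_i]],
                  repeat_pair = NULL, is_transposon = FALSE,
                  members = members))
    }
    # a member's run may be rotated relative to the element, and every
    # rotation of a string is a substring of the string doubled
    doubled <- vapply(members, function(id)
      paste0(inserts[[id]], inserts[[id]]), character(1))
    support <- vapply(cand, function(tt) {
      sum(vapply(doubled, function(dd) {
        grepl(tt, dd, fixed = TRUE) &&
          grepl(revcomp(tt), dd, fixed = TRUE)
      }, logical(1)))
    }, numeric(1))
    best_tir <- cand[order(-support, -nchar(cand), cand)][1L]
    carriers <- members[vapply(members, function(id) {
      !is.null(rps[[id]]) && rps[[id]]$tir_seq == best_tir
    }, logical(1))]
    if (length(carriers) == 0L)
      carriers <- members[!vapply(rps, is.null, logical(1))]
    rep_i <- carriers[order(-nchar(inserts[carriers]),
                            inserts[carriers])][1L]
    rp <- rps[[rep_i]]
    list(type_id = tid, consensus = rp$element_seq, repeat_pair = rp,
         is_transposon = TRUE, members = members)
  })
}

#' Census of element copies by exact TIR match
#'
#' Finds every exact occurrence of the type's TIR and of its reverse
#' complement on the forward strand of the genome, pairs each left
#' occurrence with the nearest downstream right occurrence whose span lies
#' inside the length window, and accepts candidates greedily shortest-span
#' first so copies never overlap (nested or adjacent occurrences cannot
#' create chimeric calls). Because an element and its reverse complement
#' present the same terminal pattern, orientation is assigned afterwards by
#' comparing the copy's core to the consensus in both orientations.
#'
#' @param genome [genome_seq] or bare sequence.
#' @param etype element type from [build_element_types()] (must be a
#'   transposon).
#' @param length_window numeric length-2 vector `[min_bp, max_bp]`; the
#'   default `NULL` scans with `[0.3 x consensus length, Inf)` and then
#'   keeps copies within `[0.3, 1.05] x` the longest copy found, so
#'   full-length elements longer than the (possibly truncated) differential
#'   inserts are still recovered.
#' @param exclude optional data.frame of 1-based `start`/`end` intervals
#'   (differential insert loci); overlapping copies are flagged
#'   `differential = TRUE` rather than removed.
#' @return data.frame of copies: `genome_id`, `start`, `end` (1-based
#'   inclusive), `type_id`, `strand`, `length`, `full_length` (NA until
#'   [classify_copies()]), `differential`.
#' @export
scan_copies <- function(genome, etype, length_window = NULL,
                        exclude = NULL) {
  g <- as_genome_seq(genome)
  if (!isTRUE(etype$is_transposon)) stop("element type is not a transposon")
  tir <- etype$repeat_pair$tir_seq
  if (is.null(tir) || nchar(tir) == 0L) stop("empty TIR")
  auto_window <- is.null(length_window)
  Lc <- nchar(etype$consensus)
  if (auto_window) length_window <- c(floor(0.3 * Lc), Inf)
  subj <- Biostrings::DNAString(g$sequence)
  starts <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::DNAString(tir), subj))
  ends <- Biostrings::end(
    Biostrings::matchPattern(Biostrings::DNAString(revcomp(tir)), subj))
  min_span <- max(length_window[1L], 2L * nchar(tir))
  cand <- list()
  ends_sorted <- sort(ends)
  for (s in starts) {
    # nearest downstream right occurrence with span inside the window
    i <- findInterval(s + min_span - 1L - 1L, ends_sorted) + 1L
    if (i <= length(ends_sorted)) {
      e <- ends_sorted[i]
      span <- e - s + 1L
      if (span >= min_span && span <= length_window[2L]) {
        cand[[length(cand) + 1L]] <- c(start = s, end = e, span = span)
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(genome_id = character(), start = integer(),
                      end = integer(), type_id = integer(),
                      strand = character(), length = integer(),
                      full_length = logical(), differential = logical(),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, "span"], cand[, "start"]), , drop = FALSE]
  taken_start <- integer()
  taken_end <- integer()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand[i, "start"]; e <- cand[i, "end"]
    if (!any(s <= taken_end & e >= taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (auto_window) {
    full <- max(cand[, "span"])
    ok <- cand[, "span"] >= 0.3 * full & cand[, "span"] <= 1.05 * full
    cand <- cand[ok, , drop = FALSE]
  }
  # orientation: compare the first stretch of core to the consensus core in
  # both orientations (an element and its reverse complement share TIR ends)
  tl <- nchar(tir)
  cons <- etype$consensus
  rc_cons <- revcomp(cons)
  strand <- vapply(seq_len(nrow(cand)), function(i) {
    s <- cand[i, "start"]; e <- cand[i, "end"]
    w <- min(100L, cand[i, "span"] - 2L * tl, nchar(cons) - 2L * tl)
    if (w < 1L) return("+")
    probe <- substr(g$sequence, s + tl, s + tl + w - 1L)
    d_fwd <- .hamming_cpp(probe, substr(cons, tl + 1L, tl + w))
    d_rev <- .hamming_cpp(probe, substr(rc_cons, tl + 1L, tl + w))
    if (d_rev < d_fwd) "-" else "+"
  }, character(1))
  out <- data.frame(genome_id = g$id, start = unname(cand[, "start"]),
                    end = unname(cand[, "end"]), type_id = etype$type_id,
                    strand = strand,
                    length = unname(cand[, "span"]),
                    full_length = NA, differential = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    out$differential <- vapply(seq_len(nrow(out)), function(i) {
      any(out$start[i] <= exclude$end & out$end[i] >= exclude$start)
    }, logical(1))
  }
  out[order(out$start), , drop = FALSE]
}

#' Classify copies as full-length or truncated
#'
#' A copy is full-length iff its length is within `full_length_tolerance`
#' bp of the longest observed copy of its type; a single copy is
#' full-length by definition.
#'
#' @param copies data.frame from [scan_copies()] (one or more types).
#' @param full_length_tolerance bp tolerance (default 10).
#' @return `copies` with the `full_length` column filled.
#' @export
classify_copies <- function(copies, full_length_tolerance = 10L) {
  if (nrow(copies) == 0L) return(copies)
  for (tid in unique(copies$type_id)) {
    sel <- copies$type_id == tid
    longest <- max(copies$length[sel])
    copies$full_length[sel] <-
      abs(copies$length[sel] - longest) <= full_length_tolerance
  }
  copies
}

#' Search differential insert loci for excision scars
#'
#' A transposon that has excised leaves its target-site duplication behind
#' as a tandem repeat; a site that never received an element shows a single
#' copy of the target. For every differential long insert that is not an
#' element copy, the inserted run is tested for being an exact tandem
#' duplication of its own flank (the inserted sequence equals the adjacent
#' carrier sequence of the same length); such sites are reported as scars,
#' all others are pre-insertion sites.
#'
#' @param diff `diff_report` from [diff_genomes()].
#' @param genomes named list of the two [genome_seq] objects keyed by id.
#' @param element_types list from [build_element_types()]; inserts whose
#'   ends carry a known type's TIR are treated as elements, not scars.
#' @param dr_len minimum (and typical) target-site length; inserted runs
#'   shorter than this are never scars (default 3).
#' @param max_dr_len longest target considered (default 25).
#' @return data.frame of scars: `genome_id`, `position` (1-based start of
#'   the duplicated target in the carrier), `dr_seq`, `evidence`.
#' @export
detect_excision_scars <- function(diff, genomes, element_types = list(),
                                  dr_len = 3L, max_dr_len = 25L) {
  v <- diff$variants
  v <- v[v$kind == "long_insert", , drop = FALSE]
  out <- data.frame(genome_id = character(), position = integer(),
                    dr_seq = character(), evidence = character(),
                    stringsAsFactors = FALSE)
  if (nrow(v) == 0L) return(out)
  tirs <- vapply(element_types, function(et) {
    if (isTRUE(et$is_transposon)) et$repeat_pair$tir_seq else ""
  }, character(1))
  tirs <- tirs[nzchar(tirs)]
  for (i in seq_len(nrow(v))) {
    carrier <- v$carrier[i]
    gseq <- genomes[[carrier]]$sequence
    s <- if (v$alt[i] == "") v$ref[i] else v$alt[i]
    pos <- if (v$alt[i] == "") v$pos_a[i] else v$pos_b[i]
    L <- v$length[i]
    if (L < dr_len || L > max_dr_len) next
    # skip inserted runs that carry a known element's TIR
    is_elem <- any(vapply(tirs, function(tt) {
      nchar(s) >= 2L * nchar(tt) &&
        (startsWith(s, tt) || endsWith(s, revcomp(tt)))
    }, logical(1)))
    if (is_elem) next
    after <- substr(gseq, pos + L, pos + 2L * L - 1L)
    before <- if (pos - L >= 1L) substr(gseq, pos - L, pos - 1L) else ""
    if (identical(s, after) || identical(s, before)) {
      out <- rbind(out, data.frame(
        genome_id = carrier, position = pos, dr_seq = s,
        evidence = "tandem_duplicated_target", stringsAsFactors = FALSE))
    }
  }
  out[order(out$genome_id, out$position), , drop = FALSE]
}
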