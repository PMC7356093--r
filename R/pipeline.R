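## End-to-end orchestration: diff -> insert typing -> transposon census ->
## annotation impact, plus truth-table scoring for synthetic pairs.

#' Extract differential inserts and their genomic flanks from a diff
#'
#' @param diff `diff_report`.
#' @param genomes named list of the two [genome_seq] objects keyed by id.
#' @param flank flank length to extract (default 30 bp).
#' @param min_length only inserts at least this long are returned
#'   (default 2).
#' @return list with `seqs` (named character vector of inserted runs) and
#'   `flanks` (data.frame `insert_id`, `carrier`, `pos`, `left`, `right`).
#' @export
diff_inserts <- function(diff, genomes, flank = 30L, min_length = 2L) {
  v <- diff$variants
  v <- v[v$kind == "long_insert" & v$length >= min_length, , drop = FALSE]
  if (nrow(v) == 0L)
    return(list(seqs = character(0),
                flanks = data.frame(insert_id = character(),
                                    carrier = character(), pos = integer(),
                                    left = character(), right = character(),
                                    stringsAsFactors = FALSE)))
  ids <- sprintf("ins%02d", seq_len(nrow(v)))
  seqs <- character(nrow(v))
  left <- character(nrow(v))
  right <- character(nrow(v))
  pos <- integer(nrow(v))
  carrier <- v$carrier
  for (i in seq_len(nrow(v))) {
    g <- genomes[[carrier[i]]]$sequence
    p <- if (v$alt[i] == "") v$pos_a[i] else v$pos_b[i]
    s <- if (v$alt[i] == "") v$ref[i] else v$alt[i]
    seqs[i] <- s
    pos[i] <- p
    left[i] <- substr(g, max(1L, p - flank), p - 1L)
    right[i] <- substr(g, p + v$length[i],
                       min(nchar(g), p + v$length[i] + flank - 1L))
  }
  names(seqs) <- ids
  list(seqs = seqs,
       flanks = data.frame(insert_id = ids, carrier = carrier, pos = pos,
                           left = left, right = right,
                           stringsAsFactors = FALSE))
}

#' Run the full comparison pipeline on a genome pair
#'
#' Diffs the two genomes, clusters the differential long inserts into
#' types, detects terminal repeats per type, censuses transposon copies in
#' both genomes (differential loci flagged), searches for excision scars,
#' and annotates variants and copies against the supplied features.
#'
#' @param genome_a,genome_b [genome_seq] objects.
#' @param features_a,features_b optional feature tables (enable the impact
#'   stage).
#' @param k,substitution_ceiling,min_long_insert,min_chain_coverage see
#'   [diff_genomes()].
#' @param identity_threshold typing threshold in percent (default 90).
#' @param min_tir_len,min_dr_len see [find_terminal_repeats()].
#' @param full_length_tolerance see [classify_copies()].
#' @param promoter_window see [map_variant_to_features()].
#' @param n_bootstrap bootstrap replicates for the insert tree (0 = no
#'   tree; requires >= 4 inserts).
#' @param seed seed for the bootstrap resampling.
#' @return list of class `twindiff_result` with `diff`, `inserts`,
#'   `typing`, `element_types`, `census`, `scars`, `impact`, `tree`.
#' @export
run_pipeline <- function(genome_a, genome_b,
                         features_a = NULL, features_b = NULL,
                         k = 21L, substitution_ceiling = 5L,
                         min_long_insert = 2L, min_chain_coverage = 0.5,
                         identity_threshold = 90,
                         min_tir_len = 10L, min_dr_len = 3L,
                         full_length_tolerance = 10L,
                         promoter_window = 150L,
                         n_bootstrap = 0L, seed = 1L) {
  ga <- as_genome_seq(genome_a, "a")
  gb <- as_genome_seq(genome_b, "b")
  genomes <- setNames(list(ga, gb), c(ga$id, gb$id))
  diff <- diff_genomes(ga, gb, k = k,
                       substitution_ceiling = substitution_ceiling,
                       min_long_insert = min_long_insert,
                       min_chain_coverage = min_chain_coverage)
  ins <- diff_inserts(diff, genomes)
  typing <- NULL
  element_types <- list()
  census <- NULL
  scars <- NULL
  tree <- NULL
  if (length(ins$seqs) > 0L) {
    # type the elements, not the raw inserted runs: a left-normalised run
    # drags site-specific TSD/rotation context along, which contaminates
    # within-type identity (worst between opposite-orientation copies);
    # members without a terminal repeat are typed as called
    typing_seqs <- ins$seqs
    for (i in seq_along(typing_seqs)) {
      rp <- find_terminal_repeats(ins$seqs[[i]], ins$flanks$left[i],
                                  ins$flanks$right[i], min_tir_len,
                                  min_dr_len)
      if (!is.null(rp)) typing_seqs[[i]] <- rp$element_seq
    }
    typing <- cluster_inserts(typing_seqs, identity_threshold)
    element_types <- build_element_types(ins$seqs, typing, ins$flanks,
                                         min_tir_len, min_dr_len)
    # census per genome for each transposon type, flagging differential loci
    parts <- list()
    for (et in element_types) {
      if (!et$is_transposon) next
      for (gid in names(genomes)) {
        here <- ins$flanks$carrier == gid &
          ins$flanks$insert_id %in% et$members
        excl <- if (any(here)) {
          data.frame(start = ins$flanks$pos[here],
                     end = ins$flanks$pos[here] +
                       nchar(ins$seqs[here]) - 1L)
        } else NULL
        parts[[length(parts) + 1L]] <-
          scan_copies(genomes[[gid]], et, exclude = excl)
      }
    }
    census <- if (length(parts)) do.call(rbind, parts) else NULL
    if (!is.null(census) && nrow(census) > 0L) {
      census <- classify_copies(census, full_length_tolerance)
      census <- census[order(census$genome_id, census$start), ,
                       drop = FALSE]
      rownames(census) <- NULL
    }
    scars <- detect_excision_scars(diff, genomes, element_types,
                                   dr_len = min_dr_len)
    if (n_bootstrap > 0L && length(ins$seqs) >= 4L) {
      tree <- bootstrap_support(star_msa(ins$seqs), n_bootstrap, seed)
    }
  }
  impact <- NULL
  if (!is.null(features_a) || !is.null(features_b)) {
    rows <- list()
    if (!is.null(features_a))
      rows[[1L]] <- annotate_diff(diff, ga, features_a, "a",
                                  promoter_window)
    if (!is.null(features_b))
      rows[[2L]] <- annotate_diff(diff, gb, features_b, "b",
                                  promoter_window)
    impact <- do.call(rbind, rows)
    # count CDS fully inside each census copy
    if (!is.null(census) && nrow(census) > 0L) {
      feats <- setNames(list(features_a, features_b), c(ga$id, gb$id))
      census$cds_count <- vapply(seq_len(nrow(census)), function(i) {
        ff <- feats[[census$genome_id[i]]]
        if (is.null(ff)) return(0L)
        count_cds_in_copy(census[i, , drop = FALSE], ff)
      }, integer(1))
    }
  }
  structure(list(diff = diff, inserts = ins, typing = typing,
                 element_types = element_types, census = census,
                 scars = scars, impact = impact, tree = tree,
                 genomes = genomes),
            class = "twindiff_result")
}

#' @export
print.twindiff_result <- function(x, ...) {
  cat("<twindiff_result>\n")
  print(x$diff)
  if (!is.null(x$typing)) {
    cat(sprintf("  insert types: %d (transposon types: %d)\n",
                length(unique(x$typing$type_id)),
                sum(vapply(x$element_types, `[[`, logical(1),
                           "is_transposon"))))
  }
  if (!is.null(x$census))
    cat(sprintf("  census copies: %d (%d full-length)\n",
                nrow(x$census), sum(x$census$full_length)))
  invisible(x)
}

## ---- truth scoring -----------------------------------------------------

## canonical key of a differential small/long variant
variant_key <- function(kind, carrier, pos_a, pos_b, seq) {
  paste(kind, carrier, pos_a, pos_b, seq, sep = "|")
}

#' Score a pipeline result against a simulator truth table
#'
#' Compares, at exact coordinates: every differential event of the truth
#' (long inserts, one-letter indels, substitution) against the diff's
#' variants; truth element copies (shared plus differential) against the
#' census; the truth type partition against the called types (requiring a
#' one-to-one mapping); transposon flags per type; scar calls; and the
#' disrupted locus tag against the `gene_disrupted` impact reports.
#'
#' @param result [run_pipeline()] output.
#' @param truth truth data.frame from the simulator.
#' @return list of percentages and counts; `diff_recovery`,
#'   `census_recall`, `census_precision`, `typing_one_to_one`,
#'   `transposon_flags_correct`, `scars_recovered`, `disrupted_locus_found`
#'   and supporting detail.
#' @export
score_against_truth <- function(result, truth) {
  v <- result$diff$variants
  tr_ev <- truth[truth$event_kind %in%
                   c("long_insert", "indel_1bp", "substitution", "scar"), ,
                 drop = FALSE]
  truth_keys <- vapply(seq_len(nrow(tr_ev)), function(i) {
    r <- tr_ev[i, ]
    kind <- if (r$event_kind == "scar") "long_insert" else r$event_kind
    kind <- if (kind == "long_insert" && r$length < 2L) "indel_1bp" else kind
    carrier <- if (r$event_kind == "substitution") "" else r$genome
    variant_key(kind, carrier, r$pos_a, r$pos_b, r$sequence)
  }, character(1))
  call_keys <- if (nrow(v)) vapply(seq_len(nrow(v)), function(i) {
    s <- if (v$kind[i] == "substitution") v$alt[i]
         else if (v$alt[i] == "") v$ref[i] else v$alt[i]
    variant_key(v$kind[i], v$carrier[i], v$pos_a[i], v$pos_b[i], s)
  }, character(1)) else character(0)
  diff_recovered <- truth_keys %in% call_keys
  diff_extra <- sum(!call_keys %in% truth_keys)

  # census: truth copies with a TIR-bearing type
  tir_types <- unique(truth$type[nzchar(truth$tir_seq %||% "") &
                                   !is.na(truth$type)])
  cen <- result$census
  census_recall <- census_precision <- NA_real_
  if (!is.null(cen)) {
    truth_copies <- list()
    for (i in seq_len(nrow(truth))) {
      r <- truth[i, ]
      if (is.na(r$type) || !r$type %in% tir_types) next
      if (r$event_kind == "shared_copy") {
        truth_copies[[length(truth_copies) + 1L]] <-
          c(g = "strainA", s = r$elem_start_a, e = r$elem_start_a +
              r$elem_len - 1L)
        truth_copies[[length(truth_copies) + 1L]] <-
          c(g = "strainB", s = r$elem_start_b, e = r$elem_start_b +
              r$elem_len - 1L)
      } else if (r$event_kind == "long_insert") {
        s0 <- if (r$genome == "strainA") r$elem_start_a else r$elem_start_b
        truth_copies[[length(truth_copies) + 1L]] <-
          c(g = r$genome, s = s0, e = s0 + r$elem_len - 1L)
      }
    }
    tc <- unique(vapply(truth_copies, paste, character(1), collapse = "|"))
    cc <- if (nrow(cen)) paste(cen$genome_id, cen$start, cen$end,
                               sep = "|") else character(0)
    census_recall <- if (length(tc)) 100 * mean(tc %in% cc) else NA_real_
    census_precision <- if (length(cc)) 100 * mean(cc %in% tc) else NA_real_
  }

  # typing: one-to-one mapping between called types and truth families
  typing_one_to_one <- NA
  transposon_flags_correct <- NA
  if (!is.null(result$typing)) {
    fl <- result$inserts$flanks
    truth_ins <- truth[truth$event_kind == "long_insert", , drop = FALSE]
    truth_pos <- ifelse(truth_ins$genome == "strainA",
                        truth_ins$pos_a, truth_ins$pos_b)
    truth_family <- vapply(seq_len(nrow(result$typing)), function(i) {
      id <- result$typing$insert_id[i]
      row <- fl[fl$insert_id == id, ]
      hit <- truth_ins$genome == row$carrier & truth_pos == row$pos
      if (sum(hit) == 1L) truth_ins$type[hit] else NA_character_
    }, character(1))
    tab <- table(result$typing$type_id, truth_family, useNA = "ifany")
    typing_one_to_one <- !anyNA(truth_family) &&
      all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
    flags <- vapply(result$element_types, function(et) {
      fam <- truth_family[match(et$members[1L],
                                result$typing$insert_id)]
      if (is.na(fam)) return(NA)
      et$is_transposon == (fam %in% tir_types)
    }, logical(1))
    transposon_flags_correct <- all(flags, na.rm = FALSE)
  }

  # scars
  truth_scars <- truth[truth$event_kind == "scar", , drop = FALSE]
  scars_recovered <- if (nrow(truth_scars) == 0L) {
    is.null(result$scars) || nrow(result$scars) == 0L
  } else {
    !is.null(result$scars) &&
      nrow(result$scars) == nrow(truth_scars) &&
      all(paste(truth_scars$genome,
                ifelse(truth_scars$genome == "strainA",
                       truth_scars$pos_a, truth_scars$pos_b)) %in%
            paste(result$scars$genome_id, result$scars$position))
  }

  # disrupted gene
  truth_tag <- truth$locus_tag[!is.na(truth$locus_tag)]
  disrupted_locus_found <- if (length(truth_tag) == 0L) NA else {
    !is.null(result$impact) &&
      all(truth_tag %in%
            result$impact$feature[result$impact$effect == "gene_disrupted"])
  }

  list(
    diff_recovery = 100 * mean(diff_recovered),
    diff_extra_calls = diff_extra,
    n_truth_events = length(truth_keys),
    census_recall = census_recall,
    census_precision = census_precision,
    typing_one_to_one = typing_one_to_one,
    transposon_flags_correct = transposon_flags_correct,
    scars_recovered = scars_recovered,
    disrupted_locus_found = disrupted_locus_found
  )
}
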