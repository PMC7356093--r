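## Seeded generator of synthetic strain pairs with the statistical
## structure the analysis assumes: an ancestral genome with annotated ORFs,
## a transposon library with terminal inverted repeats (TIR) and
## target-site duplications (TSD), shared dispersed copies, per-strain
## differential inserts (one optionally disrupting a gene), one-letter
## indels, substitutions and optional excision scars -- plus a
## machine-readable truth table for recovery scoring.

#' Default element-type library parameters
#'
#' Three families modelled on typical bacterial insertion-sequence anatomy:
#' two TIR-bearing transposon types whose commonly mobilised form is a
#' truncated copy of a longer full element (853 of 1731 bp and 782 of
#' 1660 bp) with 4 bp target-site duplications, and one short family
#' without terminal repeats (378 bp).
#'
#' @return data.frame with columns `name`, `full_length`, `insert_length`,
#'   `tir_len`, `dr_len`, `has_tir`.
#' @export
default_element_types <- function() {
  data.frame(
    name = c("IS_A", "IS_B", "X"),
    full_length = c(1731L, 1660L, 378L),
    insert_length = c(853L, 782L, 378L),
    tir_len = c(24L, 26L, 0L),
    dr_len = c(4L, 4L, 0L),
    has_tir = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' The defaults are the package's reference study conditions: a 200 kb
#' ancestor at 40% GC with 100 ORFs, three element families
#' ([default_element_types()]), eight differential inserts per strain
#' (strain A: 7 IS_A + 1 X; strain B: 3 IS_A + 4 IS_B + 1 X, so the second
#' transposon family occurs only in strain B), 42 shared dispersed copies
#' (30 IS_A + 10 IS_B + 2 X, one full-length copy per transposon family),
#' four one-letter indels, one substitution, no scars, and one engineered
#' CDS disruption. Copies diverge from their family consensus by 0.5%
#' substitutions in the core (never in the TIRs), so realised within-type
#' identities are high but not exactly 100%.
#'
#' @param genome_length ancestor length in bp.
#' @param gc_content fraction in (0,1).
#' @param n_genes number of non-overlapping ORFs (300-1500 bp).
#' @param element_types data.frame as [default_element_types()].
#' @param n_differential integer matrix, rows `A`/`B`, one column per
#'   element type: differential insert counts.
#' @param n_shared shared dispersed copies per type (implanted in the
#'   ancestor, so both strains carry them identically).
#' @param n_full_shared how many of the shared copies per type are
#'   full-length rather than the truncated insert form.
#' @param n_indel_1bp,n_substitutions,n_scars small-event counts.
#' @param copy_divergence per-base substitution probability applied to each
#'   implanted copy's core.
#' @param disrupt_gene place one differential insert inside a CDS and
#'   record the disrupted locus tag.
#' @param scar_dr_len target length used for scar events.
#' @param margin exclusion margin in bp between implanted events.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L, gc_content = 0.40,
                       n_genes = 100L,
                       element_types = default_element_types(),
                       n_differential = rbind(A = c(7L, 0L, 1L),
                                              B = c(3L, 4L, 1L)),
                       n_shared = c(30L, 10L, 2L),
                       n_full_shared = c(1L, 1L, 0L),
                       n_indel_1bp = 4L, n_substitutions = 1L,
                       n_scars = 0L, copy_divergence = 0.005,
                       disrupt_gene = TRUE, scar_dr_len = 4L,
                       margin = 50L) {
  stopifnot(genome_length >= 1000L, gc_content > 0, gc_content < 1)
  stopifnot(nrow(element_types) == ncol(n_differential),
            length(n_shared) == nrow(element_types),
            length(n_full_shared) == nrow(element_types))
  stopifnot(all(n_differential >= 0L), all(n_shared >= 0L),
            all(n_full_shared <= n_shared),
            n_indel_1bp >= 0L, n_substitutions >= 0L, n_scars >= 0L)
  with(element_types,
       stopifnot(all(!has_tir | full_length > 2L * tir_len),
                 all(insert_length <= full_length)))
  structure(list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    n_genes = as.integer(n_genes), element_types = element_types,
    n_differential = n_differential, n_shared = as.integer(n_shared),
    n_full_shared = as.integer(n_full_shared),
    n_indel_1bp = as.integer(n_indel_1bp),
    n_substitutions = as.integer(n_substitutions),
    n_scars = as.integer(n_scars), copy_divergence = copy_divergence,
    disrupt_gene = isTRUE(disrupt_gene),
    scar_dr_len = as.integer(scar_dr_len),
    margin = as.integer(margin)
  ), class = "sim_config")
}

random_dna <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## m random sense codons (no stop codons), base composition near gc
random_codons <- function(m, gc) {
  stops <- c("TAA", "TAG", "TGA")
  out <- character(0)
  while (length(out) < m) {
    need <- m - length(out)
    bases <- sample(c("A", "C", "G", "T"), 3L * need, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    cods <- apply(matrix(bases, nrow = 3L), 2L, paste, collapse = "")
    out <- c(out, cods[!cods %in% stops])
  }
  out[seq_len(m)]
}

#' Simulate an ancestral genome with ORF annotation
#'
#' I.i.d. nucleotide background at the requested GC content; `n_genes`
#' non-overlapping CDS of 300-1500 bp (start codon, sense codons at the
#' background composition, stop codon), placed with at least 60 bp between
#' genes, on random strands, with locus tags `SYN_0001` ...
#'
#' @param config [sim_config()].
#' @param seed integer seed; identical `(config, seed)` gives identical
#'   output.
#' @return list with `genome` ([genome_seq], id `"ancestor"`) and
#'   `features` (data.frame).
#' @export
simulate_ancestor <- function(config, seed = 1L) {
  withr::with_seed(seed, {
    L <- config$genome_length
    gc <- config$gc_content
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    occupied <- logical(L)
    feats <- list()
    for (i in seq_len(config$n_genes)) {
      len <- 3L * sample(100:500, 1L)
      placed <- FALSE
      for (try in seq_len(2000L)) {
        pos <- sample.int(L - len - 400L, 1L) + 200L
        win <- max(1L, pos - 60L):min(L, pos + len + 59L)
        if (!any(occupied[win])) {
          occupied[win] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("cannot place ", config$n_genes,
             " genes without overlap; increase genome_length")
      strand <- sample(c("+", "-"), 1L)
      orf <- paste0("ATG",
                    paste(random_codons(len / 3L - 2L, gc), collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      if (strand == "-") orf <- revcomp(orf)
      chars[pos:(pos + len - 1L)] <- seq_chars(orf)
      feats[[i]] <- data.frame(
        seqid = "ancestor", start = pos, end = pos + len - 1L,
        strand = strand, type = "CDS",
        locus_tag = sprintf("SYN_%04d", i),
        product = "hypothetical protein", stringsAsFactors = FALSE)
    }
    features <- if (length(feats)) do.call(rbind, feats) else
      data.frame(seqid = character(), start = integer(), end = integer(),
                 strand = character(), type = character(),
                 locus_tag = character(), product = character(),
                 stringsAsFactors = FALSE)
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
    list(genome = genome_seq("ancestor", paste(chars, collapse = "")),
         features = features)
  })
}

#' Build the synthetic element library
#'
#' Each TIR-bearing type is `TIR + random core + revcomp(TIR)` in both its
#' full-length and truncated (insert) form, the two forms sharing their 5'
#' core; TIRs are drawn until non-palindromic so left and right termini are
#' distinguishable. Types without TIR are plain random sequence. Random
#' cores make the families mutually unrelated (pairwise identity far below
#' any typing threshold).
#'
#' @param config [sim_config()].
#' @param seed integer seed.
#' @return list of types: `name`, `has_tir`, `tir_seq`, `dr_len`,
#'   `full_seq`, `insert_seq`.
#' @export
build_element_library <- function(config, seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(nrow(config$element_types)), function(i) {
      et <- config$element_types[i, ]
      if (!et$has_tir) {
        s <- random_dna(et$insert_length, 0.5)
        return(list(name = et$name, has_tir = FALSE, tir_seq = "",
                    dr_len = 0L, full_seq = s, insert_seq = s))
      }
      repeat {
        tir <- random_dna(et$tir_len, 0.5)
        if (tir != revcomp(tir)) break
      }
      # the TIR must not extend into the core by chance: the first core
      # base may not complement the last core base of either the full or
      # the truncated form, or every copy of the family would carry a
      # one-base-longer palindrome than the element's true terminus
      n_core <- et$full_length - 2L * et$tir_len
      n_ins <- et$insert_length - 2L * et$tir_len
      repeat {
        core <- random_dna(n_core, 0.5)
        first <- substr(core, 1L, 1L)
        ends <- c(substr(core, n_core, n_core), substr(core, n_ins, n_ins))
        if (!any(first == vapply(ends, revcomp, character(1)))) break
      }
      ins_core <- substr(core, 1L, n_ins)
      list(name = et$name, has_tir = TRUE, tir_seq = tir,
           dr_len = et$dr_len,
           full_seq = paste0(tir, core, revcomp(tir)),
           insert_seq = paste0(tir, ins_core, revcomp(tir)))
    })
  })
}

## one mutated instance of a library element (substitutions in the core
## only, never in the TIRs), optionally reverse-complemented
element_instance <- function(lib_type, full, strand, divergence) {
  s <- if (full) lib_type$full_seq else lib_type$insert_seq
  tl <- nchar(lib_type$tir_seq)
  n <- nchar(s)
  core_idx <- if (tl > 0L) (tl + 1L):(n - tl) else seq_len(n)
  if (divergence > 0 && length(core_idx) > 0L) {
    hit <- core_idx[runif(length(core_idx)) < divergence]
    if (length(hit) > 0L) {
      cs <- seq_chars(s)
      cs[hit] <- vapply(cs[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      s <- paste(cs, collapse = "")
    }
  }
  if (strand == "-") revcomp(s) else s
}

#' Derive a synthetic strain pair from an ancestor
#'
#' Implants shared dispersed copies into the ancestor (inherited
#' identically by both strains), per-strain differential inserts with
#' target-site duplication, one-letter indels, substitutions and scars
#' (tandem target duplication with no element), keeping a `margin` bp
#' exclusion zone between events, then lifts the annotation through all
#' events. When `disrupt_gene` is set, the first differential insert of the
#' last transposon family carried by strain B (falling back to strain A) is
#' placed inside a CDS and its locus tag recorded.
#'
#' Truth coordinates for inserted runs are left-normalised with the same
#' canonical rule the diff applies, so exact-coordinate comparison is well
#' defined even inside duplicated target sequence.
#'
#' @param ancestor list from [simulate_ancestor()].
#' @param library list from [build_element_library()].
#' @param config [sim_config()].
#' @param seed integer seed.
#' @return list with `genomes` (named list of two [genome_seq], ids
#'   `strainA`/`strainB`), `features` (named list of lifted feature
#'   tables), and `truth` (data.frame, one row per implanted event).
#' @export
derive_strain_pair <- function(ancestor, library, config, seed = 1L) {
  withr::with_seed(seed, {
    anc <- ancestor$genome$sequence
    L <- nchar(anc)
    margin <- config$margin
    gene_mask <- logical(L)
    for (i in seq_len(nrow(ancestor$features))) {
      f <- ancestor$features[i, ]
      gene_mask[max(1L, f$start - margin):min(L, f$end + margin)] <- TRUE
    }
    ev_occ <- logical(L)
    place_point <- function(width, intergenic = TRUE) {
      for (try in seq_len(5000L)) {
        q <- sample.int(L - 400L - width, 1L) + 200L
        win <- (q - margin):(q + margin + width)
        busy <- any(ev_occ[win]) || (intergenic && any(gene_mask[win]))
        if (!busy) {
          ev_occ[win] <<- TRUE
          return(q)
        }
      }
      stop("requested events exceed available non-overlapping space")
    }

    events <- list()
    add_event <- function(e) events[[length(events) + 1L]] <<- e

    types <- config$element_types
    # shared dispersed copies
    for (ti in seq_len(nrow(types))) {
      n_sh <- config$n_shared[ti]
      if (n_sh == 0L) next
      n_full <- config$n_full_shared[ti]
      lib <- library[[ti]]
      for (ci in seq_len(n_sh)) {
        full <- ci <= n_full
        strand <- sample(c("+", "-"), 1L)
        inst <- element_instance(lib, full, strand, config$copy_divergence)
        dr <- lib$dr_len
        q <- place_point(dr, intergenic = TRUE)
        target <- if (dr > 0L) substr(anc, q + 1L, q + dr) else ""
        add_event(list(kind = "shared_copy", carrier = "both",
                       type = lib$name, point = q + dr,
                       seq = paste0(inst, target), elem_len = nchar(inst),
                       strand = strand, full = full, dr_seq = target,
                       tir_seq = lib$tir_seq, locus_tag = NA_character_))
      }
    }
    # differential inserts
    disrupt_left <- config$disrupt_gene &&
      nrow(ancestor$features) > 0L
    # prefer to disrupt with a transposon carried by strain B
    disrupt_key <- if (disrupt_left) {
      tir_types <- which(types$has_tir)
      b_types <- tir_types[config$n_differential["B", tir_types] > 0L]
      a_types <- tir_types[config$n_differential["A", tir_types] > 0L]
      if (length(b_types)) c("B", max(b_types))
      else if (length(a_types)) c("A", max(a_types)) else NULL
    } else NULL
    disrupted_tag <- NA_character_
    for (strain in c("A", "B")) {
      for (ti in seq_len(nrow(types))) {
        n_di <- config$n_differential[strain, ti]
        if (n_di == 0L) next
        lib <- library[[ti]]
        for (ci in seq_len(n_di)) {
          strand <- sample(c("+", "-"), 1L)
          inst <- element_instance(lib, FALSE, strand,
                                   config$copy_divergence)
          dr <- lib$dr_len
          disrupting <- !is.null(disrupt_key) && is.na(disrupted_tag) &&
            strain == disrupt_key[1L] && ti == as.integer(disrupt_key[2L]) &&
            ci == 1L
          if (disrupting) {
            # inside a CDS interior, clear of other events
            genes <- ancestor$features[
              ancestor$features$end - ancestor$features$start >= 400L, ,
              drop = FALSE]
            q <- NA_integer_
            for (try in seq_len(2000L)) {
              gi <- sample.int(nrow(genes), 1L)
              gf <- genes[gi, ]
              cand <- sample((gf$start + 150L):(gf$end - 150L - dr), 1L)
              win <- (cand - margin):(cand + margin + dr)
              if (!any(ev_occ[win])) {
                ev_occ[win] <- TRUE
                q <- cand
                disrupted_tag <- gf$locus_tag
                break
              }
            }
            if (is.na(q))
              stop("cannot place the disrupting insert inside a CDS")
          } else {
            q <- place_point(dr, intergenic = TRUE)
          }
          target <- if (dr > 0L) substr(anc, q + 1L, q + dr) else ""
          add_event(list(kind = "long_insert", carrier = strain,
                         type = lib$name, point = q + dr,
                         seq = paste0(inst, target), elem_len = nchar(inst),
                         strand = strand, full = FALSE, dr_seq = target,
                         tir_seq = lib$tir_seq,
                         locus_tag = if (disrupting) disrupted_tag
                                     else NA_character_))
        }
      }
    }
    # one-letter indels (an insertion in one strain == a deletion in the
    # other); alternate carrier and flavour
    for (i in seq_len(config$n_indel_1bp)) {
      strain <- c("A", "B")[1L + i %% 2L]
      q <- place_point(1L, intergenic = TRUE)
      base <- sample(c("A", "C", "G", "T"), 1L)
      add_event(list(kind = "indel_1bp", carrier = strain, type = NA,
                     point = q, seq = base, elem_len = 0L, strand = "+",
                     full = FALSE, dr_seq = "", tir_seq = "",
                     locus_tag = NA_character_))
    }
    # substitutions (applied to strain B)
    for (i in seq_len(config$n_substitutions)) {
      q <- place_point(1L, intergenic = TRUE)
      pos <- q + 1L
      ref <- substr(anc, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      add_event(list(kind = "substitution", carrier = "B", type = NA,
                     point = pos, seq = alt, elem_len = 0L, strand = "+",
                     full = FALSE, dr_seq = ref, tir_seq = "",
                     locus_tag = NA_character_))
    }
    # excision scars: tandem duplication of the target, no element
    for (i in seq_len(config$n_scars)) {
      strain <- c("A", "B")[1L + i %% 2L]
      dr <- config$scar_dr_len
      q <- place_point(dr, intergenic = TRUE)
      target <- substr(anc, q + 1L, q + dr)
      add_event(list(kind = "scar", carrier = strain, type = NA,
                     point = q + dr, seq = target, elem_len = 0L,
                     strand = "+", full = FALSE, dr_seq = target,
                     tir_seq = "", locus_tag = NA_character_))
    }

    # ---- build each strain and its coordinate liftover ----
    build_strain <- function(strain) {
      mine <- Filter(function(e) e$carrier %in% c("both", strain), events)
      ord <- order(vapply(mine, function(e) e$point, integer(1)))
      mine <- mine[ord]
      pieces <- character()
      cursor <- 1L
      bp <- integer(0)      # breakpoint: applies to ancestor pos > bp
      delta <- integer(0)
      for (e in mine) {
        if (e$kind == "substitution") {
          pieces <- c(pieces, substr(anc, cursor, e$point - 1L), e$seq)
          cursor <- e$point + 1L
        } else {
          pieces <- c(pieces, substr(anc, cursor, e$point), e$seq)
          cursor <- e$point + 1L
          bp <- c(bp, e$point)
          delta <- c(delta, nchar(e$seq))
        }
      }
      pieces <- c(pieces, substr(anc, cursor, L))
      lift <- local({
        bp_ <- bp
        cum <- cumsum(delta)
        function(x) {
          i <- findInterval(x - 1L, bp_)
          x + ifelse(i > 0L, cum[pmax(i, 1L)], 0L)
        }
      })
      list(seq = paste(pieces, collapse = ""), lift = lift)
    }
    sa <- build_strain("A")
    sb <- build_strain("B")
    genomes <- list(strainA = genome_seq("strainA", sa$seq),
                    strainB = genome_seq("strainB", sb$seq))
    lift <- list(A = sa$lift, B = sb$lift)

    lift_features <- function(strain) {
      f <- ancestor$features
      if (nrow(f) == 0L) {
        f$seqid <- character(0)
        return(f)
      }
      f$start <- as.integer(lift[[strain]](f$start))
      f$end <- as.integer(lift[[strain]](f$end))
      f$seqid <- paste0("strain", strain)
      f
    }
    features <- list(strainA = lift_features("A"),
                     strainB = lift_features("B"))

    # ---- truth table ----
    rows <- lapply(seq_along(events), function(i) {
      e <- events[[i]]
      row <- data.frame(
        event_id = sprintf("ev%03d", i), event_kind = e$kind,
        type = if (is.na(e$type[1L])) NA_character_ else e$type,
        genome = switch(e$carrier, both = "both",
                        A = "strainA", B = "strainB"),
        pos_a = NA_integer_, pos_b = NA_integer_,
        length = nchar(e$seq), elem_start_a = NA_integer_,
        elem_start_b = NA_integer_, elem_len = e$elem_len,
        strand = e$strand, sequence = e$seq, ref = "", alt = "",
        tir_seq = e$tir_seq, dr_seq = e$dr_seq,
        locus_tag = e$locus_tag, stringsAsFactors = FALSE)
      if (e$kind == "substitution") {
        row$pos_a <- as.integer(lift$A(e$point))
        row$pos_b <- as.integer(lift$B(e$point))
        row$ref <- e$dr_seq
        row$alt <- e$seq
        row$length <- 1L
        row$dr_seq <- ""
      } else if (e$kind == "shared_copy") {
        row$elem_start_a <- as.integer(lift$A(e$point)) + 1L
        row$elem_start_b <- as.integer(lift$B(e$point)) + 1L
        row$pos_a <- row$elem_start_a
        row$pos_b <- row$elem_start_b
        row$length <- e$elem_len
        row$sequence <- substr(e$seq, 1L, e$elem_len)
      } else {
        # an inserted run carried by one strain
        carrier <- e$carrier
        other <- setdiff(c("A", "B"), carrier)
        cseq <- genomes[[paste0("strain", carrier)]]$sequence
        start_c <- as.integer(lift[[carrier]](e$point)) + 1L
        nm <- normalize_insertion(cseq, start_c, e$seq)
        after_o <- as.integer(lift[[other]](e$point)) - nm$shift
        if (carrier == "A") {
          row$pos_a <- nm$pos
          row$pos_b <- after_o
          row$ref <- nm$seq
        } else {
          row$pos_b <- nm$pos
          row$pos_a <- after_o
          row$alt <- nm$seq
        }
        row$sequence <- nm$seq
        if (e$elem_len > 0L) {
          # element coordinates (un-normalised) in the carrier
          if (carrier == "A") row$elem_start_a <- start_c
          else row$elem_start_b <- start_c
        }
      }
      row
    })
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(event_id = character(), event_kind = character(),
                 type = character(), genome = character(),
                 pos_a = integer(), pos_b = integer(), length = integer(),
                 elem_start_a = integer(), elem_start_b = integer(),
                 elem_len = integer(), strand = character(),
                 sequence = character(), ref = character(),
                 alt = character(), tir_seq = character(),
                 dr_seq = character(), locus_tag = character(),
                 stringsAsFactors = FALSE)
    truth <- truth[order(truth$genome, truth$pos_a, truth$pos_b), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    list(genomes = genomes, features = features, truth = truth)
  })
}

#' Simulate a complete synthetic strain pair
#'
#' Convenience wrapper: derives per-stage seeds from one master seed, then
#' runs [simulate_ancestor()], [build_element_library()] and
#' [derive_strain_pair()].
#'
#' @param config [sim_config()].
#' @param seed master integer seed.
#' @return list with `ancestor`, `library`, `genomes`, `features`, `truth`.
#' @export
simulate_strain_pair <- function(config = sim_config(), seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  ancestor <- simulate_ancestor(config, seeds[1L])
  library <- build_element_library(config, seeds[2L])
  pair <- derive_strain_pair(ancestor, library, config, seeds[3L])
  c(list(ancestor = ancestor, library = library), pair)
}

#' Write a truth table to TSV and JSON
#'
#' @param truth truth data.frame from [derive_strain_pair()].
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  tsv <- file.path(dir, "truth.tsv")
  js <- file.path(dir, "truth.json")
  write_tsv(truth, tsv)
  jsonlite::write_json(truth, js, auto_unbox = FALSE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(tsv, js))
}

#' Read a truth table written by [write_truth()]
#'
#' @param path `truth.tsv` or `truth.json`.
#' @return truth data.frame.
#' @export
read_truth <- function(path) {
  if (grepl("\\.json$", path)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
  }
  chr <- c("type", "locus_tag", "sequence", "ref", "alt", "tir_seq",
           "dr_seq")
  for (cc in intersect(chr, names(df))) {
    df[[cc]] <- as.character(df[[cc]])
    df[[cc]][is.na(df[[cc]]) & cc %in% c("sequence", "ref", "alt",
                                         "tir_seq", "dr_seq")] <- ""
  }
  int <- c("pos_a", "pos_b", "length", "elem_start_a", "elem_start_b",
           "elem_len")
  for (cc in intersect(int, names(df))) df[[cc]] <- as.integer(df[[cc]])
  df
}
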