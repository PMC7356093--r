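## Intersection of variants and element copies with gene annotations:
## disruption, frameshift and synonymous/missense/nonsense calls, and a
## coding+promoter identity comparison over a configured gene panel.

#' Extract a CDS sequence from a genome
#'
#' @param genome [genome_seq] or bare sequence.
#' @param feature one-row feature data.frame (`start`, `end`, `strand`).
#' @return the coding-strand sequence (reverse-complemented for `-`).
#' @export
extract_cds <- function(genome, feature) {
  g <- as_genome_seq(genome)
  s <- substr(g$sequence, feature$start, feature$end)
  if (feature$strand == "-") revcomp(s) else s
}

## translate a coding-strand nucleotide string with the bacterial code
## (translation table 11); trailing partial codons are dropped with a
## warning
translate_cds <- function(seq, quiet = FALSE) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    if (!quiet) warning("CDS length not a multiple of 3; partial codon dropped")
    seq <- substr(seq, 1L, n - n %% 3L)
  }
  as.character(Biostrings::translate(
    Biostrings::DNAString(seq),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
}

## promoter interval for a feature: promoter_window bp immediately upstream
## of the CDS start, strand-aware; clipped to the genome
promoter_interval <- function(feature, promoter_window, genome_length) {
  if (feature$strand == "+") {
    c(max(1L, feature$start - promoter_window), feature$start - 1L)
  } else {
    c(feature$end + 1L, min(genome_length, feature$end + promoter_window))
  }
}

#' Map one variant or element copy onto gene annotations
#'
#' The event interval is intersected (closed-interval semantics: touching a
#' CDS boundary counts as overlap) with the CDS features of the carrier
#' genome, then with strand-aware promoter windows upstream of CDS starts.
#' Effects: a long insert or element copy inside a CDS disrupts the gene;
#' a 1-bp indel inside a CDS is a frameshift; a substitution inside a CDS
#' is translated in-frame with the bacterial genetic code (table 11) to
#' decide synonymous / missense / nonsense; everything else is `none`.
#'
#' @param kind `"substitution"`, `"indel_1bp"`, `"long_insert"` or
#'   `"element_copy"`.
#' @param start,end 1-based inclusive interval of the event in the carrier
#'   genome (for a substitution or indel, `start == end`; for an insertion
#'   the span of the inserted run).
#' @param alt alternate base (substitutions only).
#' @param genome carrier [genome_seq].
#' @param features feature data.frame for the carrier genome.
#' @param promoter_window bp upstream of a CDS start considered promoter
#'   (default 150).
#' @return one-row data.frame: `genome_id`, `pos`, `kind`, `feature`
#'   (locus_tag or "intergenic"), `region`, `effect`.
#' @export
map_variant_to_features <- function(kind, start, end, alt = "",
                                    genome, features,
                                    promoter_window = 150L) {
  g <- as_genome_seq(genome)
  glen <- nchar(g$sequence)
  if (start < 1L || end > glen) stop("event locus outside genome bounds")
  cds <- features[features$type == "CDS", , drop = FALSE]
  report <- function(feature, region, effect) {
    data.frame(genome_id = g$id, pos = start, kind = kind,
               feature = feature, region = region, effect = effect,
               stringsAsFactors = FALSE)
  }
  if (nrow(cds) > 0L) {
    hit <- which(cds$start <= end & cds$end >= start)
    if (length(hit) > 0L) {
      f <- cds[hit[1L], , drop = FALSE]
      tag <- f$locus_tag
      effect <- switch(kind,
        long_insert = ,
        element_copy = "gene_disrupted",
        indel_1bp = "frameshift",
        substitution = {
          cds_seq <- extract_cds(g, f)
          off <- if (f$strand == "+") start - f$start + 1L else
            f$end - start + 1L
          base <- if (f$strand == "+") alt else revcomp(alt)
          mut <- cds_seq
          substr(mut, off, off) <- base
          codon_i <- (off - 1L) %/% 3L
          ref_cod <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
          alt_cod <- substr(mut, codon_i * 3L + 1L, codon_i * 3L + 3L)
          if (nchar(ref_cod) < 3L) {
            "none"  # partial trailing codon
          } else {
            aa_ref <- translate_cds(ref_cod, quiet = TRUE)
            aa_alt <- translate_cds(alt_cod, quiet = TRUE)
            if (aa_ref == aa_alt) "synonymous"
            else if (aa_alt == "*") "nonsense"
            else "missense"
          }
        },
        "none")
      return(report(tag, "CDS", effect))
    }
    # promoter windows
    for (i in seq_len(nrow(cds))) {
      pr <- promoter_interval(cds[i, , drop = FALSE], promoter_window, glen)
      if (pr[1L] <= pr[2L] && pr[1L] <= end && pr[2L] >= start) {
        return(report(cds$locus_tag[i], "promoter", "none"))
      }
    }
  }
  report("intergenic", "intergenic", "none")
}

#' Annotate every variant of a diff against one genome's features
#'
#' Substitutions and indels are evaluated at their position in the chosen
#' genome; insertions are evaluated only against the genome that carries
#' them.
#'
#' @param diff `diff_report`.
#' @param genome carrier [genome_seq].
#' @param features features of that genome.
#' @param side `"a"` or `"b"`: which side of the diff `genome` is.
#' @param promoter_window see [map_variant_to_features()].
#' @return data.frame of disruption reports (one row per evaluated event).
#' @export
annotate_diff <- function(diff, genome, features, side = c("a", "b"),
                          promoter_window = 150L) {
  side <- match.arg(side)
  g <- as_genome_seq(genome)
  v <- diff$variants
  rows <- list()
  for (i in seq_len(nrow(v))) {
    kind <- v$kind[i]
    if (kind == "substitution") {
      pos <- if (side == "a") v$pos_a[i] else v$pos_b[i]
      alt <- if (side == "a") v$alt[i] else v$ref[i]
      # alt, seen from this genome, is the other genome's base
      rows[[length(rows) + 1L]] <-
        map_variant_to_features("substitution", pos, pos, alt, g, features,
                                promoter_window)
    } else {
      if (v$carrier[i] != g$id) next
      pos <- if (v$alt[i] == "") v$pos_a[i] else v$pos_b[i]
      rows[[length(rows) + 1L]] <-
        map_variant_to_features(kind, pos, pos + v$length[i] - 1L, "",
                                g, features, promoter_window)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(genome_id = character(), pos = integer(),
                      kind = character(), feature = character(),
                      region = character(), effect = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Count CDS features fully contained in an element copy
#'
#' @param copy one-row data.frame with `start`, `end`.
#' @param features feature data.frame.
#' @return integer count of CDS fully inside `[start, end]`.
#' @export
count_cds_in_copy <- function(copy, features) {
  cds <- features[features$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(0L)
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = cds$start, end = cds$end),
    IRanges::IRanges(start = copy$start, end = copy$end),
    type = "within")
  length(unique(S4Vectors::queryHits(hits)))
}

#' Read a gene panel from YAML
#'
#' The panel file lists, per gene, the gene name and one locus tag per
#' strain, e.g. `- {gene: soxB, locus_a: AL038_05225, locus_b:
#' BLE401_00760}`. A panel for the dissimilatory sulfur-metabolism genes of
#' the two *Beggiatoa leptomitoformis* strains ships with the package
#' (`system.file("extdata", "sulfur_panel.yaml", package = "twindiff")`).
#'
#' @param path YAML file.
#' @return data.frame with columns `gene`, `locus_a`, `locus_b`.
#' @export
read_gene_panel <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- y$panel %||% y
  do.call(rbind, lapply(entries, function(e) {
    data.frame(gene = e$gene, locus_a = e$locus_a, locus_b = e$locus_b,
               stringsAsFactors = FALSE)
  }))
}

#' Compare a gene panel between two genomes
#'
#' For every panel gene, extracts the CDS and the promoter window upstream
#' of it from each genome, aligns them globally and reports percent
#' identities; `differs` is `TRUE` when either region is below 100%.
#'
#' @param genome_a,genome_b [genome_seq] objects.
#' @param features_a,features_b their feature tables.
#' @param panel data.frame from [read_gene_panel()] (or with the same
#'   columns).
#' @param promoter_window bp upstream (default 150).
#' @return data.frame: one row per gene with `cds_identity`,
#'   `promoter_identity`, `differs`, `missing`.
#' @export
compare_gene_panel <- function(genome_a, features_a, genome_b, features_b,
                               panel, promoter_window = 150L) {
  ga <- as_genome_seq(genome_a, "a")
  gb <- as_genome_seq(genome_b, "b")
  one_side <- function(g, features, tag) {
    i <- which(features$type == "CDS" & features$locus_tag == tag)
    if (length(i) == 0L) return(NULL)
    f <- features[i[1L], , drop = FALSE]
    pr <- promoter_interval(f, promoter_window, nchar(g$sequence))
    prom <- if (pr[1L] > pr[2L]) "" else
      substr(g$sequence, pr[1L], pr[2L])
    if (f$strand == "-" && nchar(prom) > 0L) prom <- revcomp(prom)
    list(cds = extract_cds(g, f), prom = prom)
  }
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    xa <- one_side(ga, features_a, panel$locus_a[i])
    xb <- one_side(gb, features_b, panel$locus_b[i])
    if (is.null(xa) || is.null(xb)) {
      return(data.frame(gene = panel$gene[i], locus_a = panel$locus_a[i],
                        locus_b = panel$locus_b[i],
                        cds_identity = NA_real_,
                        promoter_identity = NA_real_,
                        differs = NA, missing = TRUE,
                        stringsAsFactors = FALSE))
    }
    cid <- pair_identity(xa$cds, xb$cds)
    pid <- if (nchar(xa$prom) == 0L || nchar(xb$prom) == 0L) NA_real_ else
      pair_identity(xa$prom, xb$prom)
    data.frame(gene = panel$gene[i], locus_a = panel$locus_a[i],
               locus_b = panel$locus_b[i],
               cds_identity = cid, promoter_identity = pid,
               differs = cid < 100 || (!is.na(pid) && pid < 100),
               missing = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
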