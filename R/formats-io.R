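#' Genome sequence container
#'
#' A minimal container for one assembly: identifier, uppercase sequence over
#' the A/C/G/T/N alphabet, and a topology flag. The chromosomes this package
#' targets are single replicons, so the default topology is linear; circular
#' handling (rotation before diffing) is opt-in per genome.
#'
#' @param id non-empty identifier.
#' @param sequence character scalar; will be uppercased and validated.
#' @param topology `"linear"` (default) or `"circular"`.
#' @return an object of class `genome_seq` with fields `id`, `sequence`,
#'   `topology`.
#' @export
genome_seq <- function(id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("sequence of '", id, "' is empty")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                 substr(sequence, bad, bad), bad, id))
  }
  structure(list(id = id, sequence = sequence, topology = topology),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %s bp (%s)\n",
              x$id, format(nchar(x$sequence), big.mark = ","), x$topology))
  invisible(x)
}

## accept either a genome_seq or a bare string
as_genome_seq <- function(x, id = "genome") {
  if (inherits(x, "genome_seq")) return(x)
  genome_seq(id, x)
}

#' Read a FASTA file into genome_seq objects
#'
#' Sequences are uppercased; any character outside A/C/G/T/N is rejected with
#' the offending position named. Record ids (first whitespace-delimited token
#' of the header) must be unique.
#'
#' @param path FASTA file.
#' @param topology topology assigned to every record.
#' @return list of [genome_seq] objects.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(recs))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) stop("duplicate FASTA ids in ", path)
  lapply(seq_along(recs), function(i) {
    genome_seq(ids[[i]], as.character(recs[[i]]), topology)
  })
}

#' Write genome_seq objects to FASTA (60-column wrapping)
#'
#' @param genomes a [genome_seq] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_seq")) genomes <- list(genomes)
  seqs <- vapply(genomes, function(g) g$sequence, character(1))
  ids <- vapply(genomes, function(g) g$id, character(1))
  set <- Biostrings::DNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Thin wrapper around [rtracklayer::import()] that flattens the result into
#' a feature table and validates coordinates against the genome when one is
#' supplied. `locus_tag` and `product` attributes are extracted when present.
#'
#' @param path GFF3 file.
#' @param genome optional [genome_seq]; when given, `seqid` must match its id
#'   and all coordinates must fall inside the sequence.
#' @return data.frame with columns `seqid`, `start`, `end` (1-based
#'   inclusive), `strand`, `type`, `locus_tag`, `product`.
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      type = character(), locus_tag = character(),
                      product = character(), stringsAsFactors = FALSE))
  }
  mc <- S4Vectors::mcols(gr)
  grab <- function(col) {
    if (col %in% colnames(mc)) as.character(mc[[col]]) else
      rep(NA_character_, length(gr))
  }
  feats <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    locus_tag = grab("locus_tag"),
    product = grab("product"),
    stringsAsFactors = FALSE
  )
  if (any(feats$start < 1L) || any(feats$start > feats$end))
    stop("malformed feature coordinates in ", path)
  if (!all(feats$strand %in% c("+", "-")))
    stop("features must be stranded (+/-) in ", path)
  if (!is.null(genome)) {
    genome <- as_genome_seq(genome)
    if (!all(feats$seqid == genome$id))
      stop("GFF3 seqid does not match genome id '", genome$id, "'")
    if (any(feats$end > nchar(genome$sequence)))
      stop("feature end exceeds genome length in ", path)
  }
  feats[order(feats$seqid, feats$start, feats$end), , drop = FALSE]
}

#' Write a feature table to GFF3
#'
#' @param features feature data.frame as returned by [read_gff3()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$locus_tag <- features$locus_tag
  S4Vectors::mcols(gr)$product <- features$product
  # complete CDS features start in frame
  S4Vectors::mcols(gr)$phase <- ifelse(features$type == "CDS", 0L,
                                       NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Convert 1-based inclusive coordinates to BED (0-based half-open)
#'
#' @param start,end 1-based inclusive integer vectors.
#' @return data.frame with columns `start0`, `end0`.
#' @export
coords_to_bed <- function(start, end) {
  stopifnot(all(start >= 1L), all(end >= start))
  data.frame(start0 = start - 1L, end0 = end)
}

#' Convert BED (0-based half-open) intervals to 1-based inclusive
#'
#' @param start0,end0 0-based half-open integer vectors.
#' @return data.frame with columns `start`, `end`.
#' @export
bed_to_coords <- function(start0, end0) {
  stopifnot(all(start0 >= 0L), all(end0 > start0))
  data.frame(start = start0 + 1L, end = end0)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write the pipeline's report tables
#'
#' Emits one file per computed stage under `out_dir`: `variants.tsv` and
#' `inserts.bed` from the diff, `types.tsv` and `identity_matrix.tsv` from
#' insert typing, `copies.tsv`/`copies.bed`/`scars.tsv` from the census,
#' `disruptions.tsv` and `gene_panel.tsv` from the annotation stage,
#' `tree.nwk` when a tree is present, and `summary.json`. TSV coordinates are
#' 1-based inclusive; BED is 0-based half-open. Row ordering is deterministic
#' (genome id, then coordinate, then kind), so identical inputs give
#' byte-identical outputs.
#'
#' @param results a [run_pipeline()] result, or any list with a subset of the
#'   fields `diff`, `typing`, `identity`, `element_types`, `census`, `scars`,
#'   `impact`, `gene_panel`, `tree`.
#' @param out_dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_report_tables <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  written <- character()
  emit <- function(name) written <<- c(written, file.path(out_dir, name))

  summary <- list()
  if (!is.null(results$diff)) {
    v <- results$diff$variants
    v <- v[order(v$carrier, v$pos_a, v$kind), , drop = FALSE]
    tab <- data.frame(kind = v$kind, carrier = v$carrier,
                      pos_a = v$pos_a, pos_b = v$pos_b,
                      ref = v$ref, alt = v$alt, length = v$length,
                      stringsAsFactors = FALSE)
    write_tsv(tab, file.path(out_dir, "variants.tsv")); emit("variants.tsv")
    ins <- v[v$kind == "long_insert", , drop = FALSE]
    pos <- ifelse(ins$alt == "", ins$pos_a, ins$pos_b)
    bed <- data.frame(chrom = ins$carrier,
                      start0 = as.integer(pos) - 1L,
                      end0 = as.integer(pos) + ins$length - 1L,
                      name = if (nrow(ins)) paste0("insert_",
                                                   seq_len(nrow(ins)))
                             else character(0),
                      stringsAsFactors = FALSE)
    write_tsv(bed, file.path(out_dir, "inserts.bed")); emit("inserts.bed")
    summary$variant_counts <- as.list(table(v$kind))
    summary$aligned_identity <- results$diff$aligned_identity
    summary$chain_coverage <- as.list(results$diff$chain_coverage)
  }
  if (!is.null(results$typing)) {
    write_tsv(results$typing, file.path(out_dir, "types.tsv"))
    emit("types.tsv")
    summary$n_types <- length(unique(results$typing$type_id))
    idm <- attr(results$typing, "identity") %||% results$identity
    if (!is.null(idm)) {
      df <- data.frame(insert_id = rownames(idm), idm, check.names = FALSE)
      write_tsv(df, file.path(out_dir, "identity_matrix.tsv"))
      emit("identity_matrix.tsv")
    }
  }
  if (!is.null(results$census)) {
    cp <- results$census
    cp <- cp[order(cp$genome_id, cp$start, cp$type_id), , drop = FALSE]
    write_tsv(cp, file.path(out_dir, "copies.tsv")); emit("copies.tsv")
    bed <- data.frame(chrom = cp$genome_id, start0 = cp$start - 1L,
                      end0 = cp$end,
                      name = paste0("type", cp$type_id),
                      score = 0L, strand = cp$strand,
                      stringsAsFactors = FALSE)
    write_tsv(bed, file.path(out_dir, "copies.bed")); emit("copies.bed")
    summary$n_copies <- nrow(cp)
  }
  if (!is.null(results$scars)) {
    write_tsv(results$scars, file.path(out_dir, "scars.tsv"))
    emit("scars.tsv")
    summary$n_scars <- nrow(results$scars)
  }
  if (!is.null(results$impact)) {
    im <- results$impact
    im <- im[order(im$genome_id, im$pos, im$effect), , drop = FALSE]
    write_tsv(im, file.path(out_dir, "disruptions.tsv"))
    emit("disruptions.tsv")
  }
  if (!is.null(results$gene_panel)) {
    write_tsv(results$gene_panel, file.path(out_dir, "gene_panel.tsv"))
    emit("gene_panel.tsv")
  }
  if (!is.null(results$tree)) {
    ape::write.tree(results$tree, file.path(out_dir, "tree.nwk"))
    emit("tree.nwk")
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit("summary.json")
  invisible(written)
}
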