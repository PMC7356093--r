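test_that("simulation is deterministic given (config, seed)", {
  cfg <- small_config()
  s1 <- simulate_strain_pair(cfg, seed = 61L)
  s2 <- simulate_strain_pair(cfg, seed = 61L)
  expect_identical(s1$genomes$strainA$sequence, s2$genomes$strainA$sequence)
  expect_identical(s1$genomes$strainB$sequence, s2$genomes$strainB$sequence)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$features, s2$features)
  s3 <- simulate_strain_pair(cfg, seed = 62L)
  expect_false(identical(s1$genomes$strainA$sequence,
                         s3$genomes$strainA$sequence))
})

test_that("ancestor GC content and gene placement obey the config", {
  cfg <- sim_config(genome_length = 100000L, gc_content = 0.40,
                    n_genes = 40L)
  anc <- simulate_ancestor(cfg, seed = 7L)
  gc <- sum(chars(anc$genome$sequence) %in% c("G", "C")) /
    nchar(anc$genome$sequence)
  expect_lt(abs(gc - 0.40), 0.02)
  expect_equal(nrow(anc$features), 40L)
  expect_true(all(anc$features$end - anc$features$start + 1 >= 300))
  expect_true(all(anc$features$end - anc$features$start + 1 <= 1500))
  # non-overlapping
  f <- anc$features[order(anc$features$start), ]
  expect_true(all(f$start[-1] > f$end[-nrow(f)]))
  # every ORF translates cleanly
  for (i in seq_len(10)) {
    aa <- twindiff:::translate_cds(extract_cds(anc$genome, f[i, ]))
    expect_match(aa, "^M[^*]*\\*$")
  }
  # no genes requested
  anc0 <- simulate_ancestor(sim_config(genome_length = 20000L,
                                       n_genes = 0L), seed = 7L)
  expect_equal(nrow(anc0$features), 0L)
})

test_that("element library types have the promised anatomy", {
  cfg <- sim_config()
  lib <- build_element_library(cfg, seed = 13L)
  for (i in seq_along(lib)) {
    et <- cfg$element_types[i, ]
    el <- lib[[i]]
    expect_equal(nchar(el$full_seq), et$full_length)
    expect_equal(nchar(el$insert_seq), et$insert_length)
    if (et$has_tir) {
      expect_true(startsWith(el$full_seq, el$tir_seq))
      expect_true(endsWith(el$full_seq, rc_oracle(el$tir_seq)))
      expect_true(startsWith(el$insert_seq, el$tir_seq))
      expect_true(endsWith(el$insert_seq, rc_oracle(el$tir_seq)))
    } else {
      expect_null(find_terminal_repeats(el$insert_seq, rand_dna(30),
                                        rand_dna(30)))
    }
  }
  # families mutually unrelated: identity far below any typing threshold
  m <- identity_matrix(setNames(vapply(lib, `[[`, character(1),
                                       "insert_seq"),
                                vapply(lib, `[[`, character(1), "name")),
                       both_strands = TRUE)
  expect_true(all(m[upper.tri(m)] < 90))
})

test_that("truth events are embedded verbatim in the derived strains", {
  sim <- simulate_strain_pair(small_config(n_scars = 1L), seed = 71L)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    r <- tr[i, ]
    if (r$event_kind == "substitution") {
      expect_equal(substr(sim$genomes$strainA$sequence, r$pos_a, r$pos_a),
                   r$ref)
      expect_equal(substr(sim$genomes$strainB$sequence, r$pos_b, r$pos_b),
                   r$alt)
    } else if (r$genome == "both") {
      expect_equal(substr(sim$genomes$strainA$sequence, r$elem_start_a,
                          r$elem_start_a + r$elem_len - 1L),
                   r$sequence)
      expect_equal(substr(sim$genomes$strainB$sequence, r$elem_start_b,
                          r$elem_start_b + r$elem_len - 1L),
                   r$sequence)
    } else {
      gseq <- sim$genomes[[r$genome]]$sequence
      pos <- if (r$genome == "strainA") r$pos_a else r$pos_b
      expect_equal(substr(gseq, pos, pos + r$length - 1L), r$sequence)
    }
  }
})

test_that("annotation liftover keeps undisrupted ORFs translating", {
  sim <- simulate_strain_pair(small_config(), seed = 72L)
  disrupted <- sim$truth$locus_tag[!is.na(sim$truth$locus_tag)]
  expect_length(disrupted, 1L)
  for (strain in c("strainA", "strainB")) {
    f <- sim$features[[strain]]
    for (i in seq_len(nrow(f))) {
      if (f$locus_tag[i] %in% disrupted && strain == "strainB") next
      aa <- twindiff:::translate_cds(extract_cds(sim$genomes[[strain]],
                                                 f[i, ]), quiet = TRUE)
      expect_match(aa, "^M[^*]*\\*$")
    }
  }
  # the disrupted ORF no longer translates cleanly in its carrier
  fB <- sim$features$strainB
  fd <- fB[fB$locus_tag == disrupted, ]
  aa_bad <- twindiff:::translate_cds(extract_cds(sim$genomes$strainB, fd),
                                     quiet = TRUE)
  expect_false(grepl("^M[^*]*\\*$", aa_bad))
})

test_that("a zero-event config yields identical strains", {
  cfg <- sim_config(genome_length = 20000L, n_genes = 8L,
                    n_differential = rbind(A = c(0L, 0L, 0L),
                                           B = c(0L, 0L, 0L)),
                    n_shared = c(0L, 0L, 0L), n_full_shared = c(0L, 0L, 0L),
                    n_indel_1bp = 0L, n_substitutions = 0L,
                    disrupt_gene = FALSE)
  sim <- simulate_strain_pair(cfg, seed = 73L)
  expect_identical(sim$genomes$strainA$sequence,
                   sim$genomes$strainB$sequence)
  expect_identical(sim$genomes$strainA$sequence,
                   sim$ancestor$genome$sequence)
  expect_equal(nrow(sim$truth), 0L)
  d <- diff_genomes(sim$genomes$strainA, sim$genomes$strainB)
  expect_equal(nrow(d$variants), 0L)
})

test_that("event counts match the configuration by construction", {
  cfg <- small_config(n_scars = 1L)
  sim <- simulate_strain_pair(cfg, seed = 74L)
  k <- table(sim$truth$event_kind)
  expect_equal(unname(k[["long_insert"]]), sum(cfg$n_differential))
  expect_equal(unname(k[["shared_copy"]]), sum(cfg$n_shared))
  expect_equal(unname(k[["indel_1bp"]]), cfg$n_indel_1bp)
  expect_equal(unname(k[["substitution"]]), cfg$n_substitutions)
  expect_equal(unname(k[["scar"]]), 1L)
  # requested events beyond the available space fail loudly
  expect_error(
    simulate_strain_pair(
      sim_config(genome_length = 20000L, n_genes = 5L,
                 n_shared = c(150L, 0L, 0L),
                 n_full_shared = c(0L, 0L, 0L)),
      seed = 74L),
    "non-overlapping space")
})

test_that("truth tables round-trip through TSV and JSON", {
  sim <- simulate_strain_pair(small_config(), seed = 75L)
  d <- withr::local_tempdir()
  paths <- write_truth(sim$truth, d)
  t_tsv <- read_truth(file.path(d, "truth.tsv"))
  t_json <- read_truth(file.path(d, "truth.json"))
  cols <- c("event_id", "event_kind", "genome", "pos_a", "pos_b",
            "length", "sequence")
  expect_equal(t_tsv[, cols], sim$truth[, cols], ignore_attr = TRUE)
  expect_equal(t_json[, cols], sim$truth[, cols], ignore_attr = TRUE)
  # sorted by genome then position
  expect_false(is.unsorted(order(sim$truth$genome, sim$truth$pos_a)))
  # empty truth -> header-only TSV
  write_truth(sim$truth[0, ], d)
  expect_length(readLines(file.path(d, "truth.tsv")), 1L)
})
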