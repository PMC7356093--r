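test_that("anchors are unique shared k-mers, matching brute-force sets", {
  set.seed(101)
  a <- rand_dna(2000)
  b <- mutate_oracle(a, n_sub = 2L, n_indel = 1L, n_ins = 1L, ins_len = 30L)
  k <- 15L
  anc <- index_anchors(a, b, k)
  # brute force: dictionary of all k-mers unique in each genome
  km <- function(s) substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  ka <- km(a); kb <- km(b)
  ua <- names(which(table(ka) == 1L))
  ub <- names(which(table(kb) == 1L))
  shared <- intersect(ua, ub)
  expect_setequal(paste(anc$pos_a, anc$pos_b),
                  paste(match(shared, ka) - 1L, match(shared, kb) - 1L))
  # identity case
  anc2 <- index_anchors(a, a, k)
  expect_true(all(anc2$pos_a == anc2$pos_b))
  expect_gt(nrow(anc2), 1900)
})

test_that("anchors across a single insert split into two offset classes", {
  set.seed(102)
  a <- rand_dna(10000)
  ins <- rand_dna(100)
  b <- paste0(substr(a, 1, 5000), ins, substr(a, 5001, 10000))
  anc <- index_anchors(a, b, 21L)
  expect_true(all(anc$pos_b - anc$pos_a %in% c(0L, 100L)))
  expect_error(index_anchors(a, b, 9L), ">= 15")
})

test_that("chaining keeps collinear anchors and drops translocated ones", {
  anc <- data.frame(pos_a = seq(0L, 4900L, by = 100L),
                    pos_b = seq(0L, 4900L, by = 100L), k = 21L)
  expect_equal(nrow(chain_anchors(anc)), nrow(anc))
  # one wildly out-of-place anchor
  anc2 <- anc
  anc2$pos_b[25] <- 100000L
  ch <- chain_anchors(anc2)
  expect_equal(nrow(ch), 49L)
  expect_false(100000L %in% ch$pos_b)
})

test_that("chain cardinality matches the quadratic LIS oracle", {
  set.seed(103)
  for (rep in 1:40) {
    n <- sample(10:60, 1)
    anc <- data.frame(pos_a = sort(sample.int(10000L, n)) - 1L,
                      pos_b = sample.int(10000L, n) - 1L, k = 1L)
    ch <- chain_anchors(anc)
    expect_equal(nrow(ch), lis_len_oracle(anc$pos_b))
    expect_true(all(diff(ch$pos_a) > 0) && all(diff(ch$pos_b) > 0))
  }
})

test_that("gap alignment classifies the trivial cases", {
  g <- twindiff:::align_gap("", "GATTACA")
  expect_equal(g$frags$kind, "long_insert")
  expect_equal(g$frags$carrier, "b")
  expect_equal(g$frags$length, 7L)
  expect_equal(g$frags$alt, "GATTACA")

  g2 <- twindiff:::align_gap("A", "")
  expect_equal(g2$frags$kind, "indel_1bp")
  expect_equal(g2$frags$carrier, "a")

  g3 <- twindiff:::align_gap("ACGT", "AGGT")
  expect_equal(g3$frags$kind, "substitution")
  expect_equal(g3$frags$rel_a, 2L)
})

test_that("gap decomposition is score-optimal and reconstructs segment b", {
  set.seed(104)
  edit_lightly <- function(s) {
    cs <- chars(s)
    for (p in sample(length(cs), min(length(cs), sample(0:3, 1)))) {
      cs[p] <- sample(c("A", "C", "G", "T"), 1)
    }
    if (length(cs) > 2 && runif(1) < 0.5) cs <- cs[-sample(length(cs), 1)]
    if (runif(1) < 0.5) {
      at <- sample(length(cs), 1)
      cs <- append(cs, chars(rand_dna(sample(1:5, 1))), after = at)
    }
    paste(cs, collapse = "")
  }
  for (rep in 1:120) {
    la <- sample(0:40, 1)
    seg_a <- if (la) rand_dna(la) else ""
    seg_b <- if (runif(1) < 0.3 || la == 0) {
      if (runif(1) < 0.5 && la > 0) "" else rand_dna(sample(1:40, 1))
    } else {
      edit_lightly(seg_a)
    }
    g <- twindiff:::align_gap(seg_a, seg_b)
    expect_identical(apply_frags_oracle(seg_a, g$frags), seg_b)
    if (nchar(seg_a) > 0 && nchar(seg_b) > 0) {
      expect_equal(frag_score_oracle(g$frags, nchar(seg_a), nchar(seg_b)),
                   nw_score_oracle(seg_a, seg_b))
    }
  }
})

test_that("identical genomes diff to nothing", {
  set.seed(105)
  a <- genome_seq("s1", rand_dna(5000))
  d <- diff_genomes(a, genome_seq("s2", a$sequence))
  expect_equal(nrow(d$variants), 0L)
  expect_equal(d$aligned_identity, 100)
  expect_equal(unname(d$chain_coverage), c(1, 1))
})

test_that("wildly different genomes are rejected", {
  set.seed(106)
  expect_error(diff_genomes(rand_dna(5000), rand_dna(5000)),
               "not near-identical")
})

test_that("diff recovers implanted truth events at exact coordinates", {
  sim <- simulate_strain_pair(small_config(), seed = 23L)
  d <- diff_genomes(sim$genomes$strainA, sim$genomes$strainB)
  tr <- sim$truth[sim$truth$event_kind %in%
                    c("long_insert", "indel_1bp", "substitution"), ]
  expect_equal(nrow(d$variants), nrow(tr))
  v <- d$variants
  vk <- paste(v$kind, v$pos_a, v$pos_b,
              ifelse(v$kind == "substitution", v$alt,
                     ifelse(v$alt == "", v$ref, v$alt)))
  tk <- paste(ifelse(tr$length < 2 & tr$event_kind == "long_insert",
                     "indel_1bp", tr$event_kind),
              tr$pos_a, tr$pos_b, tr$sequence)
  expect_setequal(vk, tk)
})

test_that("applying the diff to genome A reconstructs genome B (fuzz)", {
  set.seed(107)
  for (rep in 1:20) {
    a <- rand_dna(3000)
    b <- mutate_oracle(a, n_sub = 3L, n_indel = 2L, n_ins = 2L,
                       ins_len = sample(10:120, 1))
    d <- diff_genomes(genome_seq("a", a), genome_seq("b", b))
    expect_identical(apply_variants(a, d$variants, "b"), b)
  }
})

test_that("diff is symmetric up to carrier relabelling", {
  set.seed(108)
  a <- rand_dna(4000)
  b <- mutate_oracle(a, n_sub = 2L, n_indel = 2L, n_ins = 2L, ins_len = 50L)
  d1 <- diff_genomes(genome_seq("a", a), genome_seq("b", b))
  d2 <- diff_genomes(genome_seq("b", b), genome_seq("a", a))
  v1 <- d1$variants
  v2 <- d2$variants
  expect_equal(nrow(v1), nrow(v2))
  k1 <- paste(v1$kind, v1$carrier, v1$pos_a, v1$pos_b, v1$ref, v1$alt)
  k2 <- paste(v2$kind, v2$carrier, v2$pos_b, v2$pos_a, v2$alt, v2$ref)
  expect_setequal(k1, k2)
})

test_that("adding one insert adds exactly one record, others untouched", {
  set.seed(109)
  a <- rand_dna(8000)
  b1 <- mutate_oracle(substr(a, 1, 4000), n_sub = 2L, n_indel = 1L,
                      n_ins = 1L, ins_len = 60L)
  b1 <- paste0(b1, substr(a, 4001, 8000))
  extra <- rand_dna(80)
  b2 <- paste0(substr(b1, 1, nchar(b1) - 2000), extra,
               substr(b1, nchar(b1) - 1999, nchar(b1)))
  d1 <- diff_genomes(genome_seq("a", a), genome_seq("b", b1))
  d2 <- diff_genomes(genome_seq("a", a), genome_seq("b", b2))
  expect_equal(nrow(d2$variants), nrow(d1$variants) + 1L)
  shared_rows <- d2$variants$pos_a <= 4000
  expect_equal(d2$variants[shared_rows, ], d1$variants, ignore_attr = TRUE)
})

test_that("aligned identity respects the variant-mass bound", {
  sim <- simulate_strain_pair(small_config(), seed = 31L)
  d <- diff_genomes(sim$genomes$strainA, sim$genomes$strainB)
  tot <- sum(d$variants$length)
  bound <- 100 * (1 - tot / nchar(sim$genomes$strainA$sequence))
  expect_gte(d$aligned_identity, bound - 1e-9)
})

test_that("circular genomes are rotated before diffing", {
  set.seed(110)
  a <- rand_dna(6000)
  b <- paste0(substr(a, 2001, 6000), substr(a, 1, 2000))  # rotation of a
  ga <- genome_seq("a", a, topology = "circular")
  gb <- genome_seq("b", b, topology = "circular")
  d <- diff_genomes(ga, gb, circular = TRUE)
  expect_equal(nrow(d$variants), 0L)
  expect_equal(d$rotation_b, 4000L)
})
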