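test_that("pairwise alignment matches the exhaustive DP oracle", {
  al <- align_pair("ACGT", "ACGT")
  expect_equal(al$aligned_x, "ACGT")
  expect_equal(al$aligned_y, "ACGT")
  expect_equal(al$score, 4L)

  al2 <- align_pair("ACGT", "ACT")
  expect_equal(nchar(al2$aligned_x), 4L)
  expect_equal(sum(chars(al2$aligned_y) == "-"), 1L)

  set.seed(201)
  for (rep in 1:100) {
    x <- rand_dna(sample(1:50, 1))
    y <- rand_dna(sample(1:50, 1))
    al <- align_pair(x, y)
    expect_equal(al$score, nw_score_oracle(x, y))
    # the reported alignment really has that score
    cx <- chars(al$aligned_x); cy <- chars(al$aligned_y)
    sc <- sum(ifelse(cx == "-" | cy == "-", -2, ifelse(cx == cy, 1, -1)))
    expect_equal(sc, al$score)
  }
})

test_that("p-distance follows the gap-exclusion rule", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)   # 3 compared, 0 mismatch
  expect_equal(p_distance("AC-T", "AGGT"), 1 / 3)
  expect_error(p_distance("---", "AC-"), "no gap-free columns")
  expect_error(p_distance("AC", "ACG"), "equal length")
})

test_that("p-distance is a metric on gap-free strings", {
  alph <- c("A", "C", "G")
  strs <- apply(expand.grid(alph, alph, alph), 1, paste, collapse = "")
  n <- length(strs)
  d <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) p_distance(strs[i], strs[j])))
  expect_identical(d, t(d))                      # symmetry
  expect_identical(d == 0, outer(strs, strs, `==`))  # identity
  # triangle inequality, checked over every (i, j, k) at once
  worst <- max(vapply(seq_len(n), function(k) {
    max(d - outer(d[, k], d[k, ], `+`))
  }, numeric(1)))
  expect_lte(worst, 1e-12)
})

test_that("single-linkage typing groups related inserts", {
  set.seed(202)
  s1 <- rand_dna(200)
  s2 <- rand_dna(180)
  seqs <- c(a = s1, b = s1, c = s1, d = s2, e = s2)
  ty <- cluster_inserts(seqs, 90)
  expect_equal(sort(table(ty$type_id), decreasing = TRUE),
               sort(table(c(1, 1, 1, 2, 2)), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(ty$type_id[1:3], rep(ty$type_id[1], 3))  # a,b,c together
  expect_equal(ty$type_id[ty$insert_id == "a"], 1L)     # biggest first
  expect_true(all(ty$within_type_min_identity == 100))

  # all-dissimilar limit: every insert its own type
  seqs2 <- setNames(replicate(4, rand_dna(150)), letters[1:4])
  ty2 <- cluster_inserts(seqs2, 95)
  expect_equal(length(unique(ty2$type_id)), 4L)

  # reverse-complement copies belong to the same family
  ty3 <- cluster_inserts(c(x = s1, y = rc_oracle(s1)), 90)
  expect_equal(ty3$type_id, c(1L, 1L))
})

test_that("typing is invariant to input order", {
  set.seed(203)
  s1 <- rand_dna(150); s2 <- rand_dna(150)
  seqs <- c(a = s1, b = s2, c = s1, d = s1, e = s2)
  ty <- cluster_inserts(seqs, 90)
  for (rep in 1:5) {
    perm <- sample(length(seqs))
    typ <- cluster_inserts(seqs[perm], 90)
    m1 <- setNames(ty$type_id, ty$insert_id)
    m2 <- setNames(typ$type_id, typ$insert_id)
    expect_equal(m1[names(m2)], m2)
  }
})

test_that("2- and 3-leaf NJ trees solve the closed-form equations", {
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- neighbor_joining(d2)
  expect_equal(sum(t2$edge.length), 0.3)

  d3 <- matrix(c(0, 0.4, 0.6,
                 0.4, 0, 0.8,
                 0.6, 0.8, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(d3)
  # three-point formulas
  want <- c(x = (0.4 + 0.6 - 0.8) / 2,
            y = (0.4 + 0.8 - 0.6) / 2,
            z = (0.6 + 0.8 - 0.4) / 2)
  got <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(got, want[names(got)])
})

test_that("NJ picks the least-squares topology on additive 4-leaf data", {
  set.seed(204)
  for (rep in 1:50) {
    tree <- ape::rtree(4, tip.label = c("t1", "t2", "t3", "t4"))
    d <- ape::cophenetic.phylo(tree)[c("t1", "t2", "t3", "t4"),
                                     c("t1", "t2", "t3", "t4")]
    nj <- neighbor_joining(d)
    rss <- vapply(1:3, function(i) ls_fit_4leaf(d, i), numeric(1))
    expect_equal(topo_index_4leaf(nj, c("t1", "t2", "t3", "t4")),
                 which.min(rss))
  }
})

test_that("NJ reconstructs random additive trees exactly", {
  set.seed(205)
  for (n in 4:10) {
    tree <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tree)
    nj <- neighbor_joining(d[tree$tip.label, tree$tip.label])
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(nj)), 0,
                 ignore_attr = TRUE)
    # path lengths reproduced
    expect_equal(ape::cophenetic.phylo(nj)[tree$tip.label, tree$tip.label],
                 d, tolerance = 1e-9)
    # independent implementation agrees on the topology
    expect_equal(ape::dist.topo(ape::unroot(ape::nj(d)), ape::unroot(nj)),
                 0, ignore_attr = TRUE)
  }
})

test_that("NJ rejects asymmetric input", {
  d <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(d), "not symmetric")
})

test_that("bootstrap saturates on clean splits and degenerate input", {
  set.seed(206)
  block <- function(ch, n) strrep(ch, n)
  # two clades: distance 0 within, ~0.5 between
  s1 <- paste0(block("A", 50), block("C", 50))
  s2 <- paste0(block("G", 50), block("C", 50))
  msa <- rbind(w = chars(s1), x = chars(s1), y = chars(s2), z = chars(s2))
  tr <- bootstrap_support(msa, n_replicates = 100, seed = 1)
  sup <- attr(tr, "support")
  expect_equal(nrow(sup), 1L)
  expect_equal(sup$support, 100)

  # identical sequences: supports defined as 100 by convention
  msa2 <- rbind(a = chars(s1), b = chars(s1), c = chars(s1),
                d = chars(s1))
  tr2 <- bootstrap_support(msa2, n_replicates = 50, seed = 1)
  expect_true(all(attr(tr2, "support")$support == 100))
})

test_that("bootstrap supports are stable across seeds", {
  set.seed(207)
  base <- rand_dna(400)
  mut <- function(s, k) {
    cs <- chars(s)
    idx <- sample(length(cs), k)
    cs[idx] <- vapply(cs[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(cs, collapse = "")
  }
  cladeA <- base
  cladeB <- mut(base, 120)
  seqs <- c(a1 = mut(cladeA, 4), a2 = mut(cladeA, 4), a3 = mut(cladeA, 4),
            a4 = mut(cladeA, 4), b1 = mut(cladeB, 4), b2 = mut(cladeB, 4),
            b3 = mut(cladeB, 4), b4 = mut(cladeB, 4))
  msa <- star_msa(seqs)
  t1 <- bootstrap_support(msa, 1000, seed = 11)
  t2 <- bootstrap_support(msa, 1000, seed = 99)
  s1 <- attr(t1, "support")
  s2 <- attr(t2, "support")
  shared <- intersect(s1$bipartition, s2$bipartition)
  expect_gt(length(shared), 0)
  expect_true(all(abs(s1$support[match(shared, s1$bipartition)] -
                        s2$support[match(shared, s2$bipartition)]) <= 5))
})

test_that("trees serialise to Newick and parse back isomorphic", {
  set.seed(208)
  tree <- ape::rtree(6)
  d <- ape::cophenetic.phylo(tree)
  nj <- neighbor_joining(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(nj, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(nj)), 0,
               ignore_attr = TRUE)
  expect_setequal(back$tip.label, nj$tip.label)
})
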