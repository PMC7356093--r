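## Neighbor-joining on p-distances, star-anchored multiple alignment, and
## bootstrap support for internal edges.

fmt_bl <- function(x) formatC(x, digits = 15, format = "g")

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical agglomerative neighbor joining: at each step the pair
#' minimising the Q-criterion
#' \eqn{Q_{ij} = (m-2) d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}} is joined and
#' pendant branch lengths follow the standard two-point formulas. Negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' sister branch, so path lengths are preserved. Q ties are broken on the
#' lexicographically smallest pair of representative labels (the smallest
#' leaf label in each cluster), making the result deterministic. On an
#' additive matrix the generating tree is recovered exactly.
#'
#' @param dm symmetric numeric matrix with zero diagonal; `rownames` are the
#'   leaf labels (>= 2 leaves).
#' @return an unrooted [ape] `phylo` tree (trifurcating root for n >= 3).
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 labels")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  diag(dm) <- 0
  if (n == 2L) {
    nwk <- sprintf("(%s:%s,%s:%s);", labels[1L], fmt_bl(dm[1L, 2L] / 2),
                   labels[2L], fmt_bl(dm[1L, 2L] / 2))
    return(ape::read.tree(text = nwk))
  }
  sub <- labels               # Newick subtree per active cluster
  rep_lab <- labels           # smallest leaf label per cluster
  D <- dm
  while (length(sub) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(r) {
      pair <- sort(c(rep_lab[cand[r, 1L]], rep_lab[cand[r, 2L]]))
      paste(pair, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1L], ]
    f <- pick[[1L]]
    g <- pick[[2L]]
    bf <- 0.5 * D[f, g] + (rs[f] - rs[g]) / (2 * (m - 2))
    bg <- D[f, g] - bf
    if (bf < 0) { bg <- bg + bf; bf <- 0 }
    if (bg < 0) { bf <- bf + bg; bg <- 0 }
    bf <- max(bf, 0)
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[f], fmt_bl(bf),
                       sub[g], fmt_bl(bg))
    new_rep <- min(rep_lab[f], rep_lab[g])
    others <- setdiff(seq_len(m), c(f, g))
    dnew <- 0.5 * (D[f, others] + D[g, others] - D[f, g])
    D <- rbind(cbind(D[others, others, drop = FALSE], dnew),
               c(dnew, 0))
    sub <- c(sub[others], new_sub)
    rep_lab <- c(rep_lab[others], new_rep)
  }
  # final three-point join
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  x <- max((d12 + d13 - d23) / 2, 0)
  y <- max((d12 + d23 - d13) / 2, 0)
  z <- max((d13 + d23 - d12) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1L], fmt_bl(x),
                 sub[2L], fmt_bl(y), sub[3L], fmt_bl(z))
  ape::read.tree(text = nwk)
}

#' Star-anchored multiple alignment
#'
#' Aligns every sequence to the longest member (ties: first) with
#' [align_pair()] and projects onto the reference columns, discarding
#' insertions relative to the reference. Crude but deterministic, and
#' adequate for the >97%-identical element families this package types;
#' used to feed the bootstrap.
#'
#' @param seqs named character vector (>= 2 sequences).
#' @return character matrix, one row per sequence, one column per reference
#'   position; gaps are `-`.
#' @export
star_msa <- function(seqs) {
  stopifnot(length(seqs) >= 2L)
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  ref_i <- which.max(nchar(seqs))
  ref <- seqs[[ref_i]]
  L <- nchar(ref)
  msa <- matrix("-", nrow = length(seqs), ncol = L,
                dimnames = list(ids, NULL))
  for (i in seq_along(seqs)) {
    if (i == ref_i) {
      msa[i, ] <- seq_chars(ref)
      next
    }
    al <- align_pair(ref, seqs[[i]])
    cr <- seq_chars(al$aligned_x)
    cs <- seq_chars(al$aligned_y)
    msa[i, ] <- cs[cr != "-"]
  }
  msa
}

## pairwise p-distance matrix from an MSA given per-column weights
## (bootstrap resampling is a multinomial reweighting of columns)
msa_pdist <- function(msa, w = NULL) {
  n <- nrow(msa)
  L <- ncol(msa)
  if (is.null(w)) w <- rep(1, L)
  d <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- msa[i, ] != "-" & msa[j, ] != "-"
      denom <- sum(w[ok])
      d[i, j] <- d[j, i] <-
        if (denom == 0) 0 else sum(w[ok & msa[i, ] != msa[j, ]]) / denom
    }
  }
  d
}

## canonical bipartition keys of a phylo tree's internal edges: for each
## non-root internal node, the tip set on its side of the edge, represented
## by the side not containing the alphabetically first tip
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character()
  for (i in seq_along(pp)) {
    if (i == 1L) next  # root: all tips
    side <- labs[pp[[i]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_replicates` times
#' (seeded), rebuilds the NJ tree on p-distances for each replicate, and
#' annotates each internal edge of the master tree with the percentage of
#' replicates whose tree contains the same bipartition. When every pairwise
#' distance is zero the topology carries no signal and supports are defined
#' as 100 by convention.
#'
#' @param msa character matrix from [star_msa()] (or any gapped alignment),
#'   >= 4 rows.
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed for column resampling.
#' @return the master `phylo` tree with `node.label` holding percent
#'   supports (root label empty) and attribute `"support"`: a data.frame of
#'   bipartition keys and supports.
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = 1L) {
  stopifnot(nrow(msa) >= 4L, ncol(msa) >= 1L)
  L <- ncol(msa)
  d0 <- msa_pdist(msa)
  master <- neighbor_joining(d0)
  keys <- tree_bipartitions(master)
  if (all(d0 == 0)) {
    support <- setNames(rep(100, length(keys)), keys)
  } else {
    counts <- setNames(rep(0L, length(keys)), keys)
    withr::with_seed(seed, {
      for (r in seq_len(n_replicates)) {
        w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
        bt <- neighbor_joining(msa_pdist(msa, w))
        hit <- keys %in% tree_bipartitions(bt)
        counts[hit] <- counts[hit] + 1L
      }
    })
    support <- 100 * counts / n_replicates
  }
  # attach supports as node labels
  ntip <- length(master$tip.label)
  labs <- character(master$Nnode)
  pp <- ape::prop.part(master)
  plabs <- attr(pp, "labels")
  tips <- sort(master$tip.label)
  anchor <- tips[1L]
  for (i in seq_along(pp)) {
    if (i == 1L) next
    side <- plabs[pp[[i]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      labs[i] <- formatC(support[[key]], format = "f", digits = 1)
    }
  }
  master$node.label <- labs
  attr(master, "support") <-
    data.frame(bipartition = names(support), support = unname(support),
               stringsAsFactors = FALSE)
  master
}
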