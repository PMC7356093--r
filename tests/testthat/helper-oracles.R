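# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (quadratic scans, full DP, explicit
# enumeration) and shares no code path with the package implementation.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

rc_oracle <- function(x) {
  paste(rev(chartr("ACGTN", "TGCAN", chars(x))), collapse = "")
}

## plain-R global alignment score (linear gaps, end gaps penalised)
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- chars(a); cb <- chars(b)
  n <- length(ca); m <- length(cb)
  prev <- (0:m) * gap
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i * gap
    for (j in seq_len(m)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      cur[j + 1] <- max(prev[j] + s, prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1]
}

## score implied by an align_gap() variant decomposition: matches +1,
## substitutions -1, each inserted base -2
frag_score_oracle <- function(frags, la, lb) {
  ins <- sum(frags$length[frags$kind != "substitution"])
  subs <- sum(frags$kind == "substitution")
  matched <- ((la + lb) - ins) / 2 - subs
  matched - subs - 2 * ins
}

## apply align_gap() fragments to seg_a, reconstructing seg_b (uses the
## fragment's segment-relative coordinates only)
apply_frags_oracle <- function(seg_a, frags) {
  pieces <- character(0)
  cursor <- 1L
  if (nrow(frags)) {
    frags <- frags[order(frags$rel_a, frags$rel_b), , drop = FALSE]
    for (i in seq_len(nrow(frags))) {
      f <- frags[i, ]
      if (f$kind == "substitution") {
        pieces <- c(pieces, substr(seg_a, cursor, f$rel_a - 1L), f$alt)
        cursor <- f$rel_a + 1L
      } else if (f$carrier == "b") {
        pieces <- c(pieces, substr(seg_a, cursor, f$rel_a), f$alt)
        cursor <- f$rel_a + 1L
      } else {
        pieces <- c(pieces, substr(seg_a, cursor, f$rel_a - 1L))
        cursor <- f$rel_a + f$length
      }
    }
  }
  paste(c(pieces, substr(seg_a, cursor, nchar(seg_a))), collapse = "")
}

## O(n^2) DP longest strictly-increasing subsequence length
lis_len_oracle <- function(x) {
  n <- length(x)
  if (n == 0L) return(0L)
  dp <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && dp[j] + 1L > dp[i]) dp[i] <- dp[j] + 1L
    }
  }
  max(dp)
}

## brute-force census: every (i, j) pair tested for the TIR pattern, then
## the same documented pairing rule (nearest downstream end, greedy
## shortest span, non-overlapping) applied with naive R code
naive_tir_scan <- function(genome, tir, wmin, wmax = Inf) {
  g <- chars(genome)
  tl <- nchar(tir)
  tc <- chars(tir)
  rtc <- chars(rc_oracle(tir))
  n <- length(g)
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(n - tl + 1L)) {
    if (all(g[i:(i + tl - 1L)] == tc)) starts <- c(starts, i)
    if (all(g[i:(i + tl - 1L)] == rtc)) ends <- c(ends, i + tl - 1L)
  }
  wmin <- max(wmin, 2L * tl)
  cand <- NULL
  for (s in starts) {
    ok <- ends[ends - s + 1L >= wmin]
    if (length(ok)) {
      e <- min(ok)
      if (e - s + 1L <= wmax) cand <- rbind(cand, c(s, e))
    }
  }
  if (is.null(cand)) return(cand)
  cand <- cand[order(cand[, 2] - cand[, 1], cand[, 1]), , drop = FALSE]
  kept <- NULL
  for (i in seq_len(nrow(cand))) {
    s <- cand[i, 1]; e <- cand[i, 2]
    clash <- FALSE
    if (!is.null(kept)) {
      clash <- any(s <= kept[, 2] & e >= kept[, 1])
    }
    if (!clash) kept <- rbind(kept, c(s, e))
  }
  kept[order(kept[, 1]), , drop = FALSE]
}

## least-squares fit of a 4-leaf unrooted topology to a distance matrix;
## topologies indexed by which leaf pairs are cherries: 1 = (12|34),
## 2 = (13|24), 3 = (14|23). Returns residual sum of squares.
ls_fit_4leaf <- function(d, topo) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  cherries <- switch(topo,
                     list(c(1, 2), c(3, 4)),
                     list(c(1, 3), c(2, 4)),
                     list(c(1, 4), c(2, 3)))
  # path indicator matrix over edges e1..e4 (pendant) and e5 (internal)
  X <- matrix(0, 6, 5)
  for (r in 1:6) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    X[r, i] <- 1
    X[r, j] <- 1
    same_cherry <- any(vapply(cherries, function(ch) all(c(i, j) %in% ch),
                              logical(1)))
    if (!same_cherry) X[r, 5] <- 1
  }
  y <- c(d[1, 2], d[1, 3], d[1, 4], d[2, 3], d[2, 4], d[3, 4])
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

## split of a 4-leaf unrooted tree as topology index (see ls_fit_4leaf)
topo_index_4leaf <- function(tree, labels) {
  bp <- ape::prop.part(ape::unroot(tree))
  for (i in seq_along(bp)) {
    side <- attr(bp, "labels")[bp[[i]]]
    if (length(side) == 2L) {
      pair <- sort(match(side, labels))
      if (all(pair == c(1, 2)) || all(pair == c(3, 4))) return(1L)
      if (all(pair == c(1, 3)) || all(pair == c(2, 4))) return(2L)
      return(3L)
    }
  }
  NA_integer_
}

## a small, fast simulation configuration for unit tests
small_config <- function(...) {
  sim_config(genome_length = 50000L, n_genes = 25L,
             n_differential = rbind(A = c(3L, 0L, 1L), B = c(1L, 2L, 1L)),
             n_shared = c(5L, 3L, 1L), n_full_shared = c(1L, 1L, 0L),
             ...)
}

## mutate genome a into a derived genome b, returning only b (independent
## of the package's variant machinery); inserts use fresh random sequence
mutate_oracle <- function(a, n_sub = 3L, n_indel = 2L, n_ins = 1L,
                          ins_len = 40L) {
  ca <- chars(a)
  n <- length(ca)
  pos <- sort(sample(seq(100L, n - 100L), n_sub + n_indel + n_ins))
  # keep events apart so edits stay independent
  while (any(diff(pos) < 60L)) {
    pos <- sort(sample(seq(100L, n - 100L), n_sub + n_indel + n_ins))
  }
  kinds <- sample(c(rep("sub", n_sub), rep("indel", n_indel),
                    rep("ins", n_ins)))
  out <- character(0)
  cursor <- 1L
  for (i in seq_along(pos)) {
    p <- pos[i]
    out <- c(out, ca[cursor:(p - 1L)])
    if (kinds[i] == "sub") {
      out <- c(out, sample(setdiff(c("A", "C", "G", "T"), ca[p]), 1L))
      cursor <- p + 1L
    } else if (kinds[i] == "indel") {
      if (runif(1) < 0.5) {
        out <- c(out, sample(c("A", "C", "G", "T"), 1L), ca[p])
      }  # else: delete ca[p]
      cursor <- p + 1L
    } else {
      out <- c(out, chars(rand_dna(ins_len)), ca[p])
      cursor <- p + 1L
    }
  }
  out <- c(out, ca[cursor:n])
  paste(out, collapse = "")
}
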