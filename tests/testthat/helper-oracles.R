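# Independently coded brute-force oracles and fixture builders.  These stay
# deliberately naive (double loops, direct textbook formulas) so they share
# no code path with the implementation they check.

random_calls <- function(n_hap, n_site, seed, missing_rate = 0) {
  withr::with_seed(seed, {
    calls <- matrix(sample(0:1, n_hap * n_site, replace = TRUE), n_hap, n_site)
    if (missing_rate > 0) {
      calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
    }
    # keep at least one segregating site
    if (all(colSums(calls, na.rm = TRUE) %in% c(0, n_hap))) calls[1, 1] <- 1L
    calls
  })
}

random_gm <- function(n_hap, n_site, seed, missing_rate = 0, chrom = "1") {
  calls <- random_calls(n_hap, n_site, seed, missing_rate)
  genotype_matrix(calls, sprintf("s%03d", seq_len(n_hap)),
                  rep(chrom, n_site), seq_len(n_site) * 10L)
}

# mean pairwise Hamming distance / span over all C(n,2) pairs (complete data)
oracle_pi <- function(calls, span) {
  n <- nrow(calls); tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(calls[i, ] != calls[j, ])
    np <- np + 1
  }
  tot / np / span
}

oracle_watterson <- function(calls) {
  n <- nrow(calls)
  S <- sum(apply(calls, 2, function(x) length(unique(x)) == 2))
  S / sum(1 / seq_len(n - 1))
}

# direct-formula Tajima's D (1989), constants recomputed from scratch
oracle_tajimas_d <- function(calls) {
  n <- nrow(calls)
  seg <- apply(calls, 2, function(x) length(unique(x)) == 2)
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pi_tot <- pi_tot + sum(calls[i, ] != calls[j, ])
  }
  pi_hat <- pi_tot / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# haploid Weir-Cockerham variance components, written out long-hand
oracle_fst_wc <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  r <- 2
  nbar_tot <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / nbar_tot
  msb <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nbar_tot - r)
  nc <- (nbar_tot - (n1^2 + n2^2) / nbar_tot) / (r - 1)
  a <- (msb - msw) / nc
  list(a = a, b = msw, fst = a / (a + msw))
}

# r^2 via haplotype frequencies: D^2 / (p (1-p) q (1-q))
oracle_r2 <- function(x, y) {
  pAB <- mean(x == 1 & y == 1)
  pA <- mean(x == 1); pB <- mean(y == 1)
  Dld <- pAB - pA * pB
  Dld^2 / (pA * (1 - pA) * pB * (1 - pB))
}

oracle_jc69 <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  p <- sum(av != bv) / length(av)
  if (p >= 0.75) return(NA_real_)
  -3 / 4 * log(1 - 4 * p / 3)
}

# the missingness -> MAF -> windowed greedy LD pruning cascade, re-done naively
oracle_filter <- function(calls, maf_min, r2_max, missing_max, win = 50L) {
  n <- nrow(calls)
  keep <- c()
  for (j in seq_len(ncol(calls))) {
    x <- calls[, j]
    if (sum(is.na(x)) / n >= missing_max) next
    p <- mean(x, na.rm = TRUE)
    if (min(p, 1 - p) <= maf_min) next
    keep <- c(keep, j)
  }
  retained <- c()
  for (pos_j in seq_along(keep)) {
    j <- keep[pos_j]
    drop <- FALSE
    for (pos_i in seq_along(retained)) {
      i <- retained[pos_i]
      ii <- match(i, keep); jj <- pos_j
      if (jj - ii >= win) next
      x <- calls[, i]; y <- calls[, j]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) next
      if (stats::cor(x[ok], y[ok])^2 >= r2_max) { drop <- TRUE; break }
    }
    if (!drop) retained <- c(retained, j)
  }
  retained
}

# random unrooted tree with positive branch lengths -> additive matrix
random_additive <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
    list(tree = tr, D = ape::cophenetic.phylo(tr))
  })
}
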