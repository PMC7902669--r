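#' Per-sample SNP vectors over one locus
#'
#' A [genotype_matrix()] restricted to a single locus, together with the
#' locus span (0-based half-open) used as the diversity denominator.
#'
#' @param matrix a [genotype_matrix()] whose sites all fall inside the span.
#' @param chrom,start,end locus span, 0-based half-open.
#' @return a `locus_haplotype_set`.
#' @export
locus_haplotype_set <- function(matrix, chrom, start, end) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (end <= start) stop("locus end must be > start")
  if (length(matrix$pos) &&
      (any(matrix$chrom != chrom) ||
       any(matrix$pos - 1L < start) || any(matrix$pos - 1L >= end))) {
    stop("all variant sites must lie inside the locus span")
  }
  structure(list(matrix = matrix, chrom = chrom, start = start, end = end,
                 sample_ids = matrix$sample_ids),
            class = "locus_haplotype_set")
}

#' @export
print.locus_haplotype_set <- function(x, ...) {
  cat(sprintf("<locus_haplotype_set> %s:%d-%d (%d bp), %d samples, %d SNPs\n",
              x$chrom, x$start, x$end, x$end - x$start,
              length(x$sample_ids), ncol(x$matrix$calls)))
  invisible(x)
}

#' Pairwise SNP-count distance matrix
#'
#' Distance between two samples is the number of sites at which they differ,
#' counted over pairwise-complete (both non-missing) positions.  A pair with
#' zero shared called sites gets `NA` and is reported with a warning.
#'
#' @param locus a [locus_haplotype_set()] (or a [genotype_matrix()]).
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
snp_distance_matrix <- function(locus) {
  gm <- if (inherits(locus, "locus_haplotype_set")) locus$matrix else locus
  if (nrow(gm$calls) < 2L) stop("at least 2 samples required")
  M <- (!is.na(gm$calls)) * 1
  X <- gm$calls; X[is.na(X)] <- 0L
  storage.mode(X) <- "double"
  P <- X %*% t(M)                  # P_ij = sum_s x_is * m_js
  Q <- X %*% t(X)
  d <- P + t(P) - 2 * Q
  shared <- M %*% t(M)
  if (any(shared == 0 & upper.tri(shared))) {
    warning("some sample pairs share no called sites; distances set to NA")
    d[shared == 0] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(gm$sample_ids, gm$sample_ids)
  d
}

#' K-means haplotype-group assignment
#'
#' Lloyd's algorithm on the raw 0/1 SNP vectors (missing calls imputed to the
#' site mean for clustering only), best of `n_init` seeded restarts by total
#' within-cluster sum of squares.  To make the partition invariant to input
#' sample order, rows are put in a canonical (lexicographic-by-content) order
#' before clustering.  Returned labels are canonicalized by cluster size,
#' largest group = 1 (ties broken by earliest canonical sample).
#'
#' @param locus a [locus_haplotype_set()] (or a [genotype_matrix()]).
#' @param k number of groups (2 <= k <= samples).
#' @param seed integer seed for the restarts.
#' @param n_init number of random restarts (default 10).
#' @return integer vector of group labels named by sample id.
#' @export
kmeans_haplotype_groups <- function(locus, k = 2L, seed = 1L, n_init = 10L) {
  gm <- if (inherits(locus, "locus_haplotype_set")) locus$matrix else locus
  n <- nrow(gm$calls)
  if (k > n) stop("k cannot exceed the number of samples")
  if (k < 2L) stop("k must be >= 2")
  X <- gm$calls
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    for (j in which(colSums(is.na(X)) > 0L)) X[is.na(X[, j]), j] <- mu[j]
  }
  ord <- do.call(order, c(as.data.frame(X), list(gm$sample_ids)))
  fit <- with_seed(seed, {
    stats::kmeans(X[ord, , drop = FALSE], centers = k, nstart = n_init,
                  algorithm = "Lloyd", iter.max = 200L)
  })
  cl <- integer(n)
  cl[ord] <- fit$cluster
  sizes <- tabulate(cl, k)
  first_seen <- vapply(seq_len(k), function(g) min(which(fit$cluster == g)), 0L)
  rank <- order(-sizes, first_seen)
  relabel <- integer(k); relabel[rank] <- seq_len(k)
  stats::setNames(relabel[cl], gm$sample_ids)
}

#' Per-group nucleotide diversity at a locus
#'
#' Delegates to [nucleotide_diversity()] on each group's haplotypes over the
#' locus span.  Groups with fewer than two samples get `NA`.
#'
#' @param locus a [locus_haplotype_set()].
#' @param labels group labels named by sample id (e.g. from
#'   [kmeans_haplotype_groups()]).
#' @param span_bp diversity denominator; default: the locus span length.
#' @return named numeric vector of per-site pi, one entry per group.
#' @export
per_group_diversity <- function(locus, labels, span_bp = NULL) {
  stopifnot(inherits(locus, "locus_haplotype_set"))
  span_bp <- span_bp %||% (locus$end - locus$start)
  groups <- sort(unique(labels))
  out <- stats::setNames(rep(NA_real_, length(groups)), as.character(groups))
  for (g in groups) {
    ids <- names(labels)[labels == g]
    if (length(ids) >= 2L) {
      out[as.character(g)] <- nucleotide_diversity(locus$matrix, samples = ids,
                                                   span_bp = span_bp)
    }
  }
  out
}

#' Jukes-Cantor (JC69) distance between two aligned sequences
#'
#' `d = -(3/4) * log(1 - (4/3) * p)` with `p` the proportion of differing
#' sites over pairwise-complete positions (positions where either sequence
#' has a non-ACGT character, e.g. `N` or `-`, are excluded).
#'
#' @param seq_a,seq_b equal-length character strings (or character vectors of
#'   single bases).
#' @return substitutions per site; `NA` when `p >= 3/4` (saturated).
#' @export
jc69_distance <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1]] else toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1]] else toupper(seq_b)
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no pairwise-complete sites")
  p <- mean(a[ok] != b[ok])
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard neighbor joining with the Q-criterion
#' `Q_ij = (n - 2) d_ij - r_i - r_j`.  Ties in Q are resolved by the
#' lexicographically smallest pair of node labels, so reconstruction is
#' deterministic.  Negative branch lengths are clamped to zero with the
#' deficit moved to the sister branch (path lengths through the joined pair
#' are conserved).  When `outgroup` is given, the returned tree is rooted at
#' the midpoint of the outgroup's terminal edge; otherwise it is unrooted.
#'
#' @param dist complete symmetric distance matrix with unique dimnames
#'   (>= 3 taxa).
#' @param outgroup optional leaf label to root on.
#' @return an `ape::phylo` tree.
#' @export
neighbor_joining <- function(dist, outgroup = NULL) {
  D <- as.matrix(dist)
  n0 <- nrow(D)
  if (n0 < 3L) stop("at least 3 taxa required")
  if (anyNA(D)) stop("distance matrix must be complete")
  labs <- rownames(D) %||% paste0("t", seq_len(n0))
  if (anyDuplicated(labs)) stop("leaf labels must be unique")
  # working node ids: 1..n0 leaves, then internal nodes n0+1, ...
  ids <- seq_len(n0)
  node_lab <- labs                       # label used for tie-breaking
  edges <- list()                        # (parent, child, length)
  next_id <- n0 + 1L
  while (length(ids) > 3L) {
    n <- length(ids)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(z) {
      p <- sort(c(node_lab[cand[z, 1]], node_lab[cand[z, 2]]))
      paste(p, collapse = "\r")
    }, "")
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    u <- next_id; next_id <- next_id + 1L
    edges[[length(edges) + 1L]] <- c(u, ids[i], bi)
    edges[[length(edges) + 1L]] <- c(u, ids[j], bj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    ids <- c(ids[keep], u)
    node_lab <- c(node_lab[keep],
                  paste(sort(c(node_lab[i], node_lab[j])), collapse = "\r"))
  }
  # final star join of the last three nodes
  u <- next_id
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (z in 1:3) {
    edges[[length(edges) + 1L]] <- c(u, ids[z], max(c(b1, b2, b3)[z], 0))
  }
  em <- do.call(rbind, edges)
  n_internal <- max(em[, 1]) - n0
  # renumber internal nodes so the (star) root is n0 + 1, as ape expects
  remap <- c(seq_len(n0), rep(NA_integer_, n_internal))
  remap[u] <- n0 + 1L
  others <- setdiff((n0 + 1L):max(em[, 1]), u)
  remap[others] <- n0 + 1L + seq_along(others)
  phy <- structure(list(edge = cbind(remap[em[, 1]], remap[em[, 2]]),
                        edge.length = em[, 3],
                        tip.label = labs, Nnode = n_internal),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  if (!is.null(outgroup)) {
    if (!outgroup %in% labs) stop(sprintf("outgroup '%s' not among leaves", outgroup))
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
    # place the root at the midpoint of the outgroup's terminal edge
    root <- ape::Ntip(phy) + 1L
    og_tip <- match(outgroup, phy$tip.label)
    e_og <- which(phy$edge[, 1] == root & phy$edge[, 2] == og_tip)
    e_other <- which(phy$edge[, 1] == root & phy$edge[, 2] != og_tip)
    if (length(e_og) == 1L && length(e_other) == 1L) {
      half <- phy$edge.length[e_og] / 2
      phy$edge.length[e_og] <- half
      phy$edge.length[e_other] <- phy$edge.length[e_other] + half
    }
  }
  phy
}
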