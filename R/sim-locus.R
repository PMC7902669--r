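#' Simulate a locus carrying two divergent haplotype groups
#'
#' Emulates the structure seen at a starch-pathway locus in maize panels:
#' two haplotype groups whose consensus sequences differ at exactly `n_diff`
#' uniformly placed SNPs, with unequal within-group diversity.  Each sampled
#' haplotype mutates off its group consensus independently at a per-site
#' rate (`div1` / `div2`), so the expected within-group pairwise diversity is
#' about `2 * div * (1 - div)` per site and each haplotype carries about
#' `div * locus_len` private SNPs.
#'
#' Defaults mirror the emulated design: 114 vs 1065 samples, 165
#' differentiating SNPs over an 11,598 bp locus, group 1 (the minor,
#' "sweet"-type group) more diverse than group 2.  The reference allele is
#' the group-2 consensus, so group-1 haplotypes carry the derived allele at
#' every differentiating site.
#'
#' @param n1,n2 samples in group 1 / group 2 (each >= 2).
#' @param n_diff number of differentiating SNPs (`<= locus_len`).
#' @param div1,div2 within-group per-site mutation rate off the consensus.
#' @param locus_len locus length in bp.
#' @param seed integer seed.
#' @return list with `locus` (a `locus_haplotype_set`) and `truth`
#'   (a [sim_truth()] with `group_labels`).
#' @export
simulate_haplotype_groups <- function(n1 = 114L, n2 = 1065L, n_diff = 165L,
                                      div1 = 4.6e-4, div2 = 1.2e-4,
                                      locus_len = 11598L, seed = 1L) {
  if (n1 < 2L || n2 < 2L) stop("n1 and n2 must each be >= 2")
  if (n_diff > locus_len) stop("n_diff cannot exceed locus_len")
  stopifnot_scalar(div1, "div1", 0, 1)
  stopifnot_scalar(div2, "div2", 0, 1)
  n <- n1 + n2
  with_seed(seed, {
    diff_pos <- sort(sample.int(locus_len, n_diff))
    # private mutations per haplotype, anywhere on the locus
    events <- lapply(seq_len(n), function(i) {
      rate <- if (i <= n1) div1 else div2
      nm <- stats::rbinom(1L, locus_len, rate)
      if (nm > 0L) sample.int(locus_len, nm) else integer(0)
    })
    var_pos <- sort(unique(c(diff_pos, unlist(events))))
    calls <- matrix(0L, n, length(var_pos))
    calls[seq_len(n1), match(diff_pos, var_pos)] <- 1L   # group-1 consensus
    for (i in seq_len(n)) {
      j <- match(events[[i]], var_pos)
      calls[i, j] <- 1L - calls[i, j]
    }
    seg <- colSums(calls)
    keep <- seg > 0L & seg < n
    ids <- c(sprintf("g1_%04d", seq_len(n1)), sprintf("g2_%04d", seq_len(n2)))
    gm <- genotype_matrix(calls[, keep, drop = FALSE], ids,
                          chrom = rep("locus", sum(keep)),
                          pos = var_pos[keep])
    locus <- locus_haplotype_set(gm, chrom = "locus", start = 0,
                                 end = locus_len)
    labels <- stats::setNames(rep(c(1L, 2L), c(n1, n2)), ids)
    list(locus = locus, truth = sim_truth(group_labels = labels))
  })
}
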