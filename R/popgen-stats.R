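#' Per-site derived-allele counts for a set of haplotypes
#'
#' For each site, the derived (alt) allele count `k` and the number of
#' non-missing haplotype calls `n` in the chosen subset.  These (k, n) pairs
#' are the sufficient statistics consumed by the FST estimator and the
#' XP-CLR scan.
#'
#' @param matrix a [genotype_matrix()].
#' @param samples haplotype ids or indices (default: all).
#' @return data.frame with columns `chrom`, `pos`, `k`, `n`.
#' @export
site_counts <- function(matrix, samples = NULL) {
  sub <- subset_matrix(matrix, samples = samples)
  cc <- sub$calls
  data.frame(chrom = sub$chrom, pos = sub$pos,
             k = colSums(cc == 1L, na.rm = TRUE),
             n = colSums(!is.na(cc)),
             stringsAsFactors = FALSE)
}

#' Nucleotide diversity (pi) per site
#'
#' Mean pairwise difference per pair per site,
#' `sum_sites 2 k (n - k) / (n (n - 1)) / span_bp`, pairwise-complete over
#' non-missing calls (per-site `n` is the called-haplotype count).
#'
#' @param matrix a [genotype_matrix()].
#' @param samples haplotype subset (default all).
#' @param span_bp total length in bp of the region the sites were called in
#'   (monomorphic positions contribute zero differences but are part of the
#'   denominator).
#' @return per-site pi, or `NA` when `span_bp <= 0` or every site is fully
#'   missing in the subset.
#' @examples
#' gm <- genotype_matrix(rbind(rep(0L, 100), c(rep(1L, 3), rep(0L, 97))),
#'                       c("a", "b"), rep("1", 100), 1:100)
#' nucleotide_diversity(gm, span_bp = 100)  # 0.03
#' @export
nucleotide_diversity <- function(matrix, samples = NULL, span_bp) {
  sub <- subset_matrix(matrix, samples = samples)
  if (nrow(sub$calls) < 2L) stop("at least 2 haplotypes required")
  if (!is.numeric(span_bp) || length(span_bp) != 1L || is.na(span_bp) ||
      span_bp <= 0) {
    return(NA_real_)
  }
  if (ncol(sub$calls) == 0L) return(0)
  k <- colSums(sub$calls == 1L, na.rm = TRUE)
  n <- colSums(!is.na(sub$calls))
  if (all(n == 0L)) return(NA_real_)
  ok <- n >= 2L
  sum(2 * k[ok] * (n[ok] - k[ok]) / (n[ok] * (n[ok] - 1))) / span_bp
}

# Tajima (1989) normalizing constants for sample size n.
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Standard Tajima (1989) D contrasting mean pairwise diversity with the
#' segregating-sites estimator of theta.  Sites are counted as segregating
#' when both alleles are observed among non-missing calls; per-site pairwise
#' differences are pairwise-complete; the normalizing constants use the
#' nominal subset size n.
#'
#' @inheritParams nucleotide_diversity
#' @return D, or `NA` when there are no segregating sites (S = 0).
#' @export
tajimas_d <- function(matrix, samples = NULL) {
  sub <- subset_matrix(matrix, samples = samples)
  n <- nrow(sub$calls)
  if (n < 2L) stop("at least 2 haplotypes required")
  if (ncol(sub$calls) == 0L) return(NA_real_)
  k <- colSums(sub$calls == 1L, na.rm = TRUE)
  nn <- colSums(!is.na(sub$calls))
  seg <- nn >= 2L & k > 0L & k < nn
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  pi_hat <- sum(2 * k[seg] * (nn[seg] - k[seg]) / (nn[seg] * (nn[seg] - 1)))
  cst <- tajima_constants(n)
  vr <- cst$e1 * S + cst$e2 * S * (S - 1)
  if (vr <= 0) return(NA_real_)
  (pi_hat - S / cst$a1) / sqrt(vr)
}

#' Weir-Cockerham fixation index for two populations (haploid)
#'
#' Haploid analysis-of-variance estimator of FST in the Weir-Cockerham
#' framework: per site, the among-population component
#' `a = (MSB - MSW) / n_c` and the within-population component `b = MSW`,
#' where `MSB = sum n_i (p_i - p_bar)^2 / (r - 1)`,
#' `MSW = sum n_i p_i (1 - p_i) / (sum n_i - r)` and
#' `n_c = (sum n_i - sum n_i^2 / sum n_i) / (r - 1)` with r = 2.
#' The per-site estimate is `a / (a + b)`; the multi-locus estimate is the
#' ratio of sums `sum(a) / sum(a + b)` (standard Weir-Cockerham practice);
#' the mean of per-site values is also reported.  There is no heterozygosity
#' component: calls are haplotypes (inbred lines / haploid-split genotypes).
#'
#' Sites monomorphic across both populations, or with fewer than two called
#' haplotypes in either population, are excluded.  Values are reported as
#' computed (no clamping), so slightly negative estimates occur when there is
#' no differentiation beyond sampling.
#'
#' @param counts_ref,counts_query per-population [site_counts()] data frames
#'   over the same sites (matched by chrom and pos).
#' @return list with `per_site` (data.frame: chrom, pos, a, b, fst),
#'   `fst` (ratio-of-sums), `fst_mean` (mean of per-site values),
#'   `n_sites_used`.
#' @export
fst_weir_cockerham <- function(counts_ref, counts_query) {
  if (nrow(counts_ref) != nrow(counts_query) ||
      !all(counts_ref$chrom == counts_query$chrom) ||
      !all(counts_ref$pos == counts_query$pos)) {
    stop("counts_ref and counts_query must cover the same sites in order")
  }
  k1 <- counts_ref$k; n1 <- counts_ref$n
  k2 <- counts_query$k; n2 <- counts_query$n
  use <- n1 >= 2L & n2 >= 2L & (k1 + k2) > 0L & (k1 + k2) < (n1 + n2)
  if (!any(use)) {
    return(list(per_site = data.frame(chrom = character(0), pos = integer(0),
                                      a = numeric(0), b = numeric(0),
                                      fst = numeric(0)),
                fst = NA_real_, fst_mean = NA_real_, n_sites_used = 0L))
  }
  k1 <- k1[use]; n1 <- n1[use]; k2 <- k2[use]; n2 <- n2[use]
  p1 <- k1 / n1; p2 <- k2 / n2
  ntot <- n1 + n2
  pbar <- (k1 + k2) / ntot
  msb <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # r - 1 = 1
  msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (ntot - 2)
  nc <- ntot - (n1^2 + n2^2) / ntot
  a <- (msb - msw) / nc
  b <- msw
  denom <- a + b
  fst_site <- ifelse(denom == 0, NA_real_, a / denom)
  list(per_site = data.frame(chrom = counts_ref$chrom[use],
                             pos = counts_ref$pos[use],
                             a = a, b = b, fst = fst_site,
                             stringsAsFactors = FALSE),
       fst = sum(a) / sum(denom),
       fst_mean = mean(fst_site, na.rm = TRUE),
       n_sites_used = sum(use))
}

#' Linkage disequilibrium r-squared between two sites
#'
#' Squared Pearson correlation of the 0/1 haplotype vectors over
#' pairwise-complete haplotypes.
#'
#' @param matrix a [genotype_matrix()].
#' @param site_i,site_j site indices (columns).
#' @param samples haplotype subset (default all).
#' @return r^2 in \[0, 1\], or `NA` when either site is monomorphic among the
#'   shared called haplotypes.
#' @export
ld_r2 <- function(matrix, site_i, site_j, samples = NULL) {
  sub <- subset_matrix(matrix, samples = samples)
  x <- sub$calls[, site_i]; y <- sub$calls[, site_j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::var(x) == 0 || stats::var(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

# r^2 matrix for a set of columns, pairwise-complete; NA for monomorphic.
ld_r2_matrix <- function(calls) {
  suppressWarnings(stats::cor(calls, use = "pairwise.complete.obs")^2)
}

#' Variant filtering: missingness, minor allele frequency, LD pruning
#'
#' Applies, in order: (1) per-site missingness strictly below `missing_max`;
#' (2) minor allele frequency strictly above `maf_min` (frequency over called
#' haplotypes); (3) greedy left-to-right LD pruning within a sliding
#' `ld_window`-SNP window, dropping the right member of any pair whose r^2
#' (with an already-retained left member) is `>= r2_max`.  Inequality
#' strictness follows the retained-variant description: missing < 30%,
#' MAF > 0.1, retained r^2 < 0.2.
#'
#' @param matrix a [genotype_matrix()].
#' @param maf_min minor-allele-frequency threshold (retain MAF > maf_min).
#' @param r2_max LD threshold (drop right member at r^2 >= r2_max).
#' @param missing_max missingness threshold (retain missing < missing_max).
#' @param ld_window pruning window in SNPs (pairs at most this far apart in
#'   the post-MAF site ordering are tested); default 50.
#' @param samples haplotype subset used to compute the filters (default all);
#'   the returned matrix keeps all haplotypes.
#' @return filtered [genotype_matrix()].
#' @export
filter_variants <- function(matrix, maf_min = 0.1, r2_max = 0.2,
                            missing_max = 0.3, ld_window = 50L,
                            samples = NULL) {
  stopifnot_scalar(maf_min, "maf_min", 0, 1)
  stopifnot_scalar(r2_max, "r2_max", 0, 1)
  stopifnot_scalar(missing_max, "missing_max", 0, 1)
  sub <- subset_matrix(matrix, samples = samples)
  cc <- sub$calls
  n_hap <- nrow(cc)
  miss <- colSums(is.na(cc)) / n_hap
  keep1 <- miss < missing_max
  k <- colSums(cc == 1L, na.rm = TRUE)
  n <- colSums(!is.na(cc))
  p <- ifelse(n > 0, k / n, 0)
  maf <- pmin(p, 1 - p)
  keep2 <- keep1 & maf > maf_min
  idx <- which(keep2)
  # greedy LD pruning on the surviving, position-ordered sites
  retained <- logical(length(idx))
  for (jj in seq_along(idx)) {
    lo <- max(1L, jj - as.integer(ld_window) + 1L)
    prev <- which(retained[lo:(jj - 1L)]) + lo - 1L
    drop <- FALSE
    if (jj > 1L && length(prev)) {
      for (ii in prev) {
        r2 <- ld_r2(sub, idx[ii], idx[jj])
        if (!is.na(r2) && r2 >= r2_max) { drop <- TRUE; break }
      }
    }
    retained[jj] <- !drop
  }
  subset_matrix(matrix, sites = idx[retained])
}

#' Sliding-window statistic track
#'
#' Tiles each chromosome with windows `[0, w), [step, step + w), ...`
#' (0-based half-open; a final shorter terminal window covers any remainder),
#' assigns SNPs to windows by position, and computes the chosen statistic per
#' window.  Windows with no usable SNPs get `NA` values and `n_snps = 0`.
#'
#' @param matrix a [genotype_matrix()].
#' @param populations a [population_spec()]; required for `"fst"`, optional
#'   for `"pi"` / `"tajimas_d"` (with `pop` selecting the population).
#' @param stat one of `"pi"`, `"tajimas_d"`, `"fst"`.
#' @param window_size,step window and step in bp (`window_size >= step > 0`).
#' @param pop population label used for `"pi"`/`"tajimas_d"` (default: all
#'   samples).
#' @param pops length-2 character vector (reference, query) for `"fst"`
#'   (ratio-of-sums within each window).
#' @param chrom_len named numeric vector of chromosome lengths; defaults to
#'   the last SNP position per chromosome.
#' @return a `window_stat_track`: data.frame with columns `chrom`, `start`,
#'   `end`, `n_snps`, `value`, plus attributes `stat`, `window_size`, `step`.
#' @export
windowed_stat <- function(matrix, populations = NULL,
                          stat = c("pi", "tajimas_d", "fst"),
                          window_size, step = window_size,
                          pop = NULL, pops = NULL, chrom_len = NULL) {
  stat <- match.arg(stat)
  if (!(window_size >= step && step > 0)) stop("need window_size >= step > 0")
  samples <- NULL
  if (!is.null(pop)) samples <- pop_samples(populations, pop, matrix)
  if (stat == "fst") {
    if (is.null(populations) || length(pops) != 2L) {
      stop("stat = 'fst' needs 'populations' and two labels in 'pops'")
    }
    s1 <- pop_samples(populations, pops[1], matrix)
    s2 <- pop_samples(populations, pops[2], matrix)
  }
  chroms <- unique(matrix$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    cc <- chroms[ci]
    on_chr <- which(matrix$chrom == cc)
    clen <- if (!is.null(chrom_len) && cc %in% names(chrom_len)) {
      as.numeric(chrom_len[[cc]])
    } else {
      max(matrix$pos[on_chr])
    }
    starts <- tile_starts(clen, window_size, step)
    ends <- pmin(starts + window_size, clen)
    rows <- data.frame(chrom = cc, start = starts, end = ends,
                       n_snps = 0L, value = NA_real_,
                       stringsAsFactors = FALSE)
    pos0 <- matrix$pos[on_chr] - 1L                # 0-based for half-open test
    for (wi in seq_along(starts)) {
      sel <- on_chr[pos0 >= starts[wi] & pos0 < ends[wi]]
      rows$n_snps[wi] <- length(sel)
      if (!length(sel)) next
      wm <- subset_matrix(matrix, sites = sel)
      rows$value[wi] <- switch(stat,
        pi = nucleotide_diversity(wm, samples = samples,
                                  span_bp = ends[wi] - starts[wi]),
        tajimas_d = tajimas_d(wm, samples = samples),
        fst = fst_weir_cockerham(site_counts(wm, s1), site_counts(wm, s2))$fst)
    }
    out[[ci]] <- rows
  }
  track <- do.call(rbind, out)
  attr(track, "stat") <- stat
  attr(track, "window_size") <- window_size
  attr(track, "step") <- step
  class(track) <- c("window_stat_track", "data.frame")
  track
}

# Window start coordinates covering [0, chrom_len): multiples of `step` up to
# chrom_len - window, plus one terminal (shorter) window if needed.
tile_starts <- function(chrom_len, window, step) {
  if (chrom_len <= window) return(0)
  last_full <- floor((chrom_len - window) / step) * step
  starts <- seq(0, last_full, by = step)
  if (last_full + window < chrom_len) starts <- c(starts, last_full + step)
  starts
}

#' Write / read a window statistic track as TSV
#'
#' Five tab-separated columns (`chrom`, `start`, `end`, `n_snps`, `value`)
#' with a header; 0-based half-open coordinates, so the first three columns
#' are BED-compatible.
#'
#' @param track a `window_stat_track` (or compatible data.frame).
#' @param path file path.
#' @export
write_track <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("chrom", "start", "end",
                                              "n_snps", "value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "integer", "numeric"))
  class(df) <- c("window_stat_track", "data.frame")
  df
}
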