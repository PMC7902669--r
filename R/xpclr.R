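#' Configuration of the XP-CLR selective-sweep scan
#'
#' Defaults follow the scan settings used for maize GBS panels: 50 kb sliding
#' windows with a 100 bp step, at most 50 SNPs per window (seeded uniform
#' subsampling above that), and LD down-weighting of SNP clusters whose
#' reference-population r-squared reaches 0.7.
#'
#' The composite-likelihood model itself (see [xpclr_window_score()]) is a
#' self-contained deterministic-hitchhiking + censored-normal-drift
#' formulation; `ne` (effective population size of the query) and `rec_rate`
#' (Morgans per bp; default 1 cM/Mb) convert physical distance into the
#' hitchhiking escape probability.  `sel_grid` must contain 0 so the neutral
#' model is nested and scores are non-negative.
#'
#' @param window_size,step sliding window and step in bp.
#' @param max_snps cap on SNPs per window.
#' @param r2_weight_threshold reference-population r-squared at or above
#'   which two SNPs share weight.
#' @param sel_grid ordered selection-coefficient grid including 0 (default
#'   `{0}` plus 10 log-spaced points in `[1e-4, 0.5]`).
#' @param omega genome-wide drift variance scale; estimated from the data
#'   ([estimate_omega()]) when `NULL`.
#' @param rec_rate Morgans per bp.
#' @param ne effective size of the query population.
#' @param n_quad fixed quadrature nodes on \[0, 1\] (midpoint rule).
#' @param seed seed for the SNP-cap subsampling.
#' @return an `xpclr_config` list.
#' @export
xpclr_config <- function(window_size = 50000L, step = 100L, max_snps = 50L,
                         r2_weight_threshold = 0.7,
                         sel_grid = c(0, exp(seq(log(1e-4), log(0.5),
                                                 length.out = 10))),
                         omega = NULL, rec_rate = 1e-8, ne = 1e4,
                         n_quad = 64L, seed = 1L) {
  if (!any(sel_grid == 0)) stop("sel_grid must contain 0 (nested neutral model)")
  if (window_size < step || step <= 0) stop("need window_size >= step > 0")
  if (max_snps < 1L) stop("max_snps must be >= 1")
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 max_snps = as.integer(max_snps),
                 r2_weight_threshold = r2_weight_threshold,
                 sel_grid = sort(unique(sel_grid)), omega = omega,
                 rec_rate = rec_rate, ne = ne, n_quad = as.integer(n_quad),
                 seed = as.integer(seed)),
            class = "xpclr_config")
}

#' Method-of-moments estimate of the drift variance scale omega
#'
#' Over sites polymorphic in the reference population (0 < p1 < 1), the mean
#' of `(p2 - p1)^2 / (p1 (1 - p1)) - 1/n2`; the subtracted term corrects the
#' sampling noise of the query frequency estimate.  Under pure drift the
#' expectation of the corrected ratio is the variance scale of the
#' query-frequency distribution around p1.
#'
#' @param counts_ref,counts_query [site_counts()] data frames over the same
#'   sites.
#' @return omega (may be ~0 or slightly negative with no divergence; the
#'   scan floors it at a small positive value).
#' @export
estimate_omega <- function(counts_ref, counts_query) {
  p1 <- counts_ref$k / counts_ref$n
  p2 <- counts_query$k / counts_query$n
  ok <- counts_ref$n > 0 & counts_query$n > 0 & p1 > 0 & p1 < 1
  if (!any(ok)) stop("no sites with 0 < p1 < 1; cannot estimate omega")
  mean((p2[ok] - p1[ok])^2 / (p1[ok] * (1 - p1[ok])) - 1 / counts_query$n[ok])
}

# Hitchhiking escape probability at genetic distance d (Morgans) for
# selection coefficient s: c = 1 - (2 Ne s)^(-d/s), clamped to [0, 1].
escape_prob <- function(d, s, ne) {
  pmin(pmax(1 - (2 * ne * s)^(-d / s), 0), 1)
}

#' Composite log-likelihood-ratio score of one window
#'
#' For each selection coefficient s on the grid the per-SNP likelihood
#' integrates a binomial over the modeled query-frequency density.  Neutral
#' (s = 0): a Normal(p1, omega p1 (1 - p1)) censored to \[0, 1\], censored
#' mass sitting as point masses at the boundaries.  Sweep (s > 0): with the
#' hitchhiking escape probability `c = 1 - (2 Ne s)^(-d/s)` a lineage
#' escapes and keeps its drift-smoothed frequency (the neutral density);
#' otherwise it is swept to 1 with probability p1 and to 0 otherwise.
#' Interior integration uses a fixed midpoint quadrature.  The score is
#' `2 (max_s l(s) - l(0))` with `l(s) = sum_j w_j log L_j(s)`, so it is
#' non-negative by construction; `s_hat` is the arg max (ties resolved to
#' the smallest s).
#'
#' @param p1 reference-population allele frequencies (each in (0, 1)).
#' @param k2,n2 query derived-allele counts and called sample sizes.
#' @param pos site positions in bp.
#' @param center window center in bp.
#' @param omega drift variance scale (> 0).
#' @param config an [xpclr_config()].
#' @param weights per-SNP weights (default 1).
#' @return list(score, s_hat, loglik = per-grid-point log-likelihoods).
#' @export
xpclr_window_score <- function(p1, k2, n2, pos, center, omega, config,
                               weights = NULL) {
  J <- length(p1)
  if (J == 0L) return(list(score = NA_real_, s_hat = NA_real_, loglik = NULL))
  if (any(p1 <= 0 | p1 >= 1)) stop("p1 must lie strictly in (0, 1)")
  w <- weights %||% rep(1, J)
  nq <- config$n_quad
  xq <- (seq_len(nq) - 0.5) / nq
  sg <- sqrt(omega * p1 * (1 - p1))
  # censored-normal neutral likelihood per SNP
  Dm <- matrix(stats::dnorm(rep(xq, each = J), mean = p1, sd = sg), J, nq)
  Bm <- matrix(stats::dbinom(rep(k2, times = nq), rep(n2, times = nq),
                             rep(xq, each = J)), J, nq)
  at0 <- as.numeric(k2 == 0L)
  at1 <- as.numeric(k2 == n2)
  P0 <- stats::pnorm(0, mean = p1, sd = sg)
  P1 <- stats::pnorm(1, mean = p1, sd = sg, lower.tail = FALSE)
  L_neut <- rowSums(Dm * Bm) / nq + P0 * at0 + P1 * at1
  # swept component: two-point mass at the boundaries (fixation with
  # probability p1, loss otherwise), broadened by the same censored-normal
  # drift noise as the neutral density
  D1 <- matrix(stats::dnorm(rep(xq, each = J), mean = 1, sd = sg), J, nq)
  D0 <- matrix(stats::dnorm(rep(xq, each = J), mean = 0, sd = sg), J, nq)
  L_fix <- rowSums(D1 * Bm) / nq +
    stats::pnorm(0, mean = 1, sd = sg) * at0 + 0.5 * at1
  L_loss <- rowSums(D0 * Bm) / nq +
    0.5 * at0 + stats::pnorm(1, mean = 0, sd = sg, lower.tail = FALSE) * at1
  L_swept <- p1 * L_fix + (1 - p1) * L_loss
  d <- config$rec_rate * abs(pos - center)
  grid <- config$sel_grid
  ll <- vapply(grid, function(s) {
    L <- if (s == 0) {
      L_neut
    } else {
      cc <- escape_prob(d, s, config$ne)
      cc * L_neut + (1 - cc) * L_swept
    }
    sum(w * log(pmax(L, 1e-300)))
  }, 0)
  i0 <- which(grid == 0)
  imax <- which.max(ll)
  list(score = 2 * (ll[imax] - ll[i0]), s_hat = grid[imax], loglik = ll)
}

#' Cross-population composite likelihood ratio (XP-CLR) scan
#'
#' Tiles each chromosome with sliding windows, caps the SNPs per window by
#' seeded uniform subsampling, down-weights clustered SNPs (weight `1/m_j`,
#' `m_j` = number of window SNPs, itself included, whose reference-population
#' r-squared with SNP j is at or above the threshold), and scores each window
#' with [xpclr_window_score()].  Sites used are those polymorphic in the
#' reference population with at least one called query haplotype; the derived
#' allele is the VCF alt allele by convention.
#'
#' Roles are asymmetric: `pops[1]` supplies the baseline frequencies p1,
#' `pops[2]` is the population scanned for sweeps.  Swapping them changes
#' the scores.
#'
#' @param matrix a [genotype_matrix()].
#' @param populations a [population_spec()].
#' @param config an [xpclr_config()].
#' @param pops length-2 character vector: (reference, query) labels.
#' @param chrom_len named vector of chromosome lengths (default: last SNP).
#' @return an `xpclr_result`: list with `track` (a `window_stat_track` whose
#'   `value` is the score, plus column `s_hat`), `omega`, `config`.
#' @export
xpclr_scan <- function(matrix, populations, config = xpclr_config(),
                       pops = c("ref", "query"), chrom_len = NULL) {
  stopifnot(inherits(config, "xpclr_config"))
  s_ref <- pop_samples(populations, pops[1], matrix)
  s_qry <- pop_samples(populations, pops[2], matrix)
  cr <- site_counts(matrix, s_ref)
  cq <- site_counts(matrix, s_qry)
  p1_all <- cr$k / cr$n
  usable <- cr$n > 0 & cq$n > 0 & p1_all > 0 & p1_all < 1
  omega <- config$omega %||% estimate_omega(cr[usable, ], cq[usable, ])
  omega <- max(omega, 1e-8)
  ref_calls <- subset_matrix(matrix, samples = s_ref)$calls
  out <- list()
  wcount <- 0L
  for (cc in unique(matrix$chrom)) {
    on_chr <- which(matrix$chrom == cc & usable)
    clen <- if (!is.null(chrom_len) && cc %in% names(chrom_len)) {
      as.numeric(chrom_len[[cc]])
    } else if (any(matrix$chrom == cc)) {
      max(matrix$pos[matrix$chrom == cc])
    } else 0
    starts <- tile_starts(clen, config$window_size, config$step)
    ends <- pmin(starts + config$window_size, clen)
    pos0 <- matrix$pos[on_chr] - 1L
    rows <- data.frame(chrom = cc, start = starts, end = ends,
                       n_snps = 0L, value = NA_real_, s_hat = NA_real_,
                       stringsAsFactors = FALSE)
    for (wi in seq_along(starts)) {
      wcount <- wcount + 1L
      sel <- on_chr[pos0 >= starts[wi] & pos0 < ends[wi]]
      if (!length(sel)) next
      if (length(sel) > config$max_snps) {
        sel <- with_seed(mix_seed(config$seed, wcount), {
          sort(sample(sel, config$max_snps))
        })
      }
      rows$n_snps[wi] <- length(sel)
      r2 <- ld_r2_matrix(ref_calls[, sel, drop = FALSE])
      hit <- r2 >= config$r2_weight_threshold
      hit[is.na(hit)] <- FALSE
      diag(hit) <- TRUE
      wts <- 1 / rowSums(hit)
      sc <- xpclr_window_score(p1 = p1_all[sel], k2 = cq$k[sel],
                               n2 = cq$n[sel],
                               pos = matrix$pos[sel] - 0.5,
                               center = (starts[wi] + ends[wi]) / 2,
                               omega = omega, config = config,
                               weights = wts)
      rows$value[wi] <- sc$score
      rows$s_hat[wi] <- sc$s_hat
    }
    out[[length(out) + 1L]] <- rows
  }
  track <- do.call(rbind, out)
  attr(track, "stat") <- "xpclr"
  attr(track, "window_size") <- config$window_size
  attr(track, "step") <- config$step
  class(track) <- c("window_stat_track", "data.frame")
  structure(list(track = track, omega = omega, config = config),
            class = "xpclr_result")
}

#' @export
print.xpclr_result <- function(x, ...) {
  cat(sprintf("<xpclr_result> %d windows, omega = %.4g, max score = %.3f\n",
              nrow(x$track), x$omega, max(x$track$value, na.rm = TRUE)))
  invisible(x)
}

#' Write an XP-CLR result as TSV
#'
#' Columns: chrom, start, end, n_snps, score, s_hat.
#'
#' @param result an `xpclr_result`.
#' @param path output path.
#' @export
write_xpclr_result <- function(result, path) {
  df <- result$track[, c("chrom", "start", "end", "n_snps", "value", "s_hat")]
  names(df)[5] <- "score"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
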