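#' LOESS-style smoothing of a window statistic track
#'
#' Degree-1 local regression with tricube weights, fitted per chromosome on
#' the defined windows and evaluated at window midpoints.  For a target
#' midpoint the neighbourhood is the `ceiling(span * n)` nearest defined
#' midpoints; weights are `(1 - (|x - x0| / h)^3)^3` with `h` the largest
#' neighbourhood distance.  Undefined windows (NA value) are excluded from
#' fitting and stay undefined.  Chromosomes with fewer than 3 defined
#' windows are returned unsmoothed with a warning.
#'
#' @param track a `window_stat_track`.
#' @param span fraction of points per local fit, in (0, 1\] (default 0.05).
#' @return the track with smoothed `value`.
#' @export
loess_smooth <- function(track, span = 0.05) {
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]")
  out <- track
  for (cc in unique(track$chrom)) {
    rows <- which(track$chrom == cc)
    def <- rows[!is.na(track$value[rows])]
    if (length(def) < 3L) {
      warning(sprintf("chromosome '%s': fewer than 3 defined windows; returned unsmoothed", cc))
      next
    }
    x <- (track$start[def] + track$end[def]) / 2
    y <- track$value[def]
    q <- max(2L, ceiling(span * length(def)))
    for (i in seq_along(def)) {
      out$value[def[i]] <- tricube_fit(x, y, x[i], q)
    }
  }
  out
}

# Weighted degree-1 fit at x0 using the q nearest points, tricube weights.
tricube_fit <- function(x, y, x0, q) {
  d <- abs(x - x0)
  h <- sort(d, partial = q)[q]
  w <- numeric(length(x))
  if (h > 0) {
    inside <- d < h | (d == h)
    w[inside] <- (1 - pmin(d[inside] / h, 1)^3)^3
  } else {
    w[d == 0] <- 1
  }
  use <- w > 0
  if (sum(use) < 2L || stats::var(x[use]) == 0) {
    return(sum(w * y) / sum(w))
  }
  fit <- stats::lm.wfit(cbind(1, x[use] - x0), y[use], w[use])
  unname(fit$coefficients[1])
}

#' Empirical top-fraction threshold of a score track
#'
#' Nearest-rank `(1 - fraction)` quantile over the defined window values:
#' the order statistic at rank `ceiling((1 - fraction) * n)`, so the
#' threshold is always an observed value.  Windows with `value >= threshold`
#' are candidates.
#'
#' @param track a `window_stat_track` (or any data.frame with `value`).
#' @param fraction top fraction (default 0.01, the top 1\%).
#' @return threshold value.
#' @export
empirical_top_fraction <- function(track, fraction = 0.01) {
  v <- track$value[!is.na(track$value)]
  if (!length(v)) stop("no defined windows")
  stopifnot_scalar(fraction, "fraction", 0, 1)
  sort(v)[ceiling((1 - fraction) * length(v))]
}

#' Call candidate sweep regions from a score track
#'
#' Windows at or above the threshold are merged when overlapping or within
#' `merge_gap` bp of each other; each merged region records its peak window
#' score and contributing window count.  Calling is idempotent: re-calling
#' on single-window regions built from the output changes nothing.
#'
#' @param track a `window_stat_track`.
#' @param threshold score threshold (e.g. from [empirical_top_fraction()]).
#' @param merge_gap merge distance in bp (default: the track's step, i.e.
#'   adjacent candidate windows merge).
#' @return a `sweep_regions` data.frame: `chrom`, `start`, `end` (0-based
#'   half-open), `peak`, `threshold`, `n_windows`, `genes` (empty until
#'   [annotate_regions()]).
#' @export
call_sweep_regions <- function(track, threshold, merge_gap = NULL) {
  merge_gap <- merge_gap %||% attr(track, "step") %||% 0
  cand <- which(!is.na(track$value) & track$value >= threshold)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak = numeric(0),
                      threshold = numeric(0), n_windows = integer(0),
                      genes = character(0), stringsAsFactors = FALSE)
  if (!length(cand)) return(structure(empty, class = c("sweep_regions", "data.frame")))
  d <- track[cand, , drop = FALSE]
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  res <- list()
  cur <- d[1, ]
  cur_peak <- cur$value; cur_n <- 1L
  flush <- function(res, cur, peak, n) {
    res[[length(res) + 1L]] <- data.frame(chrom = cur$chrom, start = cur$start,
                                          end = cur$end, peak = peak,
                                          threshold = threshold,
                                          n_windows = n, genes = "",
                                          stringsAsFactors = FALSE)
    res
  }
  for (i in seq_len(nrow(d))[-1]) {
    if (d$chrom[i] == cur$chrom && d$start[i] <= cur$end + merge_gap) {
      cur$end <- max(cur$end, d$end[i])
      cur_peak <- max(cur_peak, d$value[i])
      cur_n <- cur_n + 1L
    } else {
      res <- flush(res, cur, cur_peak, cur_n)
      cur <- d[i, ]; cur_peak <- cur$value; cur_n <- 1L
    }
  }
  res <- flush(res, cur, cur_peak, cur_n)
  structure(do.call(rbind, res), class = c("sweep_regions", "data.frame"))
}

#' Attach candidate genes to sweep regions
#'
#' A gene is attached to a region when any of its CDS bases overlaps the
#' region (half-open intersection; a CDS merely abutting the region edge
#' does not overlap).  Chromosome names absent from the gene set are
#' reported and yield zero overlaps.
#'
#' @param regions a `sweep_regions` data.frame.
#' @param genes a [gene_model_set()].
#' @return `regions` with the `genes` column filled (comma-separated ids).
#' @export
annotate_regions <- function(regions, genes) {
  if (!nrow(regions)) return(regions)
  missing_chr <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(missing_chr)) {
    message("annotate_regions: no genes on chromosome(s) ",
            paste(missing_chr, collapse = ", "))
  }
  for (i in seq_len(nrow(regions))) {
    ov <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] & genes$end > regions$start[i]
    regions$genes[i] <- paste(sort(unique(genes$gene_id[ov])), collapse = ",")
  }
  regions
}

#' Write sweep regions as BED3 and as a scored TSV
#'
#' @param regions a `sweep_regions` data.frame.
#' @param bed_path,tsv_path output paths (either may be `NULL`).
#' @export
write_sweep_regions <- function(regions, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    if (nrow(regions)) {
      write_bed(interval_set(regions$chrom, regions$start, regions$end),
                bed_path)
    } else {
      writeLines(character(0), bed_path)
    }
  }
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(regions), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(regions)
}
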