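#' Genomic interval set (0-based half-open)
#'
#' The package-wide internal coordinate convention is 0-based half-open;
#' conversion to/from the 1-based inclusive conventions of VCF and GFF3
#' happens only at the file boundary.
#'
#' @param chrom character vector of contig ids.
#' @param start,end numeric vectors, 0-based half-open (`end > start`).
#' @return an `interval_set` data.frame sorted by (chrom, start, end).
#' @export
interval_set <- function(chrom = character(0), start = numeric(0),
                         end = numeric(0)) {
  if (length(chrom) != length(start) || length(start) != length(end)) {
    stop("chrom, start, end must have equal length")
  }
  if (any(end <= start)) stop("interval end must be > start (0-based half-open)")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("interval_set", "data.frame"))
}

#' Merge overlapping or near-adjacent intervals
#'
#' @param x an [interval_set()].
#' @param gap merge intervals separated by less than or equal to `gap` bp
#'   (default 0: merge only overlapping or book-ended intervals).
#' @return merged [interval_set()].
#' @export
merge_intervals <- function(x, gap = 0) {
  if (nrow(x) == 0L) return(interval_set())
  x <- interval_set(x$chrom, x$start, x$end)
  out <- list()
  for (cc in unique(x$chrom)) {
    d <- x[x$chrom == cc, , drop = FALSE]
    s <- d$start; e <- d$end
    cur_s <- s[1]; cur_e <- e[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (s[i] <= cur_e + gap) {
        cur_e <- max(cur_e, e[i])
      } else {
        out[[length(out) + 1L]] <- c(cc, cur_s, cur_e)
        cur_s <- s[i]; cur_e <- e[i]
      }
    }
    out[[length(out) + 1L]] <- c(cc, cur_s, cur_e)
  }
  m <- do.call(rbind, out)
  interval_set(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]))
}

#' Total base count of an interval set
#'
#' Overlapping intervals are merged first so each base counts once.
#' @param x an [interval_set()].
#' @export
interval_total_bp <- function(x) {
  if (nrow(x) == 0L) return(0)
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# Intersection of two interval sets, as an interval_set.
interval_intersect <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  res <- list()
  for (cc in intersect(unique(a$chrom), unique(b$chrom))) {
    da <- a[a$chrom == cc, ]; db <- b[b$chrom == cc, ]
    for (i in seq_len(nrow(da))) {
      s <- pmax(da$start[i], db$start); e <- pmin(da$end[i], db$end)
      ok <- e > s
      if (any(ok)) {
        res[[length(res) + 1L]] <- data.frame(chrom = cc, start = s[ok],
                                              end = e[ok])
      }
    }
  }
  if (!length(res)) return(interval_set())
  d <- do.call(rbind, res)
  interval_set(d$chrom, d$start, d$end)
}

#' Fraction of one interval set's bases covered by another
#'
#' `|a intersect b| / |a|` by base count (both sets merged first).
#'
#' @param a,b [interval_set()] objects on the same genome.
#' @return fraction in \[0, 1\], or `NA` when `a` is empty.
#' @export
interval_overlap_fraction <- function(a, b) {
  tot <- interval_total_bp(a)
  if (tot == 0) return(NA_real_)
  interval_total_bp(interval_intersect(a, b)) / tot
}

#' Read / write BED3 files
#'
#' Plain three-column BED (chrom, start, end), already 0-based half-open like
#' the internal convention, so no coordinate shift is applied.
#'
#' @param path file path.
#' @return [read_bed()] returns an [interval_set()].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(interval_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 3L)) {
    stop(sprintf("BED line %d has fewer than 3 fields", which(n < 3L)[1]))
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  end <- as.numeric(vapply(parts, `[[`, "", 3L))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinates")
  if (any(end <= start)) {
    stop(sprintf("BED line %d has end <= start", which(end <= start)[1]))
  }
  interval_set(chrom, start, end)
}

#' @rdname read_bed
#' @param x an [interval_set()].
#' @export
write_bed <- function(x, path) {
  writeLines(sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start),
                     as.integer(x$end)), path)
  invisible(path)
}
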