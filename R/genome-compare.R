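#' A pair of genomes with a query window tiling
#'
#' @param query,target named character vectors of sequences (query = the
#'   genome whose specific material is sought, e.g. a new assembly; target =
#'   the comparator genome).
#' @param window,step query tiling in bp (default 1000 bp windows with 500 bp
#'   overlap, i.e. step 500).
#' @return a `genome_pair` list.
#' @export
genome_pair <- function(query, target, window = 1000L, step = 500L) {
  if (!length(query) || !length(target) || any(!nzchar(c(query, target)))) {
    stop("query and target must be non-empty sequences")
  }
  if (window < step) stop("window must be >= step")
  structure(list(query = query, target = target,
                 window = as.integer(window), step = as.integer(step)),
            class = "genome_pair")
}

# k-mer index of a target sequence set: data.table(kmer, tname, tpos)
# (tpos 0-based); k-mers occurring more than `max_occ` times are dropped.
kmer_index <- function(target, k, max_occ = 50L) {
  tabs <- lapply(names(target), function(nm) {
    s <- target[[nm]]
    n <- nchar(s) - k + 1L
    if (n < 1L) return(NULL)
    data.table::data.table(kmer = substring(s, 1:n, k:(n + k - 1L)),
                           tname = nm, tpos = 0:(n - 1L))
  })
  idx <- data.table::rbindlist(tabs)
  occ <- idx[, list(nocc = .N), by = "kmer"]
  data.table::setkey(idx, kmer)
  idx[idx$kmer %in% occ$kmer[occ$nocc <= max_occ], ]
}

# Best hit of one query sequence against an indexed target.  Seeds at fixed
# stride; candidate diagonals ranked by seed support; on each diagonal the
# aligned run is the maximum-scoring stretch (match +1, mismatch -4) of the
# base-wise comparison (Kadane).  Runs from different diagonals that do not
# overlap on the query are chained greedily by score, so a query interrupted
# by an intron or an insertion in the target still reports its full aligned
# fraction.  identity = matches / aligned bases over the chained runs.
best_hit <- function(qseq, target, idx, k, stride, max_diag = 8L) {
  W <- nchar(qseq)
  res <- list(aligned_fraction = 0, identity = NA_real_,
              target_name = NA_character_, target_pos = NA_real_)
  if (W < k) return(res)
  qoff <- unique(c(seq(1L, W - k + 1L, by = stride), W - k + 1L))
  seeds <- data.table::data.table(kmer = substring(qseq, qoff, qoff + k - 1L),
                                  qpos = qoff - 1L)
  hits <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(res)
  hits$diag <- hits$tpos - hits$qpos
  support <- hits[, list(ns = .N), by = c("tname", "diag")]
  support <- support[order(-support$ns, support$tname, support$diag), ]
  qv <- strsplit(qseq, "")[[1]]
  runs <- list()
  for (ci in seq_len(min(max_diag, nrow(support)))) {
    tn <- support$tname[ci]; dg <- support$diag[ci]
    ts <- target[[tn]]; tl <- nchar(ts)
    # query projected on the target along this diagonal, clipped to bounds
    q_lo <- max(0L, -dg); q_hi <- min(W - 1L, tl - 1L - dg)
    if (q_hi < q_lo) next
    tseg <- strsplit(substr(ts, dg + q_lo + 1L, dg + q_hi + 1L), "")[[1]]
    m <- (qv[(q_lo + 1L):(q_hi + 1L)] == tseg)
    score <- ifelse(m, 1, -4)
    best <- 0; cur <- 0; cur_start <- 1L; b_start <- 1L; b_end <- 0L
    for (z in seq_along(score)) {
      if (cur <= 0) { cur <- 0; cur_start <- z }
      cur <- cur + score[z]
      if (cur > best) { best <- cur; b_start <- cur_start; b_end <- z }
    }
    if (best > 0 && b_end >= b_start) {
      runs[[length(runs) + 1L]] <- list(
        score = best, q_start = q_lo + b_start - 1L, q_end = q_lo + b_end,
        m = m[b_start:b_end],
        tname = tn, tpos = dg + q_lo + b_start - 1L)
    }
  }
  if (!length(runs)) return(res)
  runs <- runs[order(-vapply(runs, `[[`, 0, "score"))]
  # greedy chain by score; lower-scoring runs are trimmed where they overlap
  # an accepted run on the query, and dropped if nothing remains
  kept <- list(runs[[1]])
  for (r in runs[-1]) {
    for (kk in kept) {
      if (r$q_start >= r$q_end) break
      if (r$q_start < kk$q_end && r$q_end > kk$q_start) {
        if (r$q_start >= kk$q_start && r$q_end <= kk$q_end) {
          r$q_start <- r$q_end                     # fully contained: drop
        } else if (r$q_start < kk$q_start) {       # trim tail
          cut <- r$q_end - kk$q_start
          r$m <- r$m[seq_len(length(r$m) - cut)]
          r$q_end <- kk$q_start
        } else {                                   # trim head
          cut <- kk$q_end - r$q_start
          r$m <- r$m[-seq_len(cut)]
          r$tpos <- r$tpos + cut
          r$q_start <- kk$q_end
        }
      }
    }
    if (r$q_end > r$q_start) kept[[length(kept) + 1L]] <- r
  }
  tot_len <- sum(vapply(kept, function(x) x$q_end - x$q_start, 0))
  tot_match <- sum(vapply(kept, function(x) sum(x$m), 0))
  list(aligned_fraction = tot_len / W,
       identity = tot_match / tot_len,
       target_name = kept[[1]]$tname,
       target_pos = kept[[1]]$tpos)
}

#' Map query windows onto a target genome
#'
#' Tiles each query sequence into overlapping windows and reports, per
#' window, the best ungapped hit on the target: `aligned_fraction` (fraction
#' of the window's bases inside the aligned run) and `identity` (matching
#' fraction within the run).  A minimal exact-k-mer-seeded mapper stands in
#' for an external aligner; hit tables computed externally in the same
#' schema are accepted anywhere a hit table is consumed.
#'
#' @param pair a [genome_pair()].
#' @param k_seed seed k-mer length (default 31).
#' @param against `"target"` (default) or `"self"` (map the query tiling
#'   back onto the query genome, the perfect-self control used by
#'   [classify_specific_windows()]).
#' @param stride spacing of seed k-mers within a window (default 20 bp).
#' @return data.frame: `query_id`, `chrom`, `start`, `end` (window, 0-based
#'   half-open), `aligned_fraction`, `identity`, `target_name`, `target_pos`.
#' @export
map_windows <- function(pair, k_seed = 31L, against = c("target", "self"),
                        stride = 20L) {
  against <- match.arg(against)
  stopifnot(inherits(pair, "genome_pair"))
  target <- if (against == "self") pair$query else pair$target
  idx <- kmer_index(target, k_seed)
  out <- list()
  for (nm in names(pair$query)) {
    s <- pair$query[[nm]]; L <- nchar(s)
    starts <- tile_starts(L, pair$window, pair$step)
    ends <- pmin(starts + pair$window, L)
    for (wi in seq_along(starts)) {
      h <- best_hit(substr(s, starts[wi] + 1L, ends[wi]), target, idx,
                    k_seed, stride)
      out[[length(out) + 1L]] <- data.frame(
        query_id = sprintf("%s:%d-%d", nm, starts[wi], ends[wi]),
        chrom = nm, start = starts[wi], end = ends[wi],
        aligned_fraction = h$aligned_fraction, identity = h$identity,
        target_name = h$target_name, target_pos = h$target_pos,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Map arbitrary query sequences (e.g. spliced CDS) onto a target genome
#'
#' Same mapper as [map_windows()] but for a set of whole sequences; used for
#' the alignment-based gene conservation categories.
#'
#' @param queries named character vector of query sequences.
#' @param target named character vector of target sequences.
#' @param k_seed,stride see [map_windows()].
#' @return data.frame: `query_id`, `aligned_fraction`, `identity`,
#'   `target_name`, `target_pos`.
#' @export
map_sequences <- function(queries, target, k_seed = 31L, stride = 20L) {
  idx <- kmer_index(target, k_seed)
  rows <- lapply(names(queries), function(nm) {
    h <- best_hit(queries[[nm]], target, idx, k_seed, stride)
    data.frame(query_id = nm, aligned_fraction = h$aligned_fraction,
               identity = h$identity, target_name = h$target_name,
               target_pos = h$target_pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Identify genome-specific query windows
#'
#' A window is specific iff its aligned fraction to the comparator genome is
#' strictly below `threshold` ("failed to align or aligned over less than
#' 20% of the window") while it maps back perfectly onto its own genome
#' (aligned fraction and identity both 1), which excludes assembly artefacts.
#' Windows lacking a self-hit record are excluded and reported.
#'
#' @param hits_to_other,hits_to_self hit tables from [map_windows()] (same
#'   tiling; `hits_to_self` from `against = "self"`).
#' @param threshold strict upper bound on the aligned fraction to the other
#'   genome (default 0.20).
#' @return an [interval_set()] of specific windows (un-merged).
#' @export
classify_specific_windows <- function(hits_to_other, hits_to_self,
                                      threshold = 0.20) {
  m <- match(hits_to_other$query_id, hits_to_self$query_id)
  if (anyNA(m)) {
    message(sprintf("classify_specific_windows: %d window(s) lack a self-hit record; excluded",
                    sum(is.na(m))))
  }
  ok <- !is.na(m)
  other <- hits_to_other[ok, , drop = FALSE]
  self <- hits_to_self[m[ok], , drop = FALSE]
  spec <- other$aligned_fraction < threshold &
    self$aligned_fraction >= 1 & !is.na(self$identity) & self$identity >= 1
  interval_set(other$chrom[spec], other$start[spec], other$end[spec])
}

#' Merge specific windows into regions and total their length
#'
#' @param windows an [interval_set()] of specific windows.
#' @return list with `intervals` (merged [interval_set()]) and `total_bp`.
#' @export
merge_specific_regions <- function(windows) {
  m <- merge_intervals(windows)
  list(intervals = m, total_bp = interval_total_bp(m))
}

#' Flag genes by CDS overlap with specific sequence
#'
#' A gene is flagged iff strictly more than `min_frac` of its CDS bases fall
#' inside the specific intervals.
#'
#' @param genes a [gene_model_set()].
#' @param specific an [interval_set()] of specific sequence.
#' @param min_frac strict lower bound on the CDS overlap fraction
#'   (default 0.80).
#' @return character vector of flagged gene ids.
#' @export
gene_specific_by_overlap <- function(genes, specific, min_frac = 0.80) {
  ids <- unique(genes$gene_id)
  flagged <- character(0)
  for (g in ids) {
    d <- genes[genes$gene_id == g, , drop = FALSE]
    cds_bp <- sum(d$end - d$start)
    if (cds_bp == 0) stop(sprintf("gene '%s' has zero-length CDS", g))
    ov <- interval_total_bp(
      interval_intersect(interval_set(d$chrom, d$start, d$end), specific))
    if (ov / cds_bp > min_frac) flagged <- c(flagged, g)
  }
  flagged
}

#' Conservation category from alignment coverage and identity
#'
#' `highly_conserved`: coverage 1 and identity 1; `mutated`: coverage 1 and
#' identity in \[0.90, 1); `structural_variant`: coverage in \[0.50, 1) and
#' identity >= 0.90; everything else (failed, coverage < 0.50 or identity
#' < 0.90) is `specific`.  The function is total on \[0,1\]^2 and the
#' categories are mutually exclusive.
#'
#' @param coverage,identity numeric vectors in \[0, 1\] (`NA` identity, as
#'   emitted for unmapped queries, counts as failed).
#' @return character vector of categories.
#' @export
categorize_gene_conservation <- function(coverage, identity) {
  if (length(coverage) != length(identity)) stop("length mismatch")
  identity[is.na(identity)] <- 0
  out <- rep("specific", length(coverage))
  out[coverage >= 1 & identity >= 1] <- "highly_conserved"
  out[coverage >= 1 & identity >= 0.90 & identity < 1] <- "mutated"
  out[coverage >= 0.50 & coverage < 1 & identity >= 0.90] <- "structural_variant"
  out
}

#' Final specific-gene set: intersection of the two detection methods
#'
#' @param method1 gene ids flagged by CDS overlap with specific sequence
#'   ([gene_specific_by_overlap()]).
#' @param method2 gene ids whose aligned CDS fell in the `specific` category
#'   ([categorize_gene_conservation()]).
#' @return character vector (set intersection).
#' @export
final_specific_genes <- function(method1, method2) {
  sort(intersect(method1, method2))
}

#' Extract spliced CDS sequences of gene models
#'
#' @param genes a [gene_model_set()].
#' @param genome named character vector containing the genes' chromosomes.
#' @return named character vector of CDS sequences (reverse-complemented for
#'   minus-strand genes).
#' @export
extract_cds_seq <- function(genes, genome) {
  ids <- unique(genes$gene_id)
  out <- stats::setNames(character(length(ids)), ids)
  for (g in ids) {
    d <- genes[genes$gene_id == g, , drop = FALSE]
    s <- genome[[d$chrom[1]]]
    if (is.null(s)) stop(sprintf("chromosome '%s' absent from genome", d$chrom[1]))
    parts <- substring(s, d$start + 1L, d$end)
    seq <- paste(parts, collapse = "")
    if (d$strand[1] == "-") {
      seq <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
    }
    out[g] <- seq
  }
  out
}

#' Pan-gene classification of gene families
#'
#' A family is `core` when present in all `n_genomes` genomes, `singleton`
#' when present in exactly one, and `dispensable` otherwise.
#'
#' @param families data.frame with columns `gene_id`, `family_id`, `genome`.
#' @param n_genomes number of genomes in the panel.
#' @return data.frame: `family_id`, `n_genomes_present`, `class`.
#' @export
pangene_classify <- function(families, n_genomes) {
  req <- c("gene_id", "family_id", "genome")
  if (!all(req %in% names(families))) {
    stop("families must have columns gene_id, family_id, genome")
  }
  if (any(is.na(families$genome) | !nzchar(families$genome))) {
    stop("every gene must carry a genome label")
  }
  fam <- unique(families[, c("family_id", "genome")])
  cnt <- table(fam$family_id)
  cls <- ifelse(cnt == n_genomes, "core",
                ifelse(cnt == 1L, "singleton", "dispensable"))
  data.frame(family_id = names(cnt),
             n_genomes_present = as.integer(cnt),
             class = as.character(cls),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genome-size estimate from a k-mer histogram
#'
#' Peak depth is the modal multiplicity at or above `min_mult` (multiplicity
#' below the cutoff is treated as noise); the estimate is the retained k-mer
#' mass divided by the peak depth:
#' `sum_(m >= min_mult) m * count(m) / peak_depth`.
#'
#' @param hist a `kmer_histogram` (data.frame `multiplicity`, `count`).
#' @param min_mult noise cutoff on multiplicity (default 3).
#' @return genome size estimate in bp (with attribute `peak_depth`).
#' @export
estimate_genome_size <- function(hist, min_mult = 3L) {
  keep <- hist$multiplicity >= min_mult & hist$count > 0
  if (!any(keep)) stop("no k-mer multiplicity mode at or above min_mult")
  h <- hist[keep, , drop = FALSE]
  peak <- h$multiplicity[which.max(h$count)]
  est <- sum(h$multiplicity * h$count) / peak
  attr(est, "peak_depth") <- peak
  est
}
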