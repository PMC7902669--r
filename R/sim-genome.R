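random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute positions (1-based) of a sequence with a different random base
mutate_bases <- function(seq, pos) {
  if (!length(pos)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate a pair of genomes with planted genome-specific insertions
#'
#' Genome B is genome A plus (a) planted insertions of novel random sequence
#' (the "specific" material -- novel, not duplicated, so a mapper cannot
#' spuriously place it), (b) background SNPs at `snp_rate` in the A-derived
#' portion, and (c) `n_genes` planted gene models *per conservation
#' category*:
#' \describe{
#'   \item{highly_conserved}{CDS in A-derived sequence, kept free of SNPs.}
#'   \item{mutated}{CDS in A-derived sequence with a forced ~5\% SNP rate.}
#'   \item{structural_variant}{CDS straddling an insertion boundary, ~30\%
#'     of CDS bases inside the novel sequence.}
#'   \item{specific}{CDS entirely inside an insertion.}
#' }
#'
#' Structural-variant and specific genes are hosted by the insertions, so
#' `n_insert >= n_genes` is required, as is enough room to pack all
#' insertions and genes without overlap (otherwise an infeasible-packing
#' error is raised).
#'
#' @param length genome A length in bp.
#' @param n_insert number of planted insertions.
#' @param insert_len_range length-2 numeric, min/max insertion length in bp
#'   (min must be >= 2600 to host the planted genes).
#' @param snp_rate per-site background substitution probability.
#' @param n_genes genes per conservation category.
#' @param seed integer seed.
#' @return list with `pair` (a [genome_pair()], query = genome B),
#'   `genes` (a [gene_model_set()] on B), and `truth` (a [sim_truth()] with
#'   `specific_intervals` in B coordinates and `gene_categories`).
#' @export
simulate_genome_pair <- function(length = 200000L, n_insert = 3L,
                                 insert_len_range = c(4000L, 8000L),
                                 snp_rate = 0.002, n_genes = 2L, seed = 1L) {
  stopifnot_scalar(snp_rate, "snp_rate", 0, 1)
  if (n_genes > 0L && n_insert < n_genes) {
    stop("infeasible packing: need n_insert >= n_genes to host the planted ",
         "structural-variant and specific genes")
  }
  if (n_genes > 0L && insert_len_range[1] < 2600) {
    stop("infeasible packing: insertions must be >= 2600 bp to host genes")
  }
  # gene geometry (bp): two CDS exons separated by an intron
  cds1 <- 400L; intron <- 200L; cds2 <- 500L
  gene_span <- cds1 + intron + cds2
  n_slots <- n_insert + 2L * n_genes
  slot_w <- floor(length / max(n_slots, 1L))
  need <- max(if (n_insert > 0L) insert_len_range[2] else 0,
              if (n_genes > 0L) gene_span else 0) + gene_span + 400L
  if (n_slots > 0L && slot_w < need) {
    stop(sprintf("infeasible packing: slot width %d < required %d bp",
                 slot_w, need))
  }
  with_seed(seed, {
    A <- random_dna(length)
    slot_order <- sample.int(max(n_slots, 1L))
    ins_slots <- slot_order[seq_len(n_insert)]
    cons_slots <- slot_order[n_insert + seq_len(n_genes)]
    mut_slots <- slot_order[n_insert + n_genes + seq_len(n_genes)]
    ins_len <- if (n_insert > 0L) {
      as.integer(round(stats::runif(n_insert, insert_len_range[1],
                                    insert_len_range[2])))
    } else integer(0)
    # anchor = position in A (0-based) where material is inserted / placed;
    # the jitter range keeps every feature strictly inside its slot
    anchor <- function(slots) {
      jit <- max(1, slot_w - need)
      (slots - 1L) * slot_w + 1000L +
        as.integer(stats::runif(length(slots), 0, jit))
    }
    ins_anchor <- sort(anchor(ins_slots))
    # build B: A segments interleaved with novel inserts; record coordinate
    # shifts so planted features can be expressed in B coordinates
    segs <- character(0); b_ins <- matrix(numeric(0), 0, 2)
    prev <- 0L; off <- 0L
    ins_seq <- vapply(ins_len, random_dna, "")
    for (i in seq_len(n_insert)) {
      segs <- c(segs, substr(A, prev + 1L, ins_anchor[i]), ins_seq[i])
      b_start <- ins_anchor[i] + off
      b_ins <- rbind(b_ins, c(b_start, b_start + ins_len[i]))
      off <- off + ins_len[i]
      prev <- ins_anchor[i]
    }
    segs <- c(segs, substr(A, prev + 1L, length))
    B <- paste(segs, collapse = "")
    a2b <- function(apos) {                     # 0-based A coord -> B coord
      apos + vapply(apos, function(p) sum(ins_len[ins_anchor <= p]), 0)
    }
    # plant genes (coordinates on B, 0-based half-open CDS intervals)
    genes <- list(); cats <- character(0)
    add_gene <- function(id, start0) {          # start0: gene start on B
      gene_model_set(rep(id, 2L), rep("chrB", 2L), rep("+", 2L),
                     c(start0, start0 + cds1 + intron),
                     c(start0 + cds1, start0 + gene_span))
    }
    protected <- list()                         # B intervals kept SNP-free
    forced <- list()                            # B intervals w/ forced SNPs
    in_bp <- as.integer(round(0.3 * (cds1 + cds2)))  # SV-gene bases in novel
    for (g in seq_len(n_genes)) {
      gc <- add_gene(sprintf("cons_%02d", g), a2b(anchor(cons_slots[g])))
      genes <- c(genes, list(gc)); cats <- c(cats, "highly_conserved")
      protected <- c(protected, list(cbind(gc$start, gc$end)))
      gm <- add_gene(sprintf("mut_%02d", g), a2b(anchor(mut_slots[g])))
      genes <- c(genes, list(gm)); cats <- c(cats, "mutated")
      forced <- c(forced, list(cbind(gm$start, gm$end)))
      protected <- c(protected, list(cbind(gm$start, gm$end)))
      # specific gene: fully inside insertion g, away from its edges
      gs <- add_gene(sprintf("spec_%02d", g), b_ins[g, 1] + 1200L)
      genes <- c(genes, list(gs)); cats <- c(cats, "specific")
      # structural-variant gene: last `in_bp` CDS bases inside insertion g
      gv <- add_gene(sprintf("sv_%02d", g), b_ins[g, 1] + in_bp - gene_span)
      genes <- c(genes, list(gv)); cats <- c(cats, "structural_variant")
      pr_s <- gv$start; pr_e <- pmin(gv$end, b_ins[g, 1])
      ok <- pr_e > pr_s
      if (any(ok)) protected <- c(protected, list(cbind(pr_s[ok], pr_e[ok])))
    }
    gene_set <- if (length(genes)) do.call(rbind, genes) else
      gene_model_set(character(0), character(0), character(0), numeric(0), numeric(0))
    if (length(genes)) class(gene_set) <- c("gene_model_set", "data.frame")
    # background SNPs on the A-derived part of B, avoiding protected CDS and
    # the novel insertions themselves
    bn <- nchar(B)
    is_novel <- logical(bn)
    for (i in seq_len(nrow(b_ins))) {
      is_novel[(b_ins[i, 1] + 1):b_ins[i, 2]] <- TRUE
    }
    is_prot <- logical(bn)
    for (iv in protected) {
      for (r in seq_len(nrow(iv))) is_prot[(iv[r, 1] + 1):iv[r, 2]] <- TRUE
    }
    eligible <- which(!is_novel & !is_prot)
    nsnp <- stats::rbinom(1L, length(eligible), snp_rate)
    snp_pos <- if (nsnp > 0L) sample(eligible, nsnp) else integer(0)
    # forced SNPs stay >= 15 bp away from exon edges so an ungapped aligner
    # still reports full coverage (identity < 1 is the planted signal)
    forced_pos <- integer(0)
    for (iv in forced) {
      for (r in seq_len(nrow(iv))) {
        cand <- (iv[r, 1] + 16):(iv[r, 2] - 15)
        nm <- max(1L, stats::rbinom(1L, length(cand), 0.05))
        forced_pos <- c(forced_pos, sample(cand, nm))
      }
    }
    B <- mutate_bases(B, c(snp_pos, forced_pos))
    truth <- sim_truth(
      specific_intervals = if (nrow(b_ins)) {
        interval_set(rep("chrB", nrow(b_ins)), b_ins[, 1], b_ins[, 2])
      } else interval_set(),
      gene_categories = if (length(genes)) {
        stats::setNames(cats, unique(gene_set$gene_id))
      } else NULL)
    list(pair = genome_pair(query = c(chrB = B), target = c(chrA = A)),
         genes = gene_set, truth = truth)
  })
}

#' Simulate a k-mer histogram from error-free shotgun reads
#'
#' Draws error-free fixed-length reads uniformly from the genome to the
#' stated fold coverage, counts all read k-mers, and returns the histogram of
#' k-mer multiplicity (distinct k-mer observation counts), the input an
#' assembly-free genome-size estimator consumes.
#'
#' @param genome a single sequence (character string).
#' @param depth fold coverage (> 0).
#' @param k k-mer size (>= 11; 25 is the conventional choice).
#' @param read_len read length in bp (default 1000, error-corrected
#'   long-read scale).
#' @param seed integer seed.
#' @return a `kmer_histogram`: data.frame with columns `multiplicity`,
#'   `count`, and attribute `k`.
#' @export
simulate_kmer_histogram <- function(genome, depth, k = 25L, read_len = 1000L,
                                    seed = 1L) {
  if (depth <= 0) stop("depth must be > 0")
  if (k < 11L) stop("k must be >= 11")
  G <- nchar(genome)
  if (G < k) stop("genome shorter than k")
  if (G < read_len) stop("genome shorter than read_len")
  with_seed(seed, {
    n_reads <- as.integer(ceiling(depth * G / read_len))
    starts <- sample.int(G - read_len + 1L, n_reads, replace = TRUE)
    # multiplicity of the k-mer starting at genome position p = number of
    # reads fully covering [p, p + k - 1] = read starts in
    # [p - (read_len - k), p]; then positions holding identical k-mer
    # strings are aggregated
    tab <- tabulate(starts, nbins = G - read_len + 1L)
    cs <- cumsum(c(0L, tab))
    npos <- G - k + 1L
    p <- seq_len(npos)
    hi <- pmin(p, G - read_len + 1L)
    lo <- pmax(p - (read_len - k), 1L)
    cov <- cs[hi + 1L] - cs[lo]
    kmers <- substring(genome, p, p + k - 1L)
    dt <- data.table::data.table(kmer = kmers, cov = cov)
    tot <- dt[, list(m = sum(cov)), by = "kmer"]
    tot <- tot[tot$m > 0L, ]
    h <- tot[, list(count = .N), by = "m"]
    h <- h[order(h$m), ]
    structure(data.frame(multiplicity = h$m, count = h$count),
              k = as.integer(k), class = c("kmer_histogram", "data.frame"))
  })
}
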