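#' Read / write FASTA sequences
#'
#' Thin wrappers around Biostrings; sequences travel through the package as
#' named uppercase character strings.
#'
#' @param path file path.
#' @return [read_fasta()]: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

#' Gene models with CDS intervals
#'
#' One row per CDS segment; coordinates 0-based half-open (converted from
#' GFF3's 1-based inclusive on read).  CDS segments of a gene must be
#' non-overlapping; they are stored sorted.
#'
#' @param gene_id,chrom,strand per-CDS vectors (strand `+` or `-`).
#' @param start,end 0-based half-open CDS coordinates.
#' @return a `gene_model_set` data.frame.
#' @export
gene_model_set <- function(gene_id, chrom, strand, start, end) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(end <= start)) stop("CDS end must be > start")
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   strand = as.character(strand), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  for (g in unique(df$gene_id)) {
    d <- df[df$gene_id == g, ]
    if (length(unique(d$chrom)) > 1L || length(unique(d$strand)) > 1L) {
      stop(sprintf("gene '%s' mixes chroms or strands", g))
    }
    if (nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)])) {
      stop(sprintf("gene '%s' has overlapping CDS segments", g))
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("gene_model_set", "data.frame"))
}

#' Read gene models from GFF3
#'
#' Accepts the standard gene/mRNA/CDS feature hierarchy (CDS may also hang
#' directly off a gene).  Only CDS intervals are retained; GFF3's 1-based
#' inclusive coordinates become 0-based half-open.
#'
#' @param path GFF3 file path.
#' @return a [gene_model_set()].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  gene_ids <- id[type == "gene"]
  tx2gene <- stats::setNames(parent[type == "mRNA"], id[type == "mRNA"])
  cds <- which(type == "CDS")
  if (!length(cds)) stop("GFF3 contains no CDS features")
  owner <- parent[cds]
  gene_of <- ifelse(owner %in% gene_ids, owner, unname(tx2gene[owner]))
  if (anyNA(gene_of)) stop("CDS feature with unresolvable Parent")
  st <- GenomicRanges::start(gr)[cds]; en <- GenomicRanges::end(gr)[cds]
  if (any(en < st)) stop("GFF3 record with end < start")
  gene_model_set(gene_of,
                 as.character(GenomicRanges::seqnames(gr))[cds],
                 as.character(GenomicRanges::strand(gr))[cds],
                 st - 1L, en)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features (one transcript per gene), converting
#' the internal 0-based half-open coordinates back to 1-based inclusive.
#'
#' @param genes a [gene_model_set()].
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in unique(genes$gene_id)) {
    d <- genes[genes$gene_id == g, , drop = FALSE]
    gs <- min(d$start) + 1L; ge <- max(d$end)
    writeLines(c(
      sprintf("%s\tzeasweep\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              d$chrom[1], gs, ge, d$strand[1], g),
      sprintf("%s\tzeasweep\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              d$chrom[1], gs, ge, d$strand[1], g, g),
      sprintf("%s\tzeasweep\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
              d$chrom, d$start + 1L, d$end, d$strand, g, g)), con)
  }
  invisible(path)
}

#' Write / read a phylogenetic tree in Newick format
#'
#' Wrappers around \pkg{ape}; trees in the package are `phylo` objects.
#'
#' @param tree an `ape::phylo` object.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
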