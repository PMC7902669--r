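#' Read a VCF into a genotype matrix
#'
#' Parses VCF 4.x with a GT field.  Haploid calls (`0` / `1` / `.`)
#' contribute one haplotype per sample; diploid calls (`0/0`, `0|1`,
#' `./.`, ...) are split into two haplotypes per sample, named
#' `<sample>_1` / `<sample>_2`, so downstream statistics always operate on
#' haplotypes.  A mixed call like `0/.` yields one called and one missing
#' haplotype.  Multiallelic and non-SNP records are skipped; the skip count
#' is reported via `message()` and attached as attribute `n_skipped`.
#'
#' @param path VCF file path (uncompressed text).
#' @param assume_haploid force haploid parsing: only the first allele of each
#'   genotype is read, one haplotype per sample.
#' @return a [genotype_matrix()] with attribute `n_skipped`.
#' @export
read_vcf <- function(path, assume_haploid = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L) stop("VCF header line '#CHROM...' missing or duplicated")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L || cols[9] != "FORMAT") {
    stop(sprintf("line %d: VCF must carry FORMAT and at least one sample", hdr))
  }
  vcf_samples <- cols[-(1:9)]
  body <- which(seq_along(lines) > hdr & nzchar(lines) & !startsWith(lines, "#"))
  n_skipped <- 0L
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    ln <- body[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols)) {
      stop(sprintf("line %d: expected %d fields, found %d", ln, length(cols),
                   length(f)))
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop(sprintf("line %d: non-integer POS '%s'", ln, f[2]))
    ref <- f[4]; alt <- f[5]
    if (grepl(",", alt, fixed = TRUE) || nchar(ref) != 1L ||
        nchar(alt) != 1L || alt == "." || ref == ".") {
      n_skipped <- n_skipped + 1L
      next
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop(sprintf("line %d: FORMAT lacks GT", ln))
    gt <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), function(x) {
      if (length(x) < gt_idx) NA_character_ else x[gt_idx]
    }, "")
    if (anyNA(gt)) stop(sprintf("line %d: sample field lacks GT value", ln))
    recs[[i]] <- list(chrom = f[1], pos = pos, ref = ref, alt = alt, gt = gt)
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (n_skipped > 0L) {
    message(sprintf("read_vcf: skipped %d multiallelic/non-SNP record(s)",
                    n_skipped))
  }
  parse_allele <- function(a, ln) {
    out <- suppressWarnings(as.integer(a))
    out[a == "."] <- NA_integer_
    bad <- is.na(out) & a != "."
    if (any(bad) || any(out[!is.na(out)] > 1L)) {
      stop(sprintf("line %s: unparseable GT allele", ln))
    }
    out
  }
  # determine ploidy from the first record (or the flag)
  diploid <- FALSE
  if (length(recs) && !assume_haploid) {
    diploid <- any(grepl("[/|]", recs[[1]]$gt))
  }
  sample_ids <- if (diploid) {
    as.vector(rbind(paste0(vcf_samples, "_1"), paste0(vcf_samples, "_2")))
  } else {
    vcf_samples
  }
  n_hap <- length(sample_ids)
  calls <- matrix(NA_integer_, n_hap, length(recs))
  for (j in seq_along(recs)) {
    gt <- recs[[j]]$gt
    if (diploid) {
      halves <- strsplit(gt, "[/|]")
      a1 <- vapply(halves, function(x) x[1], "")
      a2 <- vapply(halves, function(x) if (length(x) > 1L) x[2] else ".", "")
      calls[, j] <- as.vector(rbind(parse_allele(a1, "?"), parse_allele(a2, "?")))
    } else {
      first <- sub("[/|].*$", "", gt)       # assume_haploid: first allele only
      calls[, j] <- parse_allele(first, "?")
    }
  }
  chrom <- vapply(recs, `[[`, "", "chrom")
  pos <- vapply(recs, `[[`, 0L, "pos")
  o <- order(chrom, pos)
  gm <- genotype_matrix(calls[, o, drop = FALSE], sample_ids,
                        chrom[o], pos[o],
                        vapply(recs, `[[`, "", "ref")[o],
                        vapply(recs, `[[`, "", "alt")[o])
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write a genotype matrix as a haploid VCF 4.2
#'
#' One haplotype per VCF sample column, GT values `0` / `1` / `.`, sites
#' sorted by (chrom, pos).
#'
#' @param matrix a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  o <- order(matrix$chrom, matrix$pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(matrix$chrom[o])),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", matrix$sample_ids), collapse = "\t")),
             con)
  for (j in o) {
    gt <- as.character(matrix$calls[, j])
    gt[is.na(gt)] <- "."
    writeLines(paste(c(matrix$chrom[j], matrix$pos[j], ".", matrix$ref[j],
                       matrix$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
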