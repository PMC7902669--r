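#' Biallelic haplotype genotype matrix
#'
#' The substrate of all population-genetic statistics in the package: a set of
#' haplotypes typed at biallelic SNP sites.  Diploid VCF input is split into
#' two haplotypes per sample on read (see [read_vcf()]), so rows here are
#' always haplotypes.
#'
#' @param calls integer matrix, haplotypes x sites, entries 0 (ref), 1 (alt)
#'   or `NA` (missing).
#' @param sample_ids character vector of haplotype identifiers (row names).
#' @param chrom character vector of contig ids, one per site.
#' @param pos integer vector of 1-based site positions, strictly increasing
#'   within each contig.
#' @param ref,alt single-character reference / alternate alleles per site.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `sample_ids`, `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 1L, NA, 1L), 2, 2),
#'                       sample_ids = c("a", "b"),
#'                       chrom = c("1", "1"), pos = c(10L, 20L),
#'                       ref = c("A", "C"), alt = c("G", "T"))
#' n_sites(gm)
#' @export
genotype_matrix <- function(calls, sample_ids, chrom, pos,
                            ref = rep("A", length(pos)),
                            alt = rep("T", length(pos))) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n_hap <- nrow(calls)
  n_site <- ncol(calls)
  if (length(sample_ids) != n_hap) stop("sample_ids length must equal nrow(calls)")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(chrom) != n_site || length(pos) != n_site ||
      length(ref) != n_site || length(alt) != n_site) {
    stop("chrom, pos, ref, alt must each have one entry per site")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    stop("calls must be 0, 1 or NA (biallelic only)")
  }
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      stop(sprintf("positions must be strictly increasing within contig '%s'", cc))
    }
  }
  rownames(calls) <- sample_ids
  structure(list(calls = calls, sample_ids = as.character(sample_ids),
                 chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d haplotypes x %d biallelic sites on %d contig(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$chrom))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_sites <- function(x) ncol(x$calls)

#' @rdname genotype_matrix
#' @export
n_haplotypes <- function(x) nrow(x$calls)

#' Subset a genotype matrix by haplotypes and/or sites
#'
#' @param x a `genotype_matrix`.
#' @param samples haplotype ids or indices (default all).
#' @param sites logical or integer site index (default all).
#' @return a `genotype_matrix`.
#' @export
subset_matrix <- function(x, samples = NULL, sites = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  i <- if (is.null(samples)) seq_len(nrow(x$calls)) else samples
  if (is.character(i)) {
    j <- match(i, x$sample_ids)
    if (anyNA(j)) stop("unknown sample ids: ", paste(i[is.na(j)], collapse = ", "))
    i <- j
  }
  s <- if (is.null(sites)) seq_len(ncol(x$calls)) else sites
  if (is.logical(s)) s <- which(s)
  genotype_matrix(x$calls[i, s, drop = FALSE], x$sample_ids[i],
                  x$chrom[s], x$pos[s], x$ref[s], x$alt[s])
}

#' Sample-to-population assignment
#'
#' Maps haplotype ids to population labels (e.g. `"sweet"`, `"panel282"`).
#' Every analysis that contrasts populations takes one of these.
#'
#' @param sample_id character vector of haplotype ids.
#' @param population character vector of population labels, same length.
#' @return An object of class `population_spec` (a data.frame).
#' @export
population_spec <- function(sample_id, population) {
  if (length(sample_id) != length(population)) stop("lengths differ")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  structure(data.frame(sample_id = as.character(sample_id),
                       population = as.character(population),
                       stringsAsFactors = FALSE),
            class = c("population_spec", "data.frame"))
}

# Return haplotype ids of one population, validated against a matrix.
pop_samples <- function(spec, pop, matrix = NULL, min_n = 2L) {
  ids <- spec$sample_id[spec$population == pop]
  if (!is.null(matrix)) {
    missing <- setdiff(ids, matrix$sample_ids)
    if (length(missing)) {
      stop(sprintf("population '%s' references samples absent from the matrix: %s",
                   pop, paste(utils::head(missing, 5), collapse = ", ")))
    }
  }
  if (length(ids) < min_n) {
    stop(sprintf("population '%s' has %d samples; >= %d required", pop, length(ids), min_n))
  }
  ids
}

#' Read / write a sample-to-population table (TSV)
#'
#' Two tab-separated columns, `sample_id` and `population`, with a header.
#'
#' @param path file path.
#' @return [read_population_spec()] returns a `population_spec`.
#' @export
read_population_spec <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  population_spec(df$sample_id, df$population)
}

#' @rdname read_population_spec
#' @param spec a `population_spec`.
#' @export
write_population_spec <- function(spec, path) {
  utils::write.table(spec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
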