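test_that("interval set algebra: merge, totals, overlap fractions", {
  iv <- interval_set(c("c", "c", "c"), c(0, 500, 5000), c(1000, 1500, 6000))
  m <- merge_intervals(iv)
  expect_equal(m$start, c(0, 5000))
  expect_equal(m$end, c(1500, 6000))
  expect_equal(interval_total_bp(iv), 2500)
  a <- interval_set("c", 100, 200)
  expect_equal(interval_overlap_fraction(a, interval_set("c", 0, 1000)), 1)
  expect_equal(interval_overlap_fraction(a, interval_set("c", 300, 400)), 0)
  expect_true(is.na(interval_overlap_fraction(interval_set(), a)))
  expect_error(interval_set("c", 10, 10), "half-open")
  # per-base bitmap oracle on random sets
  for (seed in 31:33) {
    sets <- withr::with_seed(seed, {
      mk <- function() {
        s <- sort(sample(0:999, 8))
        interval_set(rep("c", 8), s, s + sample(1:120, 8, TRUE))
      }
      list(a = mk(), b = mk())
    })
    bit <- function(x) {
      v <- logical(2000)
      for (i in seq_len(nrow(x))) v[(x$start[i] + 1):x$end[i]] <- TRUE
      v
    }
    ba <- bit(sets$a); bb <- bit(sets$b)
    expect_equal(interval_total_bp(sets$a), sum(ba))
    expect_equal(interval_overlap_fraction(sets$a, sets$b),
                 sum(ba & bb) / sum(ba))
  }
})

test_that("window mapper: perfect hits, novel sequence, SNP-rate identity", {
  sg <- simulate_genome_pair(length = 60000, n_insert = 1,
                             insert_len_range = c(4000, 4000),
                             snp_rate = 0.005, n_genes = 0, seed = 14)
  hits <- map_windows(sg$pair)
  ti <- sg$truth$specific_intervals
  core <- hits$start >= ti$start + 1000 & hits$end <= ti$end - 1000
  expect_true(all(hits$aligned_fraction[core] < 0.05))   # novel: no seeds
  outside <- hits$end <= ti$start | hits$start >= ti$end
  expect_true(all(hits$aligned_fraction[outside] > 0.95))
  # mean identity of non-novel windows tracks 1 - snp_rate
  id <- hits$identity[outside]
  n_bases <- sum(hits$end[outside] - hits$start[outside])
  se2 <- 2 * sqrt(0.005 * 0.995 / n_bases)
  expect_lt(abs(mean(id) - 0.995), se2 + 0.002)
  # self-mapping is perfect
  self <- map_windows(sg$pair, against = "self")
  expect_true(all(self$aligned_fraction == 1))
  expect_true(all(self$identity == 1))
})

test_that("classify_specific_windows applies the strict 20% rule", {
  mk_hits <- function(af, id) {
    data.frame(query_id = sprintf("w%d", seq_along(af)), chrom = "c",
               start = (seq_along(af) - 1) * 500,
               end = (seq_along(af) - 1) * 500 + 1000,
               aligned_fraction = af, identity = id,
               stringsAsFactors = FALSE)
  }
  other <- mk_hits(c(0.19, 0.20, 0.0, 0.5), c(1, 1, NA, 1))
  self <- mk_hits(c(1, 1, 1, 1), c(1, 1, 1, 1))
  spec <- classify_specific_windows(other, self)
  expect_equal(spec$start, c(0, 1000))               # 0.19 yes, 0.20 no
  # imperfect self-hit disqualifies
  self2 <- self; self2$identity[3] <- 0.99
  expect_equal(nrow(classify_specific_windows(other, self2)), 1L)
  # missing self record: excluded with a message
  expect_message(out <- classify_specific_windows(other, self[-1, ]),
                 "lack a self-hit")
  expect_false(0 %in% out$start)
  # identical genomes produce zero specific windows
  idp <- simulate_genome_pair(length = 30000, n_insert = 0, snp_rate = 0,
                              n_genes = 0, seed = 15)
  ho <- map_windows(idp$pair); hs <- map_windows(idp$pair, against = "self")
  expect_equal(nrow(classify_specific_windows(ho, hs)), 0L)
})

test_that("merge_specific_regions unions windows and totals bases", {
  w <- interval_set(c("c", "c"), c(0, 500), c(1000, 1500))
  mr <- merge_specific_regions(w)
  expect_equal(nrow(mr$intervals), 1L)
  expect_equal(mr$total_bp, 1500)
  expect_equal(merge_specific_regions(interval_set())$total_bp, 0)
})

test_that("gene_specific_by_overlap uses a strict >80% CDS rule", {
  genes <- gene_model_set(c("gFull", "gExact", "gLow"), rep("c", 3),
                          rep("+", 3), c(100, 1000, 2000), c(200, 1100, 2100))
  spec <- interval_set(rep("c", 3), c(100, 1000, 2000), c(200, 1080, 2010))
  flagged <- gene_specific_by_overlap(genes, spec)   # overlaps 1.0, 0.8, 0.1
  expect_equal(flagged, "gFull")
  expect_error(gene_specific_by_overlap(
    structure(data.frame(gene_id = "z", chrom = "c", strand = "+",
                         start = 1, end = 1 + 1e-9),
              class = c("gene_model_set", "data.frame")), spec), NA)
})

test_that("conservation categories are total, exclusive and match the rules", {
  expect_equal(categorize_gene_conservation(1, 1), "highly_conserved")
  expect_equal(categorize_gene_conservation(0.70, 0.95), "structural_variant")
  expect_equal(categorize_gene_conservation(0.45, 0.99), "specific")
  expect_equal(categorize_gene_conservation(1, 0.95), "mutated")
  expect_equal(categorize_gene_conservation(1, 0.89), "specific")
  expect_equal(categorize_gene_conservation(0.5, 0.90), "structural_variant")
  expect_equal(categorize_gene_conservation(0.6, NA), "specific")
  grid <- expand.grid(cov = seq(0, 1, by = 0.05), id = seq(0, 1, by = 0.05))
  cats <- categorize_gene_conservation(grid$cov, grid$id)
  expect_true(all(cats %in% c("highly_conserved", "mutated",
                              "structural_variant", "specific")))
  expect_equal(length(cats), nrow(grid))             # total: one per input
})

test_that("final_specific_genes is the set intersection of both methods", {
  expect_equal(final_specific_genes(c("a", "b"), c("c")), character(0))
  expect_equal(final_specific_genes(c("b", "a"), c("a", "b")), c("a", "b"))
})

test_that("pangene_classify follows the core/dispensable/singleton rules", {
  fam <- data.frame(
    gene_id = sprintf("g%d", 1:11),
    family_id = c(rep("famCore", 7), rep("famDisp", 3), "famSing"),
    genome = c(paste0("G", 1:7), "G1", "G2", "G3", "G5"),
    stringsAsFactors = FALSE)
  cls <- pangene_classify(fam, n_genomes = 7)
  got <- stats::setNames(cls$class, cls$family_id)
  expect_equal(got[["famCore"]], "core")
  expect_equal(got[["famDisp"]], "dispensable")
  expect_equal(got[["famSing"]], "singleton")
  fam$genome[1] <- ""
  expect_error(pangene_classify(fam, 7), "genome label")
})

test_that("estimate_genome_size divides retained k-mer mass by peak depth", {
  h <- structure(data.frame(multiplicity = c(1L, 2L, 30L),
                            count = c(5e6, 1e5, 1e8)),
                 k = 25L, class = c("kmer_histogram", "data.frame"))
  est <- estimate_genome_size(h, min_mult = 3L)
  expect_equal(as.numeric(est), 30 * 1e8 / 30)
  expect_equal(attr(est, "peak_depth"), 30L)
  expect_error(estimate_genome_size(h, min_mult = 50L), "min_mult")
})
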