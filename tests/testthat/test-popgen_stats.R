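test_that("nucleotide diversity: definition, edge cases, missing-data rule", {
  # two haplotypes differing at 3 of 100 sites
  gm <- genotype_matrix(rbind(rep(0L, 100), c(rep(1L, 3), rep(0L, 97))),
                        c("a", "b"), rep("1", 100), 1:100)
  expect_equal(nucleotide_diversity(gm, span_bp = 100), 0.03)
  # identical haplotypes
  gm0 <- genotype_matrix(matrix(0L, 3, 5), c("a", "b", "c"), rep("1", 5), 1:5)
  expect_equal(nucleotide_diversity(gm0, span_bp = 10), 0)
  # undefined cases
  expect_true(is.na(nucleotide_diversity(gm, span_bp = 0)))
  gna <- genotype_matrix(matrix(NA_integer_, 2, 3), c("a", "b"), rep("1", 3), 1:3)
  expect_true(is.na(nucleotide_diversity(gna, span_bp = 10)))
  # per-site n: a site called in only 2 of 4 haplotypes still contributes
  calls <- matrix(0L, 4, 1); calls[1, 1] <- 1L; calls[3:4, 1] <- NA
  g1 <- genotype_matrix(calls, letters[1:4], "1", 1L)
  expect_equal(nucleotide_diversity(g1, span_bp = 1), 2 * 1 * 1 / (2 * 1))
})

test_that("pi matches the brute-force pairwise oracle on random matrices", {
  for (seed in 1:10) {
    gm <- random_gm(8, 40, seed = seed)
    expect_equal(nucleotide_diversity(gm, span_bp = 40),
                 oracle_pi(gm$calls, 40), tolerance = 1e-12)
  }
})

test_that("Tajima's D: sign, undefined cases, and direct-formula oracle", {
  gm0 <- genotype_matrix(matrix(0L, 10, 4), sprintf("s%d", 1:10),
                         rep("1", 4), 1:4)
  expect_true(is.na(tajimas_d(gm0)))                 # S = 0 -> undefined
  calls <- matrix(0L, 10, 5)
  for (j in 1:5) calls[j, j] <- 1L                   # all singletons
  gms <- genotype_matrix(calls, sprintf("s%d", 1:10), rep("1", 5), 1:5)
  expect_lt(tajimas_d(gms), 0)
  for (seed in 1:10) {
    gm <- random_gm(10, 60, seed = 100 + seed)
    expect_equal(tajimas_d(gm), oracle_tajimas_d(gm$calls),
                 tolerance = 1e-10)
  }
})

test_that("Weir-Cockerham FST: fixation, no-differentiation, oracle", {
  mk <- function(k, n) data.frame(chrom = "1", pos = seq_along(k), k = k, n = n)
  # complete fixation
  r <- fst_weir_cockerham(mk(10L, 10L), mk(0L, 10L))
  expect_equal(r$per_site$fst, 1)
  expect_equal(r$fst, 1)
  # identical frequencies -> estimate <= 0, reported unclamped
  r2 <- fst_weir_cockerham(mk(c(4L, 6L), c(10L, 10L)), mk(c(4L, 6L), c(10L, 10L)))
  expect_lte(r2$fst, 0)
  # single site: multi-locus equals per-site
  r3 <- fst_weir_cockerham(mk(8L, 10L), mk(2L, 10L))
  expect_equal(r3$fst, r3$per_site$fst[1])
  o <- oracle_fst_wc(8, 10, 2, 10)
  expect_equal(r3$per_site$a[1], o$a, tolerance = 1e-12)
  expect_equal(r3$per_site$fst[1], o$fst, tolerance = 1e-12)
  # sites monomorphic across both populations are excluded
  r4 <- fst_weir_cockerham(mk(c(0L, 8L), c(10L, 10L)), mk(c(0L, 2L), c(10L, 10L)))
  expect_equal(r4$n_sites_used, 1L)
  # FST never exceeds 1
  for (seed in 1:20) {
    kk <- withr::with_seed(seed, list(k1 = sample(0:10, 5, TRUE),
                                      k2 = sample(0:10, 5, TRUE)))
    rr <- fst_weir_cockerham(mk(kk$k1, 10L), mk(kk$k2, 10L))
    if (rr$n_sites_used > 0) expect_lte(max(rr$per_site$fst, na.rm = TRUE), 1)
  }
})

test_that("ld_r2: perfect correlation, anti-correlation, D^2 oracle", {
  calls <- cbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L))
  gm <- genotype_matrix(calls, letters[1:4], rep("1", 3), 1:3)
  expect_equal(ld_r2(gm, 1, 2), 1)
  expect_equal(ld_r2(gm, 1, 3), 1)                  # r = -1 squares to 1
  gmono <- genotype_matrix(cbind(c(0L, 0L), c(0L, 1L)), c("a", "b"),
                           rep("1", 2), 1:2)
  expect_true(is.na(ld_r2(gmono, 1, 2)))
  for (seed in 1:10) {
    gm <- random_gm(12, 2, seed = 200 + seed)
    x <- gm$calls[, 1]; y <- gm$calls[, 2]
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    expect_equal(ld_r2(gm, 1, 2), oracle_r2(x, y), tolerance = 1e-12)
  }
})

test_that("filter_variants applies missingness, MAF, LD pruning in order", {
  # all monomorphic -> empty (MAF 0 fails '> 0.1')
  gm0 <- genotype_matrix(matrix(0L, 6, 8), sprintf("s%d", 1:6), rep("1", 8), 1:8)
  expect_equal(n_sites(filter_variants(gm0)), 0L)
  # duplicated column pair: exactly one survives
  col <- c(0L, 0L, 1L, 1L, 0L, 1L)
  gm1 <- genotype_matrix(cbind(col, col), sprintf("s%d", 1:6), rep("1", 2), 1:2)
  expect_equal(n_sites(filter_variants(gm1)), 1L)
  # random matrix vs the independent cascade oracle
  for (seed in 1:5) {
    gm <- random_gm(20, 200, seed = 300 + seed, missing_rate = 0.15)
    got <- filter_variants(gm, maf_min = 0.1, r2_max = 0.2, missing_max = 0.3)
    want <- oracle_filter(gm$calls, 0.1, 0.2, 0.3)
    expect_equal(got$pos, gm$pos[want])
  }
})

test_that("windowed_stat tiles chromosomes and conserves SNP counts", {
  gm <- random_gm(6, 50, seed = 11)                  # positions 10..500
  tr <- windowed_stat(gm, stat = "pi", window_size = 1000, step = 500,
                      chrom_len = c("1" = 2000))
  expect_equal(tr$start, c(0, 500, 1000))
  expect_equal(tr$end, c(1000, 1500, 2000))
  # empty window: NA value, 0 snps
  expect_equal(tr$n_snps[3], 0L)
  expect_true(is.na(tr$value[3]))
  # partition conservation with step == window
  tr2 <- windowed_stat(gm, stat = "tajimas_d", window_size = 100, step = 100)
  expect_equal(sum(tr2$n_snps), n_sites(gm))
  # terminal window covers a remainder not divisible by step
  tr3 <- windowed_stat(gm, stat = "pi", window_size = 1000, step = 500,
                       chrom_len = c("1" = 2100))
  expect_equal(tr3$start, c(0, 500, 1000, 1500))
  expect_equal(tr3$end[4], 2100)
  # track TSV round-trip
  p <- withr::local_tempfile(fileext = ".tsv")
  write_track(tr, p)
  expect_equal(read_track(p)$value, tr$value)
})

test_that("pi, D and FST are invariant to sample order and chrom relabeling", {
  gm <- random_gm(9, 30, seed = 55)
  perm <- withr::with_seed(1, sample(9))
  gmp <- subset_matrix(gm, samples = perm)
  expect_equal(nucleotide_diversity(gmp, span_bp = 30),
               nucleotide_diversity(gm, span_bp = 30))
  expect_equal(tajimas_d(gmp), tajimas_d(gm))
  gmr <- genotype_matrix(gm$calls, gm$sample_ids, rep("chrX", 30), gm$pos)
  expect_equal(tajimas_d(gmr), tajimas_d(gm))
  c1 <- site_counts(gm, 1:4); c2 <- site_counts(gm, 5:9)
  c1p <- site_counts(gmp, gm$sample_ids[1:4])
  c2p <- site_counts(gmp, gm$sample_ids[5:9])
  expect_equal(fst_weir_cockerham(c1, c2)$fst,
               fst_weir_cockerham(c1p, c2p)$fst)
})
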