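test_that("xpclr_config validates its grid and geometry", {
  expect_error(xpclr_config(sel_grid = c(0.01, 0.1)), "must contain 0")
  expect_error(xpclr_config(window_size = 10, step = 100), "window_size >= step")
  expect_error(xpclr_config(max_snps = 0), "max_snps")
})

test_that("estimate_omega: no-divergence limit, errors, drift monotonicity", {
  mk <- function(k, n) data.frame(chrom = "1", pos = seq_along(k), k = k, n = n)
  # p2 = p1 with n2 -> large: the corrected mean goes to ~0
  k <- c(2L, 5L, 8L)
  om <- estimate_omega(mk(k, 10L), mk(k * 1000L, 10000L))
  expect_lt(abs(om), 0.01)
  expect_error(estimate_omega(mk(c(0L, 10L), 10L), mk(c(0L, 10L), 10L)),
               "0 < p1 < 1")
  # self-consistency: estimate on K sites within 20% of a 10x-sites estimate
  sim_counts <- function(S, omega, seed) {
    withr::with_seed(seed, {
      p <- stats::runif(S, 0.1, 0.9)
      p2 <- pmin(pmax(stats::rnorm(S, p, sqrt(omega * p * (1 - p))), 0), 1)
      list(ref = data.frame(chrom = "1", pos = 1:S, k = round(p * 1000),
                            n = 1000L),
           qry = data.frame(chrom = "1", pos = 1:S,
                            k = stats::rbinom(S, 200L, p2), n = 200L))
    })
  }
  small <- sim_counts(400, 0.2, 31); big <- sim_counts(4000, 0.2, 32)
  om_s <- estimate_omega(small$ref, small$qry)
  om_b <- estimate_omega(big$ref, big$qry)
  expect_lt(abs(om_s - om_b) / om_b, 0.2)
  # doubling the split duration increases estimated omega (20-seed means)
  # moderate drift (T/N <= 0.1) keeps the estimator away from its boundary
  # saturation, where (p2 - p1)^2 censoring flattens the trend
  cfgS <- function(seed, gens) {
    sim_config(pop_size = 200L, seq_len = 20000L, split_gens = gens,
               burn_gens = 800L, mu = 2e-6, n_sample_ref = 40L,
               n_sample_query = 40L, seed = seed)
  }
  om_at <- function(gens) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_two_pop_sweep(cfgS(s, gens))
      cr <- site_counts(sim$matrix, zeasweep:::pop_samples(sim$pops, "ref"))
      cq <- site_counts(sim$matrix, zeasweep:::pop_samples(sim$pops, "query"))
      p1 <- cr$k / cr$n
      ok <- p1 > 0 & p1 < 1
      if (!any(ok)) return(NA_real_)
      estimate_omega(cr[ok, ], cq[ok, ])
    }, 0), na.rm = TRUE)
  }
  expect_gt(om_at(20L), om_at(10L))
})

test_that("window score is zero at equal frequencies and never negative", {
  cfg <- xpclr_config(rec_rate = 1e-6, ne = 500)
  # p2-hat = p1-hat exactly
  p1 <- c(0.2, 0.5, 0.7)
  sc <- xpclr_window_score(p1, k2 = c(2L, 5L, 7L), n2 = rep(10L, 3),
                           pos = c(100, 200, 300), center = 200,
                           omega = 0.05, config = cfg)
  expect_lt(sc$score, 1e-6)
  expect_equal(sc$s_hat, 0)
  # non-negativity on random windows
  for (seed in 1:10) {
    w <- withr::with_seed(seed, list(p1 = stats::runif(12, 0.05, 0.95),
                                     k2 = sample(0:20, 12, TRUE),
                                     pos = sort(stats::runif(12, 0, 5e4))))
    sc <- xpclr_window_score(w$p1, w$k2, rep(20L, 12), w$pos, 2.5e4,
                             omega = 0.3, config = cfg)
    expect_gte(sc$score, 0)
  }
  expect_error(xpclr_window_score(c(0, 0.5), c(1L, 1L), c(2L, 2L),
                                  c(1, 2), 1, 0.1, cfg), "strictly in")
})

test_that("scan weights, SNP cap and determinism behave as specified", {
  # five identical SNP columns -> each weight 1/5; independent columns -> 1
  col <- rep(c(0L, 1L), each = 10)
  base <- withr::with_seed(5, replicate(5, sample(rep(c(0L, 1L), each = 10))))
  calls <- cbind(col, col, col, col, col, base)
  gm <- genotype_matrix(calls, sprintf("s%02d", 1:20),
                        rep("1", 10), seq_len(10) * 100L)
  cfg <- xpclr_config(window_size = 2000, step = 2000, ne = 100,
                      r2_weight_threshold = 0.7, omega = 0.1)
  pops <- population_spec(gm$sample_ids, rep(c("ref", "query"), 10))
  # weights are internal to the scan; check them via the helper pathway
  r2 <- zeasweep:::ld_r2_matrix(calls)
  hit <- r2 >= 0.7; hit[is.na(hit)] <- FALSE; diag(hit) <- TRUE
  w <- 1 / rowSums(hit)
  expect_equal(unname(w[1:5]), rep(0.2, 5))
  # SNP cap: 80 sites capped to 50, identical choice under identical seed
  gm80 <- random_gm(12, 80, seed = 77)
  ps <- population_spec(gm80$sample_ids, rep(c("ref", "query"), 6))
  cfg80 <- xpclr_config(window_size = 1000, step = 1000, max_snps = 50L,
                        omega = 0.2, ne = 100, seed = 9L)
  r1 <- xpclr_scan(gm80, ps, cfg80)
  r2b <- xpclr_scan(gm80, ps, cfg80)
  expect_equal(r1$track$n_snps[1], 50L)
  expect_identical(r1$track, r2b$track)
  # role asymmetry: swapping reference and query changes scores
  sim <- simulate_two_pop_sweep(sim_config(pop_size = 100L, seq_len = 3e4L,
                                           split_gens = 40L, burn_gens = 400L,
                                           n_sample_ref = 15L,
                                           n_sample_query = 15L, seed = 12))
  cfgs <- xpclr_config(window_size = 10000, step = 5000, ne = 100,
                       rec_rate = 1e-6)
  fwd <- xpclr_scan(sim$matrix, sim$pops, cfgs, pops = c("ref", "query"))
  rev <- xpclr_scan(sim$matrix, sim$pops, cfgs, pops = c("query", "ref"))
  expect_false(isTRUE(all.equal(fwd$track$value, rev$track$value)))
})

test_that("larger omega never raises the score of sweep-like fixtures", {
  cfg <- xpclr_config(window_size = 20000, step = 2000, rec_rate = 1e-6,
                      ne = 500)
  for (f in 1:5) {
    w <- withr::with_seed(400 + f, {
      J <- 30
      p1 <- stats::runif(J, 0.05, 0.95)
      swept <- stats::rbinom(J, 1, 0.8)
      k2 <- ifelse(swept == 1,
                   ifelse(stats::runif(J) < p1, 20L, 0L),
                   stats::rbinom(J, 20, p1))
      list(p1 = p1, k2 = as.integer(k2), pos = sort(stats::runif(J, 0, 2e4)))
    })
    prev <- Inf
    for (om in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
      sc <- xpclr_window_score(w$p1, w$k2, rep(20L, 30), w$pos, 1e4,
                               omega = om, config = cfg)$score
      expect_lte(sc, prev + 1e-9)
      prev <- sc
    }
  }
})

test_that("xpclr result serializes with score and s_hat columns", {
  gm <- random_gm(12, 30, seed = 13)
  ps <- population_spec(gm$sample_ids, rep(c("ref", "query"), 6))
  res <- xpclr_scan(gm, ps, xpclr_config(window_size = 100, step = 100,
                                         omega = 0.2, ne = 100))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_xpclr_result(res, p)
  df <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_named(df, c("chrom", "start", "end", "n_snps", "score", "s_hat"))
  expect_true(all(df$score >= 0, na.rm = TRUE))
})
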