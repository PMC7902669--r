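#' Configuration for the two-population Wright-Fisher sweep simulator
#'
#' Defines the stated world of the synthetic genotype generator: a haploid
#' Wright-Fisher population at mutation-drift equilibrium splits into a
#' reference and a query population; optionally a beneficial mutation is
#' introduced into the query immediately after the split and conditioned to
#' (near-)fixation, emulating a completed selective sweep such as the one at
#' a kernel-starch locus in sweet corn versus a diverse field-corn panel.
#'
#' Defaults are chosen for testability of the downstream statistics, not for
#' demographic realism (the true history separating the emulated populations
#' is unknown): `pop_size` 500 haploids, locus of 100 kb, `mu` 5e-7 so the
#' equilibrium per-site diversity 2*N*mu = 5e-4 yields a few hundred sample
#' SNPs, `split_gens` 100 so neutral drift differentiation stays moderate
#' while an s = 0.1 sweep can still complete, and `rho` 1e-6 so that sweep
#' leaves a hitchhiking footprint (~ s / (rho * log(2*N*s)), about 20 kb)
#' both wide enough to cover many SNPs and narrow enough to localize inside
#' the locus.
#'
#' @param pop_size haploid individuals per population (N >= 2).
#' @param split_gens generations each population evolves after the split.
#' @param seq_len locus length in bp.
#' @param mu per-site per-generation mutation probability (finite sites; a
#'   repeat mutation toggles the allele, so sites stay biallelic).
#' @param rho per-adjacent-site per-generation recombination probability; each
#'   offspring is a single crossover with probability `rho * (seq_len - 1)`.
#' @param sel_coeff selection coefficient s of the beneficial allele
#'   (0 = neutral; haploid fitness 1 + s).
#' @param sweep_pos 1-based position of the selected site.
#' @param n_sample_ref,n_sample_query haplotypes sampled per population.
#' @param seed integer random seed; identical seeds give identical output.
#' @param burn_gens burn-in generations for the ancestral population
#'   (default 4 * pop_size, close to coalescent equilibrium).
#' @param retry_cap maximum number of seed-deterministic retries of the query
#'   trajectory when conditioning the sweep on near-fixation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(pop_size = 500L, split_gens = 100L, seq_len = 100000L,
                       mu = 5e-7, rho = 1e-6, sel_coeff = 0,
                       sweep_pos = seq_len %/% 2L,
                       n_sample_ref = 30L, n_sample_query = 30L,
                       seed = 1L, burn_gens = 4L * pop_size,
                       retry_cap = 1000L) {
  stopifnot_scalar(pop_size, "pop_size", min = 2)
  stopifnot_scalar(sel_coeff, "sel_coeff", min = 0, max = 1)
  stopifnot_scalar(mu, "mu", min = 0, max = 1)
  stopifnot_scalar(rho, "rho", min = 0, max = 1)
  stopifnot_scalar(sweep_pos, "sweep_pos", min = 1, max = seq_len)
  stopifnot_scalar(split_gens, "split_gens", min = 0)
  stopifnot_scalar(burn_gens, "burn_gens", min = 0)
  if (n_sample_ref > pop_size || n_sample_query > pop_size) {
    stop("sample sizes cannot exceed pop_size")
  }
  structure(list(pop_size = as.integer(pop_size),
                 split_gens = as.integer(split_gens),
                 seq_len = as.integer(seq_len), mu = mu, rho = rho,
                 sel_coeff = sel_coeff, sweep_pos = as.integer(sweep_pos),
                 n_sample_ref = as.integer(n_sample_ref),
                 n_sample_query = as.integer(n_sample_query),
                 seed = as.integer(seed), burn_gens = as.integer(burn_gens),
                 retry_cap = as.integer(retry_cap)),
            class = "sim_config")
}

#' Planted ground truth of a synthetic dataset
#'
#' @param sweep_pos 1-based position of the planted selected site (or NA).
#' @param fixed did the beneficial allele reach frequency >= 0.99 in the query
#'   population?
#' @param group_labels planted haplotype-group label per sample.
#' @param specific_intervals planted genome-specific intervals, an
#'   [interval_set()] (0-based half-open).
#' @param gene_categories named character vector: planted conservation
#'   category per gene id.
#' @return a `sim_truth` list.
#' @export
sim_truth <- function(sweep_pos = NA_integer_, fixed = NA,
                      group_labels = NULL, specific_intervals = NULL,
                      gene_categories = NULL) {
  structure(list(sweep_pos = sweep_pos, fixed = fixed,
                 group_labels = group_labels,
                 specific_intervals = specific_intervals,
                 gene_categories = gene_categories),
            class = "sim_truth")
}

# Evolve one haploid Wright-Fisher population for `gens` generations.
# `mat` is an N x S 0/1 integer matrix over tracked segregating positions.
# Lost columns are always pruned; columns fixed in this population are pruned
# (and the site's reference meaning flipped) only when `prune_fixed`, which is
# safe only before a population split.  If `sel_pos` is given, allele 1 there
# has haploid fitness 1 + s.  Returns list(mat, positions) or NULL when the
# selected allele is lost (early exit so sweep retries are cheap).
wf_evolve <- function(mat, positions, gens, N, L, mu, rho,
                      sel_pos = NA_integer_, s = 0, prune_fixed = TRUE) {
  p_rec <- min(1, rho * (L - 1))
  exp_mut <- as.double(N) * as.double(L)
  for (g in seq_len(gens)) {
    S <- length(positions)
    # resample parents (selection at the beneficial site, if tracked)
    if (!is.na(sel_pos) && s > 0) {
      sc <- match(sel_pos, positions)
      if (is.na(sc)) return(NULL)           # beneficial allele lost
      w <- 1 + s * mat[, sc]
      parents <- sample.int(N, N, replace = TRUE, prob = w)
    } else {
      parents <- sample.int(N, N, replace = TRUE)
    }
    prev <- mat
    mat <- prev[parents, , drop = FALSE]
    # single crossover per recombinant offspring
    if (p_rec > 0 && S > 0L) {
      nrec <- stats::rbinom(1L, N, p_rec)
      if (nrec > 0L) {
        rows <- sample.int(N, nrec)
        p2 <- sample.int(N, nrec, replace = TRUE)
        xs <- sample.int(L - 1L, nrec, replace = TRUE)
        for (r in seq_len(nrec)) {
          right <- positions > xs[r]
          if (any(right)) mat[rows[r], right] <- prev[p2[r], right]
        }
      }
    }
    # finite-sites mutation: a hit on a tracked site toggles the allele;
    # new sites are appended as a single block (one matrix copy per
    # generation, not one per mutation event)
    nmut <- stats::rbinom(1L, exp_mut, mu)
    if (nmut > 0L) {
      ind <- sample.int(N, nmut, replace = TRUE)
      pp <- sample.int(L, nmut, replace = TRUE)
      j <- match(pp, positions)
      for (m in which(!is.na(j))) {
        mat[ind[m], j[m]] <- 1L - mat[ind[m], j[m]]
      }
      if (anyNA(j)) {
        newpos <- unique(pp[is.na(j)])
        newmat <- matrix(0L, N, length(newpos))
        for (m in which(is.na(j))) {
          k <- match(pp[m], newpos)
          newmat[ind[m], k] <- 1L - newmat[ind[m], k]
        }
        positions <- c(positions, newpos)
        mat <- cbind(mat, newmat, deparse.level = 0)
      }
    }
    # prune monomorphic columns
    if (length(positions)) {
      cnt <- .colSums(mat, N, length(positions))
      drop <- if (prune_fixed) cnt == 0L | cnt == N else cnt == 0L
      if (!is.na(sel_pos)) drop[positions == sel_pos] <- FALSE
      if (any(drop)) {
        mat <- mat[, !drop, drop = FALSE]
        positions <- positions[!drop]
      }
    }
  }
  list(mat = mat, positions = positions)
}

#' Simulate two diverged populations with an optional completed sweep
#'
#' Forward haploid Wright-Fisher simulation: an ancestral population is burnt
#' in for `burn_gens` generations, splits into a reference and a query
#' population which then evolve independently for `split_gens` generations.
#' If `sel_coeff > 0` a beneficial mutation is planted at `sweep_pos` in one
#' query haplotype immediately after the split; query trajectories are re-run
#' with a deterministic retry counter mixed into the seed until the allele
#' reaches frequency >= 0.99 in the query population (completed sweep), up to
#' `retry_cap` retries.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (a [genotype_matrix()] of the sampled
#'   haplotypes, segregating sites only), `truth` (a [sim_truth()]), and
#'   `pops` (a [population_spec()] labelling samples `"ref"` / `"query"`).
#' @examples
#' sim <- simulate_two_pop_sweep(sim_config(pop_size = 50, seq_len = 5000,
#'                                          split_gens = 20, seed = 42))
#' sim$matrix
#' @export
simulate_two_pop_sweep <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$pop_size; L <- config$seq_len
  anc <- with_seed(mix_seed(config$seed, 11L), {
    wf_evolve(matrix(integer(0), N, 0), integer(0), config$burn_gens,
              N, L, config$mu, config$rho, prune_fixed = TRUE)
  })
  ref <- with_seed(mix_seed(config$seed, 12L), {
    wf_evolve(anc$mat, anc$positions, config$split_gens,
              N, L, config$mu, config$rho, prune_fixed = FALSE)
  })
  fixed <- NA
  if (config$sel_coeff > 0) {
    qry <- NULL
    for (r in seq_len(config$retry_cap) - 1L) {
      cand <- with_seed(mix_seed(config$seed, 1000L + r), {
        qmat <- anc$mat; qpos <- anc$positions
        j <- match(config$sweep_pos, qpos)
        if (is.na(j)) {
          qpos <- c(qpos, config$sweep_pos)
          qmat <- cbind(qmat, integer(N), deparse.level = 0)
          j <- length(qpos)
        }
        qmat[sample.int(N, 1L), j] <- 1L
        wf_evolve(qmat, qpos, config$split_gens, N, L, config$mu, config$rho,
                  sel_pos = config$sweep_pos, s = config$sel_coeff,
                  prune_fixed = FALSE)
      })
      if (!is.null(cand)) {
        j <- match(config$sweep_pos, cand$positions)
        if (!is.na(j) && mean(cand$mat[, j]) >= 0.99) { qry <- cand; break }
      }
    }
    if (is.null(qry)) {
      stop(sprintf(paste("beneficial allele failed to reach frequency 0.99",
                         "within the retry cap of %d trajectories"),
                   config$retry_cap))
    }
    fixed <- TRUE
  } else {
    qry <- with_seed(mix_seed(config$seed, 1000L), {
      wf_evolve(anc$mat, anc$positions, config$split_gens,
                N, L, config$mu, config$rho, prune_fixed = FALSE)
    })
  }
  idx <- with_seed(mix_seed(config$seed, 13L), {
    list(ref = sample.int(N, config$n_sample_ref),
         qry = sample.int(N, config$n_sample_query))
  })
  all_pos <- sort(unique(c(ref$positions, qry$positions)))
  nr <- config$n_sample_ref; nq <- config$n_sample_query
  calls <- matrix(0L, nr + nq, length(all_pos))
  if (length(ref$positions)) {
    calls[seq_len(nr), match(ref$positions, all_pos)] <-
      ref$mat[idx$ref, , drop = FALSE]
  }
  if (length(qry$positions)) {
    calls[nr + seq_len(nq), match(qry$positions, all_pos)] <-
      qry$mat[idx$qry, , drop = FALSE]
  }
  seg <- .colSums(calls, nrow(calls), ncol(calls))
  keep <- seg > 0L & seg < nrow(calls)
  calls <- calls[, keep, drop = FALSE]
  all_pos <- all_pos[keep]
  ids <- c(sprintf("ref_%03d", seq_len(nr)), sprintf("query_%03d", seq_len(nq)))
  gm <- genotype_matrix(calls, ids,
                        chrom = rep("1", length(all_pos)), pos = all_pos,
                        ref = rep("A", length(all_pos)),
                        alt = rep("T", length(all_pos)))
  list(matrix = gm,
       truth = sim_truth(sweep_pos = if (config$sel_coeff > 0) config$sweep_pos
                                     else NA_integer_,
                         fixed = fixed),
       pops = population_spec(ids, rep(c("ref", "query"), c(nr, nq))))
}
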