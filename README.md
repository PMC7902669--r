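# zeasweep

Population-genomic selective-sweep and comparative-genome analysis for
maize panels.

`zeasweep` implements, as a tested R pipeline, the chain of computations
used to characterize a sweet-corn genome against diverse field-corn
panels:

- **Diversity and differentiation**: nucleotide diversity (π), Tajima's
  *D* in sliding windows, haploid Weir–Cockerham *F*<sub>ST</sub> (per-SNP
  and ratio-of-sums), LD *r*², and the missingness → MAF → LD-pruning
  variant filter cascade.
- **XP-CLR sweep scan**: a cross-population composite likelihood ratio
  contrasting a deterministic-hitchhiking sweep model (escape probability
  *c* = 1 − (2*N*<sub>e</sub>*s*)<sup>−d/s</sup>) against censored-normal
  drift, with the protocol's 50-SNP window cap and *r*² ≥ 0.7
  down-weighting of clustered SNPs.
- **Sweep calling**: LOESS-style smoothing, nearest-rank top-1% empirical
  thresholds, region merging, and candidate-gene annotation by CDS
  overlap.
- **Haplotype-locus analysis** (*su1*-style): pairwise SNP-count distance
  matrices, k-means haplotype grouping, per-group π, JC69 distances, and
  Saitou–Nei neighbor-joining trees with outgroup rooting.
- **Genome comparison**: genome-specific sequence windows (aligned
  fraction < 20% to the comparator, perfect self-map), dual-method
  specific-gene detection, conservation categories from (coverage,
  identity), pan-gene core/dispensable/singleton classes, TE-overlap
  fractions, and k-mer genome-size estimation.
- **Synthetic data with planted truth**: forward Wright–Fisher
  two-population simulations (optionally conditioned on a completed
  sweep), two-haplotype-group locus sets, genome pairs with planted
  insertions and categorized genes, and k-mer histograms — so every stage
  is testable offline.

The headline quantities of the source study (genome-wide *F*<sub>ST</sub>,
per-haplotype-group π, Mb of specific sequence) require external panels
and assemblies; this package validates the *methods* against planted
ground truth and brute-force oracles instead.  See
`vignettes/zeasweep-methods.Rmd` for the models, parameter defaults and
their rationale, and known limitations.

## Worked example: localize a planted sweep

```r
library(zeasweep)
# simulate a completed sweep (s = 0.1) in the query population
sim <- simulate_two_pop_sweep(sim_config(seed = 42, sel_coeff = 0.1))
sim$matrix
#> <genotype_matrix> 60 haplotypes x 336 biallelic sites on 1 contig(s)

# scan with XP-CLR: reference supplies baseline frequencies,
# query is the population scanned for sweeps
cfg <- xpclr_config(window_size = 20000, step = 2000,
                    rec_rate = 1e-6, ne = 500)
res <- xpclr_scan(sim$matrix, sim$pops, cfg,
                  pops = c("ref", "query"), chrom_len = c("1" = 1e5))
res
#> <xpclr_result> 41 windows, omega = 0.1346, max score = 46.421

# call candidate sweep regions from the empirical top 1%
thr <- empirical_top_fraction(res$track, 0.01)
regions <- call_sweep_regions(res$track, thr)
regions[, c("chrom", "start", "end", "peak", "n_windows")]
#>   chrom start   end     peak n_windows
#> 1     1 30000 50000 46.42098         1

c(planted_sweep_at = sim$truth$sweep_pos)
#> planted_sweep_at
#>            50000
```

The single called region (peak window [30 kb, 50 kb), score 46.4) abuts
the planted selected site at 50 kb: the scan localized the sweep.  `omega`
is the genome-wide drift variance scale estimated from the data; scores
are 2·(max<sub>s</sub> ℓ(s) − ℓ(0)) and therefore non-negative, with 0
meaning "drift explains this window at least as well as any sweep".

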