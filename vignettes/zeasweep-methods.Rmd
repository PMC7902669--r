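---
title: "Models and methods in zeasweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in zeasweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sweet corn differs from field corn through strong recent selection at a
handful of starch-pathway loci and at loci affecting plant architecture and
flowering.  Characterizing that history from SNP panels involves a standard
chain of population-genomic computations — windowed nucleotide diversity and
Tajima's $D$, Weir–Cockerham $F_{ST}$, a cross-population composite
likelihood ratio (XP-CLR) sweep scan, single-locus haplotype-group analysis —
plus comparative-genomic procedures that classify sequence and genes of a
new assembly against comparator genomes and a pan-gene panel.  `zeasweep`
implements that chain as a tested, reusable pipeline, with forward
Wright–Fisher simulators that generate every input with planted ground
truth, so each stage can be validated without any external download.

## Population-genetic statistics

All statistics operate on a `genotype_matrix`: haplotypes × biallelic SNP
sites.  Diploid VCF input is split into two haplotypes per sample on read;
inbred lines genotyped by GBS behave as haploids, which is why the package
has no heterozygosity component anywhere (the Open Question of how the
source pipeline handled residual heterozygous calls is resolved here as a
documented haploid-split rule).

- **Nucleotide diversity.**  $\pi = \sum_s 2 k_s (n_s - k_s) / (n_s (n_s -
  1)) / L$ with per-site derived counts $k_s$, called-haplotype counts
  $n_s$, and span $L$ in bp.  Pairwise-complete over missing data.
- **Tajima's $D$.**  Standard 1989 normalization ($a_1, a_2, b_1, b_2, c_1,
  c_2, e_1, e_2$) computed from the nominal subset size; undefined (NA, not
  an error) when no site segregates.
- **$F_{ST}$.**  Haploid Weir–Cockerham analysis of variance: per site
  $a = (\mathrm{MSB} - \mathrm{MSW}) / n_c$, $b = \mathrm{MSW}$, estimate
  $a/(a+b)$; multi-locus estimate as the ratio of sums $\sum a / \sum
  (a+b)$, the standard Weir–Cockerham practice.  Both the ratio-of-sums and
  the mean of per-site values are reported because the source text does not
  say which produced its genome-wide figure; ratio-of-sums is the default.
  Values are reported unclamped, so slightly negative estimates are visible
  evidence of "no differentiation beyond sampling".
- **Variant filtering.**  Missingness strictly below 30%, then minor allele
  frequency strictly above 0.1, then greedy left-to-right LD pruning that
  drops the right member of any pair with $r^2 \ge 0.2$ within a sliding
  50-SNP window.  The strictness of each inequality follows the retained-
  variant phrasing of the protocol; the 50-SNP pruning window is a default
  of this package (none is stated in the protocol).
- **Windows** are anchored at coordinate 0 of each chromosome, 0-based
  half-open, with a shorter terminal window covering any remainder.
  Anchoring is a package choice; the protocol does not state one.

## The XP-CLR model

The scan contrasts, per window, a sweep model of query-population allele
frequencies against pure drift, composite across SNPs:

$$\ell(s) = \sum_j w_j \log \int_0^1 f_s(x \mid p_{1j}, \omega, d_j)\,
\mathrm{Binom}(k_j \mid n_j, x)\, dx, \qquad
\mathrm{score} = 2\,[\max_s \ell(s) - \ell(0)].$$

- **Neutral density** ($s = 0$): Normal$(p_1, \omega\, p_1 (1 - p_1))$
  censored to $[0,1]$, censored mass sitting as point masses on the
  boundaries.  $\omega$ is the genome-wide drift scale, estimated by the
  method of moments $\omega = \mathrm{mean}\big[(\hat p_2 - \hat p_1)^2 /
  (\hat p_1(1-\hat p_1)) - 1/n_2\big]$ over sites polymorphic in the
  reference.
- **Sweep density** ($s > 0$): a lineage escapes the sweep with probability
  $c = 1 - (2 N_e s)^{-d/s}$ (clamped to $[0,1]$), $d$ the genetic distance
  from the window center ($d = \texttt{rec\_rate} \cdot |pos -
  \mathrm{center}|$ Morgans).  Escaped mass keeps the drift-smoothed
  neutral density; swept mass goes to fixation with probability $p_1$ and
  loss otherwise, **broadened by the same censored-normal drift noise**
  (Normal centred at the boundary with variance $\omega p_1 (1-p_1)$).
  The broadening matters: with pure point masses at 0/1 the sweep model
  assigns zero likelihood to any query-polymorphic SNP, and genuinely swept
  windows — which always retain some escaped polymorphism — score zero.
- **Numerics.**  The interior integral uses a fixed 64-point midpoint rule;
  likelihoods are floored at $10^{-300}$ before logs; the grid of selection
  coefficients is $\{0\} \cup$ 10 log-spaced points in $[10^{-4}, 0.5]$ and
  always contains 0, so the score is non-negative by construction and ties
  resolve to $\hat s = 0$.
- **Weights.**  $w_j = 1/m_j$ where $m_j$ counts the window's SNPs (itself
  included) whose $r^2$ with SNP $j$ **in the reference population** is at
  least 0.7 — the down-weighting of clustered, correlated SNPs.  Windows
  with more than 50 SNPs are thinned by seeded uniform subsampling.
- This is a self-contained formulation in the spirit of the original
  XP-CLR; numeric agreement with the original binary is not a goal, and the
  package is validated by property-based acceptance (localization power,
  nesting, calibration) instead.  `ne` (default $10^4$; set to the true
  population size in simulations) and `rec_rate` (default 1 cM/Mb) convert
  physical to genetic distance; a genetic map can be emulated only through
  a constant rate here.

## Sweep calling

Smoothed Tajima's $D$ uses degree-1 local regression with tricube weights
per chromosome, evaluated at window midpoints; undefined windows are
excluded from fitting and stay undefined; chromosomes with fewer than three
defined windows pass through unsmoothed with a warning (span default 0.05).
Candidate thresholds use the nearest-rank quantile
($\lceil (1-f) n \rceil$-th order statistic), so the threshold is always an
observed score.  Candidate windows merge when overlapping or within one
step (default); each region records its peak score and the genes whose CDS
overlaps it (half-open intersection — a CDS that merely abuts a region
boundary is not attached).  An optional intersection with the sign of
smoothed $D$ is deliberately not applied by default: the source protocol
overlapped the two signals visually, not formally.

## Haplotype-group analysis at a locus

Pairwise distances are SNP counts over pairwise-complete sites.  K-means
(Lloyd, best of `n_init = 10` seeded restarts) runs on the raw 0/1 vectors
— not on the distance matrix — with missing calls imputed to the site mean
for clustering only; distances are never imputed.  Rows are put in a
canonical content order before clustering so the partition is invariant to
input sample order, and labels are canonicalized by group size (largest
group = 1).  JC69 distances use the closed form
$d = -\tfrac34 \ln(1 - \tfrac43 p)$, undefined at saturation
($p \ge 3/4$).  Neighbor joining is the standard Saitou–Nei algorithm with
the Q-criterion; ties resolve to the lexicographically smallest label pair,
so reconstruction is deterministic; negative branch lengths are clamped to
zero with the deficit moved to the sister branch, conserving path lengths;
outgroup rooting bisects the outgroup's terminal edge (the protocol names
the rooting taxon but not the placement).

## Genome comparison

A minimal internal mapper (exact 31-mer seeding, per-diagonal
maximum-scoring ungapped runs with match $+1$ / mismatch $-4$, greedy
chaining of query-disjoint runs across diagonals) supplies the
(coverage, identity) pair that all classification rules consume; externally
computed hit tables in the same schema can be substituted, which keeps the
classification logic testable without wrapping an external aligner.
Chaining is what lets a spliced CDS (exons on different target diagonals)
or a window interrupted by an insertion still report its full aligned
fraction.  The $-4$ mismatch penalty keeps runs from drifting past exon
boundaries on short chance matches, which would otherwise contaminate the
exact `identity == 1` boundary of the highly-conserved category.

Classification boundaries are strict exactly where the protocol's wording
is strict: a window is *specific* iff its aligned fraction to the
comparator is $< 0.20$ **and** it maps back onto its own genome with
coverage and identity exactly 1; a gene is specific by overlap iff
$> 80\%$ of CDS bases lie in specific sequence; conservation categories
partition $[0,1]^2$ as highly-conserved (1, 1), mutated (coverage 1,
identity $[0.90, 1)$), structural-variant (coverage $[0.50, 1)$, identity
$\ge 0.90$), else specific; the final specific-gene set is the
intersection of the two methods.  Pan-gene families are core when present
in all genomes, singleton in exactly one, else dispensable.  Genome size is
the retained k-mer mass divided by the modal multiplicity at or above the
noise cutoff (default 3).

## The synthetic world: what it emulates, and what it does not

`simulate_two_pop_sweep` is a forward haploid Wright–Fisher model:
burn-in of $4N$ generations from a monomorphic start (better than 98% of
equilibrium diversity), a split into reference and query, finite-sites
mutation (re-mutation toggles, keeping sites biallelic as every downstream
statistic assumes), single-crossover recombination with probability
$\rho\,(L-1)$ per offspring, and optional selection at one site with
haploid fitness $1+s$, conditioned on reaching frequency $\ge 0.99$ by
sampling time through capped (1000), seed-deterministic retries of the
query trajectory only.

Defaults — $N = 500$, $L = 100$ kb, $\mu = 5\times10^{-7}$,
$\rho = 10^{-6}$, 100 post-split generations, 30+30 sampled haplotypes —
were frozen during pilot calibration, before the acceptance tests were
written, with this reasoning: $2N\mu = 5\times10^{-4}$ per-site diversity
gives a few hundred sample SNPs on the locus (maize diversity is higher
still, but desk-scale runtimes bound $N\mu L$); 100 generations of split
keeps neutral drift differentiation moderate while an $s = 0.1$ sweep
(fixation time $\approx (2/s)\ln 2Ns \approx 90$ generations) can still
complete; and $\rho = 10^{-6}$ puts the hitchhiking footprint
$s/(\rho \ln 2Ns) \approx 20$ kb comfortably inside the locus yet wide
enough to cover many SNPs.  The demographic history separating real sweet
corn from the diverse panel is unknown and not modeled; a green test
establishes that the pipeline recovers planted truth in this world, not
that the world matches maize history.  Features of real data deliberately
absent: diploidy and phasing error, genotyping error and ascertainment,
variable recombination and mutation rates, gene conversion, population
structure within panels, and linked background selection.

The haplotype-group generator plants two consensus sequences differing at
exactly `n_diff` uniform sites with independent per-site divergence off
each consensus; defaults mirror the emulated design (114 vs 1065 samples,
165 differentiating SNPs over 11,598 bp, the minor group more diverse).
The genome-pair generator plants insertions of *novel random* sequence —
not duplications, so the mapper cannot spuriously place them — and one
gene per conservation category per insertion, with conserved CDS kept
SNP-free and mutated CDS given a forced ~5% substitution rate that stays
15 bp clear of exon edges (an ungapped aligner must still see full
coverage; identity below 1 is the planted signal).

## Acceptance-test design choices

Two choices in `test-acceptance.R` deserve explanation.  The sweep scan in
the power study uses 20 kb windows with a 2 kb step, matched to the ~20 kb
simulated footprint rather than the 50 kb/100 bp genome-scale settings,
which on a 100 kb locus would make windows nearly global.  And the
neutral-specificity arm takes its top-1% threshold from the window scores
pooled across the 20 neutral replicates — the analogue of a genome-wide
empirical distribution; a per-replicate top-1% on ~41 windows degenerates
to "the single maximum window", whose 20 kb span covers a fifth of the
locus by chance alone.

## Known limitations

The mapper is ungapped (indels inside an aligned run break it into chained
fragments, slightly deflating coverage); region recall at insertion edges
is bounded by the 1000/500 window tiling (about ±300 bp per edge); the
XP-CLR likelihood treats SNPs as conditionally independent given the
weights, as composite likelihood always does; `estimate_omega` saturates
when drift pushes query frequencies against the boundaries ($T/N \gtrsim
0.4$), and a completed sweep inside a short simulated locus inflates it
relative to a genuinely genome-wide estimate.  Scores from scans with
swapped population roles are not comparable: the reference supplies the
baseline frequencies and the query is the population scanned for sweeps.
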