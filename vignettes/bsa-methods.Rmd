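---
title: "Methods: pooled-sequencing association mapping with bsascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-sequencing association mapping with bsascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The design the package models

Bulked segregant analysis read out by whole-genome sequencing (Seq-BSA,
also called QTL-seq) maps a quantitative trait locus without genotyping a
whole population individual by individual. From a biparental population of
recombinant inbred lines (RILs), the two phenotypic tails are pooled — here
20 cold-tolerant lines with a seed-set ratio (PSST) of at least 0.90 and 20
cold-sensitive lines at or below 0.63 — and each pool's DNA is sequenced as
one sample. At a SNP where the parents carry different alleles, reads from
a pool estimate the pool's allele frequency. Far from any trait locus both
pools are random draws of lines, so both frequencies hover around 1/2; at a
locus that helped a line into its tail, the two pools diverge.

`bsascan` implements the two standard pool-contrast statistics:

* **SNP-index.** For each pool, the fraction of reads carrying the
  tolerant-parent allele: 0 when all reads are the sensitive parent's, 1
  when all are the tolerant parent's. The scan statistic is
  `delta = index(T-pool) - index(S-pool)`, positive at a tolerance locus.
  The wording "subtract one pool's index from the other" is ambiguous in
  prose; the boundary conditions (sensitive parent gives 0, tolerant parent
  gives 1) together with a positive association threshold at the tolerant
  QTL fix the orientation used here.
* **Euclidean distance (ED).** The distance between the pools' four base
  frequency vectors,
  `ED = sqrt(sum_b (f_T(b) - f_S(b))^2)` over b in {A, C, G, T},
  raised to a power k (default 5) to suppress background relative to
  peaks. ED is symmetric in the pools and bounded by `sqrt(2)`, attained
  exactly when the pools are fixed for different bases. The full four-term
  form is evaluated even though biallelic sites have two zero terms, for
  fidelity and so multiallelic inputs would extend naturally.

Both statistics are smoothed with an unweighted sliding-window mean, 1 Mb
windows advancing in 10 kb steps, anchored at position 1 of each
chromosome. Windows with fewer than `min_snps` usable sites are flagged
missing rather than reported as zero — the scan must distinguish "no
signal" from "no data". Whether depth-weighting the window mean would be
preferable is genuinely open; the unweighted mean was chosen because it is
the common convention and keeps the window statistic independent of the
depth model.

## Thresholds

Two thresholding routes are exposed, one per statistic.

**Delta(SNP-index): Monte-Carlo null interval.** Under the no-QTL null each
pooled RIL carries the tolerant allele with probability 1/2, so a replicate
draws a pool frequency `p = Binomial(20, 1/2)/20` per pool, then read
counts `Binomial(depth, p)` at the pool's depth, and records delta. The
interval is the pair of empirical tail quantiles at the requested
confidence (default 99%). Bounds straddle zero and tighten as pool size or
depth grow. A window is called significant when its mean delta lies
strictly above the upper bound. The published analysis this package
follows reported a delta threshold of 0.9532 without its confidence level;
rather than hard-code that number, the package always recomputes a
depth-specific interval at a configurable confidence.

**ED^k: moments of the windowed background.** The published ED threshold
(3.82) is likewise reported without a derivation rule, so the package
defaults to `mean + 3 SD` of the non-missing windowed ED^k values, with
the sample (n-1) SD; the population-SD variant and an empirical-quantile
rule are available (`ed_threshold()`). Ties at the ED threshold count as
significant (`>=`); the delta rule is strict (`>`), since the bound itself
is a null quantile.

## Regions, genes and the QTL interval

Significant windows are unioned into runs; runs separated by at most one
window step are merged; bounds are rounded outward to the 10 kb grid on
which such regions are conventionally tabulated, and region size is
reported as `end - start` on that grid (the convention that reproduces the
published region sizes exactly). Region calling is idempotent — merging
already-merged regions changes nothing — and an empty scan yields an empty
region list, not an error.

Gene content is counted as any 1-bp overlap between a gene model (from
GFF3) and the region. A marker-delimited QTL interval is converted to
physical coordinates in two conventions: `outer` (left marker start to
right marker end — the span usually quoted for the interval itself) and
`left_starts` (left marker start to right marker start — the tighter edge
used when intersecting with an adjacent scan region). Intersection with
the scan regions defaults to `union_span`: the called regions on the
chromosome are first collapsed to their overall span, bridging the small
gaps between adjacent called regions, then clipped to the interval. That
is the convention under which the published 1.81 Mb refined interval
arises from the published region table and marker coordinates; `strict`
per-region clipping is also provided.

## The simulator: what it emulates and what it does not

The simulator is the package's test bed: it generates data with exactly
the statistical structure the analysis assumes, so every claim the test
suite makes about recovery or calibration is a claim about that structure.

* **Population.** 190 lines by single seed descent from a biparental F1,
  selfed to F7. Meioses recombine under Haldane's map function by default —
  its no-interference assumption matches the independent-interval Markov
  chain the generator uses exactly, with closed-form crossover
  probabilities; Kosambi's inverse is available as an alternative distance
  scale, though the chain still draws intervals independently, so true
  crossover interference is not simulated under either option. Residual
  heterozygosity halves each generation (about 1.6% of
  sites at F7); by default lines are then idealized to full homozygosity so
  pool frequencies are exact 0/1 dosages, which keeps the delta null model
  exact. Tracking heterozygotes is available (`collapse_het = FALSE`).
* **Genome.** 12 chromosomes of 25 Mb with 2000 sites each — a rice-like
  chromosome count at a site density chosen for fast repeated simulation.
  The uniform recombination rate defaults to 7.85 cM/Mb so the synthetic
  genome totals about 2355 cM, the length of the dense SSR linkage map of
  the study population this package models.
* **Phenotype.** One planted additive QTL:
  `phenotype = 0.755 +/- 0.165 + Normal(0, 0.05)`, clamped to [0, 1], so
  the homozygote class means sit at the two parent means (0.59 and 0.92).
  Minor QTLs are not planted by default; the single-major-QTL setting is
  the regime the pool design is meant to detect.
* **Pools and reads.** The phenotypic tails are pooled (20 + 20 at cutoffs
  0.90/0.63, falling back to extreme ranks with a warning if a tail is
  short; ties resolve from opposite ends of the id order so the pools can
  never collide). Reads are equal-contribution binomial draws at
  Poisson-distributed per-site depth, 31x and 45x for the two pools.
  Unequal DNA contribution per line, sequencing error, alignment artifacts
  and duplicate reads are *not* modelled — so a pass here shows the
  statistics and thresholds behave correctly under the idealized sampling
  model, not that any real library preparation is free of artifacts.

All generator stages are deterministic given their seed; the experiment
wrapper derives stage seeds from one master seed.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive throughout; BED output converts to
  0-based half-open.
* A pool with zero (or sub-`min_depth`, default 4) reads at a site makes
  that site's statistics missing, never zero; the site still counts toward
  window occupancy.
* Descriptive statistics use the sample SD, adjusted Fisher-Pearson
  skewness and bias-adjusted excess kurtosis (normal gives 0); the
  conventions ride along as metadata because moment conventions differ
  between common software packages.
* The parent comparison is the equal-variance Student t-test (Welch by
  flag). Two constant, equal groups report t = 0 and no stars, flagged
  degenerate; two constant, separated groups report infinite t and `**`.
* Relative expression averages replicate Ct values per gene before forming
  `dCt` (the mean-Ct convention); per-replicate pairing first is available
  and coincides on balanced designs. Replicate SD is propagated on the
  `ddCt` scale, where it is additive.
* Haplotype groups are labelled from the parents (sensitive parent's
  haplotype = HapI, tolerant = HapII) and then by descending group size;
  labels are invariant to input order.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on generated or
packaged plain-text inputs: oracle comparisons use 10,000 random sites,
null calibration uses 10,000 Monte-Carlo replicates at the 20/20, 31x/45x
design, and planted-QTL recovery uses 50 independent experiments on the
default 12 x 25 Mb genome. These sizes give comfortable statistical
resolution for the properties tested while keeping a full run fast on one
CPU.

## Known limitations

* The window mean is unweighted; very uneven depth could justify
  depth-weighting.
* The ED threshold rule is a background-moments heuristic; it is exposed
  precisely because no published derivation exists to reproduce.
* The simulator's idealizations listed above: equal DNA contribution,
  no sequencing error, no residual heterozygosity by default, uniform
  recombination, a single planted QTL.
* Loess-style curve fitting of the per-site statistics (sometimes drawn
  through scan figures) is not implemented; the sliding-window mean is the
  only smoother.
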