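---
title: "Dating chromosomal inversions with blockwise site frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating chromosomal inversions with blockwise site frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invdemog)
library(dplyr)
```

## The question and the model

When two sister species differ by alternatively fixed chromosomal
inversions, the inversions' age relative to the species split separates
competing speciation scenarios.  If an inversion arose after speciation,
its estimated divergence time should match the colinear background
(`T_inv = T_col`) while its long-term effective migration is reduced
(`M_inv < M_col`); if the inversion was already segregating in the common
ancestor, its divergence time predates the background (`T_inv > T_col`).
Telling these apart requires fitting an explicit demographic model to
inverted and colinear parts of the genome separately.

`invdemog` implements the full chain of analysis for two diploid
population samples:

1. summarize genotypes as the **blockwise site frequency spectrum
   (bSFS)** — for each heterospecific pair of diploid genomes, cut the
   callable sequence into blocks of a fixed number of callable sites
   (64 by default) and record the joint counts of the four folded
   mutation types per block: `hetA` (heterozygous only in species A),
   `hetB`, `hetAB` (heterozygous in both for the same two alleles) and
   `fixed` (opposite homozygotes);
2. compute the exact probability of every (truncated) block
   configuration under a **strict divergence (DIV)** or **unidirectional
   isolation-with-migration (IM)** history;
3. maximize the **composite log-likelihood** `lnCL = sum_config n *
   log P(config)` over the demographic parameters;
4. attach uncertainty and significance via a **parametric bootstrap**,
   and test inversion divergence against a **gene-conversion-only
   simulation null**.

The demographic parameters are the diploid effective sizes `Ne_A`,
`Ne_B`, `Ne_anc`, the split time `t` (generations; with a generation
time of 1 year, also years), and the per-lineage per-generation
migration probability `m`.  Reported scaled quantities follow the
conventions `M = 2 * Ne_recipient * m` and `T = t / (2 * Ne_ref)`, and the
total probability that a lineage sampled in the recipient species traces
back through migration is `1 - exp(-T * M)`.

## The probability engine

The bSFS likelihood needs `P(hetA = i, hetB = j, hetAB = k, fixed = l)`
for one pair of diploids, i.e. four sampled lineages.  Blocks are assumed
to be free of internal recombination with a constant mutation rate `mu`
(2.8e-9 per site per generation by default), so mutation counts are
Poisson given the branch lengths of the four-lineage genealogy, with each
branch classified by the leaves it subtends.

The engine integrates the structured coalescent as a finite
continuous-time Markov chain whose state is the lineage partition, the
deme of each lineage (before the split, looking backwards) and the
truncated mutation counts per class ("Poissonization": mutations are
events of the chain, so no genealogy integration is left to do).  Two
phases are composed:

* **migration phase** (scaled duration `T`): coalescence within each
  deme, unidirectional migration (backwards, lineages sampled in the
  recipient species jump into the source species) and mutation; the
  matrix exponential is applied by uniformization;
* **ancestral phase** (unbounded): every transition either coarsens the
  genealogy or increases a count, so the absorption distribution is
  obtained by a single topological sweep.

Counts are truncated at `kmax` (default 2) per type with a sticky
residual class, exactly matching the truncation used when tallying data,
so each probability table sums to one.  Correctness is checked against an
independent Monte-Carlo genealogy simulator (an event-driven
implementation sharing no code with the engine) at a grid of parameter
points spanning DIV and both IM directions; see `test-engine.R` and the
acceptance suite.

Migration direction bookkeeping deserves emphasis because it is the
classic IM bug: *forwards-time* introgression from species A into
species B means that *backwards in time* lineages sampled in B migrate
into A.  The engine, the native simulators and the msprime bridge all
follow this convention, and a label-swap symmetry test (swapping species
labels and the migration direction must leave the model invariant) locks
it in.

```{r probs}
pars <- list(ne_a = 7.35e5, ne_b = 3.77e5, ne_anc = 1.388e6,
             t = 2.526e6, m = 1.29e-8)
pr <- bsfs_probs("im_ab", pars)
sum(pr$prob)
head(arrange(pr, desc(prob)), 5)
```

## Fitting and model comparison

`fit_bsfs()` maximizes `lnCL` with a multi-start Nelder-Mead search on
log-scaled parameters (Brent for one-dimensional profiles).  The first
start is a moment-based heuristic (within-species diversity fixes the
daughter sizes, mean divergence fixes `t` given an ancestral-size guess);
the remaining starts are drawn log-uniform within the box bounds.
Defaults: 5 starts, bounds `Ne in [1e4, 5e7]`, `t in [1e3, 1e8]`,
`m in [1e-13, 1e-6]`, and a stopping tolerance well below 1e-3 lnCL
units.  Proposals implying a scaled split time `T > 30` are rejected:
such histories are indistinguishable from complete isolation at the data
sizes involved and only waste uniformization steps.

Because the IM model nests DIV at `m = 0`, warm-starting the IM fit from
the DIV solution guarantees `lnCL(IM) >= lnCL(DIV)` up to optimizer
tolerance.  Significance of `delta lnCL` comes from
`parametric_bootstrap()`: replicate tallies are simulated under the
fitted DIV model (by default 100 replicates in 1,000 chunks with
within-chunk recombination at `r = 8.9e-9` per bp per generation, to
mimic the linkage of real blocks) and both models are refit to each.
The p-value uses the add-one estimator `(1 + #{null >= obs})/(n + 1)`.

Two behaviours of this comparison are worth knowing.  First, because
`m >= 0` places the null on the boundary of the parameter space,
`delta lnCL` has an atom at zero; bootstrap p-values are therefore
approximately uniform in the rejection range but pile up mass at 1 —
this is the calibrated behaviour of a boundary test, and it is what the
acceptance suite asserts.  Second, with all five IM parameters free, data
simulated under DIV can drift along a flat `t`–`m` ridge (migration
traded against a slightly older split at essentially no likelihood
cost); the migration estimate is only meaningfully "near zero" when
profiled with the sizes held at their identified values, or judged by
`delta lnCL` against the bootstrap null rather than by `m` itself.

## Synthetic data

`sim_scenario()` + `sim_dataset()` generate everything downstream stages
consume with no external data: diploid genotypes for 12 + 9 samples
(the study design), deterministic annotation masks (a repeating 1-kb
pattern of intergenic/intronic/coding plus repeats, so intergenic minus
repeats retains exactly 70% of each chromosome), inversion coordinates,
and caller-style SV tables (`sim_sv_calls()`).  Default partition
parameters mirror the published sympatric estimates: the colinear
background (`Ne_anc = 1.388e6`, `t = 2.526e6`, `M ~ 0.0097`) and older,
less-permeable inversions (e.g. the merged X inversions at
`t = 3.32e6`).  Genotypes are drawn per 64-bp segment from an n-lineage
two-deme structured coalescent (native code, unlinked segments), with
infinite-sites mutations.

What the generator does *not* emulate: linkage between segments (except
through the msprime-backed chunk and gene-conversion modes), sequencing
error, mapping/reference bias, selection, and missing-data structure
beyond what the genotype filters create.  Passing tests therefore
demonstrate the correctness of the inference machinery under the model's
own assumptions, not robustness to real-data artefacts — the same caveat
that applies to any parametric-bootstrap analysis.

Chromosome lengths default to 250 kb and scale freely; the per-partition
sequence lengths used in any experiment are configuration, chosen here so
examples and tests complete in seconds to minutes.  The
parameter-recovery experiments use 2e5 unlinked 64-bp blocks per fit —
enough for the split time to be recovered within a few percent — and the
calibration experiments use 3,000-block tallies at `kmax = 1` with the
migration rate profiled, which preserves the calibration property while
keeping thousands of refits tractable.

Linked-sequence simulation (blocks within bootstrap chunks, and the
gene-conversion null) is delegated to the msprime coalescent simulator
through the system Python interpreter; the contract is distributional
and the bridge is cross-validated against the native engine at `r = 0`.

## The gene-conversion-only inversion null

Observed divergence inside an inversion is compared against replicate
datasets simulated under the *colinear background* demography with a
minimal, conservative model of recombination inside inversions: gene
conversion initiated at 3.59e-8 per bp per generation (equivalently,
1.4e-5 converted sites per bp per generation over a mean tract of 390 bp)
with geometrically distributed tract lengths and no crossover.  The tract
distribution is the standard coalescent-simulator model; only the mean is
an empirical input.  Sequences of 100 kb are simulated and matched in
block count to the data observed for each inversion, and one-sided
p-values (elevated `d_xy` being the hypothesis) use the add-one
estimator, so `p < 0.001` needs at least 1,000 replicates.

The calibration and significance experiments in the test suite run this
null at a reduced demographic scale (`Ne_anc = 2e5` with the study's
size ratios and scaled split times): ARG size under gene conversion
grows steeply with `Ne * L`, and the scaled history preserves every
property being tested while keeping a 1,000-replicate null within
minutes.

## Statistics and the enrichment test

`partition_stats()` computes, per block and heterospecific pair,
`d_xy = (hetA/2 + hetB/2 + hetAB/2 + fixed) / l` (the mean over the four
heterospecific haplotype pairs), `pi_A = (hetA + hetAB) / l` — note that
`hetAB` sites contribute to both diversities, an easy slip when working
from the four-type tally — and Hudson's `F_ST = 1 - mean(pi_A, pi_B) /
d_xy` on block-aggregated quantities.  The source study never specifies
its F_ST estimator; the Hudson form is the convention of the bSFS
framework it builds on, and is flagged here for that reason.  `F_ST` is
undefined (`NA`) when `d_xy = 0`.

`sliding_window_dxy()` scans block-mean `d_xy` in windows of 5,000
blocks advanced by 500 blocks (the study's figure settings), never
spanning chromosome boundaries and dropping partial tails.

`gtest_2x2()` is the plain likelihood-ratio G-test
(`G = 2 sum O ln(O/E)`, chi-square with 1 df) used for asking whether
positively selected genes are enriched inside inversions.  Applied to
the published counts (45 of 1,997 single-copy orthologs inside
inversions versus 112 of 5,426 outside), the standard formula gives
`G ~ 0.25`, not the published 0.159; no documented G-variant (Williams
or Yates corrected) reproduces that value from the printed counts, so
the discrepancy is documented rather than chased, and the conclusion
(no enrichment) is unchanged.

```{r gtest}
gtest_2x2(c(45, 1952, 112, 5314))
```

## Consensus inversion calling

`merge_sv_calls()` clusters INV calls across two callers when both
breakpoints agree within 1,000 bp and reciprocal overlap is at least 0.8
(standard SV-merging defaults; the upstream study delegates this step to
an external merger without stating its parameters).
`consensus_inversions()` then keeps clusters that are supported by both
callers, exceed 0.5 Mb, and reach the carrier threshold (9 of 12, 6 of
9) in exactly one species.  "Species-specific" tolerates one call in the
other species (`max_other = 1`) because a zero-tolerance rule is brittle
to caller noise; with noise-free input the filter returns exactly the
truth set.  A sample counts as supporting a cluster if either caller
reports it there, while caller agreement is enforced at the cluster
level.

## Numerical choices and edge cases

* Truncation `kmax = 2` per mutation type keeps the configuration space
  at `4^4` cells plus residuals while retaining most of the likelihood
  information; the residual class is sticky in the engine and in
  `tally_bsfs()`, so totals are conserved on both sides.
* Blocks are `l` *callable sites*, not `l` consecutive bp; a candidate
  block whose genomic span exceeds `2l` is discarded and packing
  restarts one site later.  Trailing sites are dropped.
* Blocks containing a missing genotype for a pair are dropped for that
  pair and logged; missingness at non-variant sites is unknowable from a
  VCF and treated as callable.
* Depth bounds are data-driven per sample (`DP >= 8` and
  `DP <= mean + 2 sd`); a `band` mode additionally applies
  `mean - 2 sd` as a floor, since the source description is ambiguous
  between the two readings.
* Uniformization splits long scaled durations into steps of at most ~100
  expected events and truncates each Poisson series at a 1e-13 tail.
* Ties in the multi-start optimizer resolve to the best `lnCL`; with
  equal values the earliest start wins (deterministic given the seed).
* `sim_dataset()` resolves infinite-sites position collisions within a
  segment by dropping the later mutation (collisions are rare at
  `theta_block < 1`) and simulates partition tails shorter than one
  segment as shorter segments, so masks and genotypes tile exactly.

## Known limitations

* The composite likelihood treats blocks as independent; with real
  linkage the support surface is too steep, which is exactly why model
  comparison uses the parametric bootstrap with chunked linkage rather
  than chi-square asymptotics.  Ignoring within-block recombination
  biases split-time estimates upward, as the bootstrap replicates of the
  source study themselves show.
* One heterospecific pair is the likelihood unit; multiple samples enter
  through the Cartesian pair tally, which re-uses the same coalescent
  marginal and therefore adds pseudo-replication, again absorbed by the
  bootstrap.
* The IM model is time-homogeneous: no secondary contact, no pulses, no
  time-varying rates, mirroring the scope of the original analysis.
* The X chromosome is treated as diploid (female samples); no
  ploidy-aware effective-size correction is applied when comparing X and
  autosomal estimates.
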