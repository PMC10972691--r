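# invdemog

Demographic inference for dating chromosomal inversions relative to a
species split, from diploid genotype data summarized as the blockwise
site frequency spectrum (bSFS).

## The problem

Alternatively fixed inversions between sister species may predate the
species split (ancestrally polymorphic inversions that shielded diverging
loci from gene flow) or postdate it (incidental rearrangements).  The two
histories are distinguished by fitting explicit demographic models
separately to inverted and colinear genomic partitions: a strict
divergence model (DIV: an ancestral population of size *N*<sub>anc</sub>
splits at time *T* into populations of sizes *N*<sub>A</sub>,
*N*<sub>B</sub>) and an isolation-with-migration model (IM: DIV plus
unidirectional migration at per-lineage per-generation rate *m*, scaled
rate *M* = 2 *N*<sub>recipient</sub> *m*).  An inversion that is older
than the colinear background (*T*<sub>inv</sub> > *T*<sub>col</sub>) with
reduced migration (*M*<sub>inv</sub> < *M*<sub>col</sub>) must have been
segregating in the common ancestor.

The data enter as the bSFS: for each heterospecific pair of diploid
genomes, short blocks of ℓ callable sites (64 by default) are summarized
by the joint counts of four folded mutation types — hetA, hetB, hetAB,
fixed — and the model is fitted by maximizing the composite
log-likelihood lnCL = Σ<sub>config</sub> *n* log *P*(config).  Block
configuration probabilities are computed exactly by integrating the
four-lineage structured coalescent as a finite Markov chain with
Poissonized mutation counts (no simulation in the likelihood), time is
converted with *t* = *T* · 2*N*<sub>e</sub> · *g* and *N*<sub>e</sub> =
θ/(4μ), and model support (ΔlnCL) is judged by parametric bootstrap.

The package is aimed at population geneticists who want a self-contained,
testable reimplementation of this analysis chain: every stage runs on
synthetic data with known truth, from genotype and SV-caller simulation
through preprocessing, blocking, fitting, bootstrap and the
gene-conversion-only null for inversion divergence.

## Worked example

Simulate a bSFS under the sympatric interspecific history (sizes in
diploids, time in generations, migration from species A into species B)
and re-estimate the parameters:

```r
library(invdemog)

pars <- list(ne_a = 7.35e5, ne_b = 3.77e5, ne_anc = 1.388e6,
             t = 2.526e6, m = 1.29e-8)
tal <- sim_tally("im_ab", pars, n_blocks = 2e5, seed = 11)
fit <- fit_bsfs(tal, "im_ab", n_starts = 5, seed = 1)
fit
#> bSFS composite-likelihood fit (IM_AB model)
#>   blocks: 200000 (length 64, kmax 2)   lnCL: -605108.43   converged: TRUE
#>   Ne_A = 7.36e+05  Ne_B = 3.75e+05  Ne_anc = 1.39e+06  t = 2.51e+06 gen  m = 1.3e-08
```

The split time is recovered within 1% (2.51 vs 2.526 million
generations) and the migration probability within a few percent.  The
derived quantities match the published scale:

```r
tidy(fit)                                # term/estimate tibble, incl. M and T
signif(M_from_m(1.29e-8, 377000), 2)     # 0.0097
round(100 * migrant_fraction(T_from_t(2.526e6, 377000), 0.0097), 1)
#> 3.2   # % of recipient lineages that trace back through migration
```

A full synthetic pipeline — genotypes, masks, SV-caller tables,
partitioning, per-partition statistics — runs from a scenario object:

```r
sc <- sim_scenario(seed = 1)      # 12 + 9 diploids, 5 fixed inversions
ds <- sim_dataset(sc)
bc <- block_counts(ds, max_pairs = 4)
partition_stats(bc)               # d_xy, pi, Hudson F_ST per partition
calls <- sim_sv_calls(sc, jitter_sd = 0, fn_rate = 0, fp_rate = 0)
consensus_inversions(merge_sv_calls(calls), min_size = 5e4)
```

On a noise-free run the consensus filter returns exactly the five
simulated inversions, and the inverted partitions show higher d<sub>xy</sub>
than the colinear background, as their older split times dictate.

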