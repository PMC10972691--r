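"""Linked-sequence coalescent simulation backend (msprime).

Called as: python sim_linked.py config.json out.tsv

Modes:
  chunks  -- simulate independently segregating chunks of blocks for one
             heterospecific pair (one diploid per species), with crossover
             recombination at rate r between sites within a chunk; emits one
             row per block with the four mutation-type counts.
  gcnull  -- simulate replicate datasets of fixed-length sequences under the
             background demography with gene conversion (geometric tracts)
             and no crossover; emits one row per replicate with summed
             per-block mutation-type counts over a requested number of
             blocks.
"""
import json
import sys

import numpy as np
import msprime


def build_demography(d):
    dem = msprime.Demography()
    dem.add_population(name="A", initial_size=d["ne_a"])
    dem.add_population(name="B", initial_size=d["ne_b"])
    dem.add_population(name="ANC", initial_size=d["ne_anc"])
    dem.add_population_split(time=d["t"], derived=["A", "B"], ancestral="ANC")
    m = float(d.get("m", 0.0))
    direction = d.get("direction", "none")
    if m > 0 and direction != "none":
        # msprime's migration matrix is in the backwards-time convention:
        # rate[source, dest] moves lineages source -> dest backwards in time,
        # i.e. individuals dest -> source forwards in time.  Forwards-time
        # introgression A -> B therefore needs lineages to jump B -> A.
        if direction == "ab":
            dem.set_migration_rate(source="B", dest="A", rate=m)
        elif direction == "ba":
            dem.set_migration_rate(source="A", dest="B", rate=m)
        else:
            raise ValueError("direction must be 'ab', 'ba' or 'none'")
    return dem


def pair_block_counts(ts, block_length, n_blocks):
    """Four mutation-type counts per block for haplotypes (a1,a2,b1,b2)."""
    counts = np.zeros((n_blocks, 4), dtype=np.int64)
    if ts.num_sites == 0:
        return counts
    g = ts.genotype_matrix()
    pos = np.array([s.position for s in ts.sites()])
    dos_a = g[:, 0] + g[:, 1]
    dos_b = g[:, 2] + g[:, 3]
    blk = np.minimum((pos // block_length).astype(int), n_blocks - 1)
    het_a = (dos_a == 1) & (dos_b != 1)
    het_b = (dos_b == 1) & (dos_a != 1)
    het_ab = (dos_a == 1) & (dos_b == 1)
    fixed = np.abs(dos_a - dos_b) == 2
    for k, mask in enumerate((het_a, het_b, het_ab, fixed)):
        np.add.at(counts[:, k], blk[mask], 1)
    return counts


def simulate_pair(dem, seq_len, seed, mu, recomb=0.0, gc_rate=0.0, gc_tract=0.0):
    kwargs = dict(
        samples={"A": 1, "B": 1},
        demography=dem,
        sequence_length=seq_len,
        recombination_rate=recomb,
        ploidy=2,
        random_seed=seed,
    )
    if gc_rate > 0:
        kwargs["gene_conversion_rate"] = gc_rate
        kwargs["gene_conversion_tract_length"] = gc_tract
    ts = msprime.sim_ancestry(**kwargs)
    ts = msprime.sim_mutations(
        ts, rate=mu, model=msprime.BinaryMutationModel(), random_seed=seed + 1
    )
    return ts


def mode_chunks(cfg, out):
    dem = build_demography(cfg["demography"])
    bl = int(cfg["block_length"])
    bpc = np.atleast_1d(np.asarray(cfg["blocks_per_chunk"], dtype=int))
    rng = np.random.default_rng(int(cfg["seed"]))
    seeds = rng.integers(1, 2**31 - 2, size=len(bpc))
    rows = []
    for nb, sd in zip(bpc, seeds):
        ts = simulate_pair(dem, nb * bl, int(sd), cfg["mu"], recomb=cfg["r"])
        rows.append(pair_block_counts(ts, bl, nb))
    counts = np.concatenate(rows, axis=0)
    write_counts(out, counts, header="hetA\thetB\thetAB\tfixed")


def mode_gcnull(cfg, out):
    dem = build_demography(cfg["demography"])
    bl = int(cfg["block_length"])
    seq_len = float(cfg["seq_length"])
    blocks_per_seq = int(seq_len // bl)
    n_blocks = int(cfg["n_blocks"])
    n_seq = max(1, int(np.ceil(n_blocks / blocks_per_seq)))
    rng = np.random.default_rng(int(cfg["seed"]))
    n_sims = int(cfg["n_sims"])
    seeds = rng.integers(1, 2**31 - 2, size=(n_sims, n_seq))
    rows = np.zeros((n_sims, 5), dtype=np.int64)
    for i in range(n_sims):
        chunks = []
        for j in range(n_seq):
            ts = simulate_pair(
                dem, seq_len, int(seeds[i, j]), cfg["mu"],
                recomb=0.0, gc_rate=cfg["gc_rate"], gc_tract=cfg["gc_tract"],
            )
            chunks.append(pair_block_counts(ts, bl, blocks_per_seq))
        counts = np.concatenate(chunks, axis=0)[:n_blocks]
        rows[i, 0] = counts.shape[0]
        rows[i, 1:] = counts.sum(axis=0)
    write_counts(out, rows, header="n_blocks\thetA\thetB\thetAB\tfixed")


def write_counts(path, mat, header):
    with open(path, "w") as fh:
        fh.write(header + "\n")
        np.savetxt(fh, mat, fmt="%d", delimiter="\t")


def main():
    with open(sys.argv[1]) as fh:
        cfg = json.load(fh)
    out = sys.argv[2]
    if cfg["mode"] == "chunks":
        mode_chunks(cfg, out)
    elif cfg["mode"] == "gcnull":
        mode_gcnull(cfg, out)
    else:
        raise ValueError("unknown mode: %s" % cfg["mode"])


if __name__ == "__main__":
    main()
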