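"""Batch coalescent haplotype simulation.

Simulates replicate populations of phased haplotypes under the neutral
coalescent with recombination (msprime) and writes, per replicate:

  <prefix>_<i>.pos : one line of 1-based integer site positions
  <prefix>_<i>.hap : raw uint8 genotype matrix, site-major
                     (site 0 over all haplotypes, then site 1, ...)

Only segregating biallelic 0/1 sites are written.  Per-replicate seeds are
drawn from a NumPy RandomState seeded with --seed, so output is fully
deterministic for a given argument set.
"""

import argparse
import sys

import numpy as np
import msprime


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--n-hap", type=int, required=True)
    ap.add_argument("--length", type=float, required=True)
    ap.add_argument("--mu", type=float, required=True)
    ap.add_argument("--rec", type=float, required=True)
    ap.add_argument("--ne", type=float, required=True)
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--reps", type=int, default=1)
    ap.add_argument("--out-prefix", required=True)
    a = ap.parse_args()

    if a.n_hap < 2 or a.length <= 0 or a.ne <= 0:
        sys.exit("invalid simulation parameters")

    rng = np.random.RandomState(a.seed)
    seeds = rng.randint(1, 2**31 - 1, size=(a.reps, 2))

    for i in range(a.reps):
        ts = msprime.sim_ancestry(
            samples=a.n_hap,
            ploidy=1,
            sequence_length=a.length,
            recombination_rate=a.rec,
            population_size=a.ne,
            random_seed=int(seeds[i, 0]),
        )
        if a.mu > 0:
            ts = msprime.sim_mutations(
                ts,
                rate=a.mu,
                model=msprime.BinaryMutationModel(),
                random_seed=int(seeds[i, 1]),
            )
            G = ts.genotype_matrix()  # sites x haplotypes, values 0/1
            pos = ts.sites_position.astype(np.int64) + 1  # 1-based bp
            f = G.mean(axis=1)
            keep = (f > 0.0) & (f < 1.0)
            G = G[keep]
            pos = pos[keep]
        else:
            G = np.zeros((0, a.n_hap), dtype=np.uint8)
            pos = np.zeros(0, dtype=np.int64)

        prefix = "%s_%d" % (a.out_prefix, i + 1)
        with open(prefix + ".pos", "w") as fh:
            fh.write(" ".join(str(p) for p in pos))
            fh.write("\n")
        G.astype(np.uint8).tofile(prefix + ".hap")


if __name__ == "__main__":
    main()
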