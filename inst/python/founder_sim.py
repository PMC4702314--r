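"""Coalescent founder haplotype simulation (msprime backend).

Reads a JSON parameter file, simulates each chromosome independently
under the standard neutral coalescent with recombination, thins
segregating sites to the requested per-chromosome locus budget after a
minor-allele-frequency filter, and writes plain-text outputs:

  <prefix>_pos.txt : one line per locus: chromosome index, position (cM)
  <prefix>_hap.txt : one line per haplotype, space-separated 0/1 alleles
                     (columns ordered as in the positions file)
  <prefix>_meta.json : realized site counts and the parameters used

Genetic coordinates are used directly: 1 cM is represented by 10 kb of
simulated sequence with a recombination rate of 1e-6 per bp, so the
per-chromosome map length in Morgans equals the intended value.
"""
import json
import sys

import numpy as np
import msprime

CM_PER_BP = 1e-4  # 10 kb per cM
RECOMB_RATE = 1e-6  # per bp, so 1 Morgan per 1e6 bp


def simulate_chromosome(length_cm, ne, n_hap, mu, seed):
    seq_len = length_cm / CM_PER_BP
    ts = msprime.sim_ancestry(
        samples=n_hap,
        ploidy=1,
        population_size=ne,
        sequence_length=seq_len,
        recombination_rate=RECOMB_RATE,
        random_seed=seed,
    )
    mts = msprime.sim_mutations(
        ts, rate=mu, random_seed=seed + 1, model=msprime.BinaryMutationModel()
    )
    geno = mts.genotype_matrix().T.astype(np.int8)  # haplotypes x sites
    geno = np.minimum(geno, 1)
    pos_cm = np.array([s.position for s in mts.sites()]) * CM_PER_BP
    return pos_cm, geno


def main(param_path):
    with open(param_path) as fh:
        par = json.load(fh)
    ne = float(par["Ne"])
    n_hap = int(par["n_haplotypes"])
    mu = float(par["mutation_rate"])
    maf_min = float(par["maf_min"])
    def as_list(x):
        return x if isinstance(x, list) else [x]

    budgets = [int(b) for b in as_list(par["loci_per_chrom"])]
    lengths = [float(x) for x in as_list(par["chrom_length_cm"])]
    seeds = [int(s) for s in as_list(par["chrom_seeds"])]
    prefix = par["out_prefix"]

    rng = np.random.default_rng(int(par["thin_seed"]))
    all_pos, all_chrom, all_geno, raw_counts = [], [], [], []
    for c, (length_cm, budget, seed) in enumerate(zip(lengths, budgets, seeds)):
        pos, geno = simulate_chromosome(length_cm, ne, n_hap, mu, seed)
        raw_counts.append(int(pos.size))
        freq = geno.mean(axis=0)
        keep = np.flatnonzero((freq >= maf_min) & (freq <= 1 - maf_min))
        if keep.size < budget:
            sys.stderr.write(
                "chromosome %d: %d usable segregating sites (MAF >= %g) "
                "but %d loci requested; raise the mutation rate or lower "
                "the locus budget\n" % (c + 1, keep.size, maf_min, budget)
            )
            sys.exit(3)
        keep = np.sort(rng.choice(keep, size=budget, replace=False))
        all_pos.append(pos[keep])
        all_chrom.append(np.full(budget, c + 1, dtype=int))
        all_geno.append(geno[:, keep])

    pos = np.concatenate(all_pos)
    chrom = np.concatenate(all_chrom)
    geno = np.concatenate(all_geno, axis=1)

    with open(prefix + "_pos.txt", "w") as fh:
        for c, p in zip(chrom, pos):
            fh.write("%d %.8f\n" % (c, p))
    np.savetxt(prefix + "_hap.txt", geno, fmt="%d")
    with open(prefix + "_meta.json", "w") as fh:
        json.dump(
            {
                "raw_segregating_sites": raw_counts,
                "n_loci": int(pos.size),
                "Ne": ne,
                "n_haplotypes": n_hap,
                "mutation_rate": mu,
                "recombination_rate_per_bp": RECOMB_RATE,
                "cm_per_bp": CM_PER_BP,
                "maf_min": maf_min,
            },
            fh,
        )


if __name__ == "__main__":
    main(sys.argv[1])
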