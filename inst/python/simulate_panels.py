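"""Two-population coalescent simulation (African / cosmopolitan bottleneck model).

Writes segregating sites as TSV: position <tab> 0/1 genotype string
(one row per site, one character per haploid sample; population 1 first).
All times/sizes are in ms-style scaled units (time in 4*N0 generations,
sizes relative to N0); they are converted to msprime's generations here.
"""
import argparse
import sys

import msprime


def build_demography(n0, cosmo_size, crash_size, crash_time, join_time,
                     ancestral_time, ancestral_size):
    # Haploid (ploidy-1) samples: msprime's pair-coalescence time for a
    # ploidy-1 population of size N is N generations, so the ms-style
    # reference (2*N0 generations for a diploid N0) needs sizes of 2*N0.
    hap = 2.0 * n0
    d = msprime.Demography()
    d.add_population(name="AFR", initial_size=hap)
    d.add_population(name="COS", initial_size=cosmo_size * hap)
    d.add_population(name="ANC", initial_size=hap)
    four_n0 = 4.0 * n0
    d.add_population_parameters_change(
        time=crash_time * four_n0, population="COS",
        initial_size=crash_size * hap)
    d.add_population_parameters_change(
        time=join_time * four_n0, population="COS", initial_size=hap)
    d.add_population_split(
        time=join_time * four_n0 * (1.0 + 1e-9),
        derived=["AFR", "COS"], ancestral="ANC")
    d.add_population_parameters_change(
        time=ancestral_time * four_n0, population="ANC",
        initial_size=ancestral_size * hap)
    d.sort_events()
    return d


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--length", type=float, required=True)
    ap.add_argument("--n-african", type=int, default=27)
    ap.add_argument("--n-cosmopolitan", type=int, default=36)
    ap.add_argument("--theta", type=float, default=0.0376)
    ap.add_argument("--rho", type=float, default=0.171)
    ap.add_argument("--gc-ratio", type=float, default=0.0,
                    help="gene conversion rate as multiple of crossover rate")
    ap.add_argument("--gc-tract", type=float, default=86.5)
    ap.add_argument("--cosmo-size", type=float, default=0.183)
    ap.add_argument("--crash-size", type=float, default=0.000377)
    ap.add_argument("--crash-time", type=float, default=0.0037281)
    ap.add_argument("--join-time", type=float, default=0.00381)
    ap.add_argument("--ancestral-time", type=float, default=0.0145)
    ap.add_argument("--ancestral-size", type=float, default=0.2)
    ap.add_argument("--n0", type=float, default=1e6)
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--out", default="-")
    args = ap.parse_args()

    n0 = args.n0
    mu = args.theta / (4.0 * n0)          # per site per generation
    rr = args.rho / (4.0 * n0)
    demog = build_demography(n0, args.cosmo_size, args.crash_size,
                             args.crash_time, args.join_time,
                             args.ancestral_time, args.ancestral_size)
    gc_rate = rr * args.gc_ratio if args.gc_ratio > 0 else None
    ts = msprime.sim_ancestry(
        samples=[msprime.SampleSet(args.n_african, population="AFR",
                                   ploidy=1),
                 msprime.SampleSet(args.n_cosmopolitan, population="COS",
                                   ploidy=1)],
        demography=demog,
        sequence_length=int(args.length),
        recombination_rate=rr,
        gene_conversion_rate=gc_rate,
        gene_conversion_tract_length=(args.gc_tract if gc_rate else None),
        ploidy=1,
        random_seed=args.seed)
    ts = msprime.sim_mutations(ts, rate=mu, random_seed=args.seed + 1,
                               model=msprime.BinaryMutationModel())

    out = sys.stdout if args.out == "-" else open(args.out, "w")
    try:
        for var in ts.variants():
            geno = var.genotypes
            # collapse any recurrent hits to presence/absence of derived state
            row = "".join("1" if g > 0 else "0" for g in geno)
            out.write(f"{int(var.site.position)}\t{row}\n")
    finally:
        if out is not sys.stdout:
            out.close()


if __name__ == "__main__":
    main()
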