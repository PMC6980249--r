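"""Coalescent backend: simulate neutral haplotypes under a two-deme demography.

Reads a JSON job description (path in argv[1]) and writes a plain-text site
table to the output path named in the job.  Used by the R wrapper
simulate_neutral_panel(); not intended to be run by hand.

Job schema (all times in generations before present, sizes in diploids):
  {
    "demography": {
      "populations": [{"name":..., "size":..., "growth":...}, ...],
      "events":      [{"time":..., "population":..., "size":...|null,
                       "growth":...|null}, ...],
      "splits":      [{"time":..., "derived":..., "ancestral":...}],
      "migrations":  [{"time":..., "rate":..., "from":..., "to":...}, ...]
    },
    "region_length": float, "mu": float,
    "recomb": {"positions": [...], "rates": [...]} | {"rate": float},
    "samples": {"<pop>": n_diploids},
    "seed": int, "n_reps": int, "genotypes": bool,
    "out": "path"
  }

Output format (one file, all replicates):
  #REP <k> <n_hap> <region_length>
  <pos>\t<count>[\t<0/1 haplotype string>]   (one line per segregating site)
"""
import json
import sys

import msprime


def build_demography(spec):
    dem = msprime.Demography()
    for p in spec["populations"]:
        dem.add_population(name=p["name"], initial_size=p["size"],
                           growth_rate=p.get("growth", 0.0))
    for ev in spec.get("events", []):
        dem.add_population_parameters_change(
            time=ev["time"], population=ev["population"],
            initial_size=ev.get("size"), growth_rate=ev.get("growth"))
    for sp in spec.get("splits", []):
        dem.add_population_split(time=sp["time"], derived=[sp["derived"]],
                                 ancestral=sp["ancestral"])
    for mg in spec.get("migrations", []):
        if mg.get("time", 0) == 0:
            dem.set_migration_rate(mg["from"], mg["to"], mg["rate"])
        else:
            dem.add_migration_rate_change(time=mg["time"], rate=mg["rate"],
                                          source=mg["from"], dest=mg["to"])
    dem.sort_events()
    return dem


def recomb_map(spec, L):
    if "rate" in spec:
        return spec["rate"]
    pos = list(map(float, spec["positions"])) + [L]
    return msprime.RateMap(position=pos, rate=list(map(float, spec["rates"])))


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    L = float(job["region_length"])
    dem = build_demography(job["demography"])
    reps = msprime.sim_ancestry(
        samples=job["samples"], demography=dem, sequence_length=L,
        recombination_rate=recomb_map(job["recomb"], L),
        num_replicates=int(job["n_reps"]), random_seed=int(job["seed"]))
    want_geno = bool(job.get("genotypes", True))
    with open(job["out"], "w") as out:
        for k, ts in enumerate(reps):
            if job["mu"] > 0:
                ts = msprime.sim_mutations(
                    ts, rate=job["mu"], random_seed=int(job["seed"]) + 7919 * (k + 1),
                    model=msprime.BinaryMutationModel(), discrete_genome=True)
            n_hap = ts.num_samples
            out.write("#REP %d %d %r\n" % (k + 1, n_hap, L))
            last_pos = -1
            for v in ts.variants():
                g = v.genotypes
                c = int(g.sum())
                if c <= 0 or c >= n_hap:
                    continue
                pos = int(v.site.position)
                if pos == last_pos:      # keep positions strictly increasing
                    continue
                last_pos = pos
                if want_geno:
                    out.write("%d\t%d\t%s\n" % (pos, c, "".join(map(str, g))))
                else:
                    out.write("%d\t%d\n" % (pos, c))


if __name__ == "__main__":
    main(sys.argv[1])
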