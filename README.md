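# issrpop

Population-genetic and virulence analysis of entomopathogenic fungi surveyed
with dominant binary markers. The package targets the common study design in
which isolates of a fungus such as *Metarhizium rileyi* are collected from
infected insect hosts across a region, fingerprinted by ISSR PCR (bands
scored 1/0 per locus), and assayed for virulence against larval cohorts —
and in which only summary tables, not the raw band matrix or survival
records, are ever published.

It provides, for the marker side:

- **Within-population diversity** per locus and averaged: observed and
  effective allele numbers (Na, Ne = 1/Σp²), Nei's gene diversity
  (He = 1 − Σp²), Shannon information index (Is = −Σ p ln p), and the
  percentage of polymorphic loci, under a haploid (band frequency = allele
  frequency) or dominant-diploid (square-root) estimator;
- **Diversity partition**: per-locus and mean total (HT) and
  within-population (HS) gene diversity, the differentiation coefficient
  GST = (HT − HS)/HT, and gene flow Nm = c(1 − GST)/GST with haploid
  (c = 0.5) or diploid (c = 0.25) coefficient;
- **Nei genetic identity/distance** (I = Jxy/√(JxJy), D = −ln I) between
  populations, Dice/Jaccard/simple-matching similarity between individual
  profiles, and deterministic **UPGMA** dendrograms with Newick export;

and for the bioassay side: mortality/mycosis summaries with standard errors,
empirical-probit regression of mortality on log time with LT50, and
Kaplan–Meier median lethal times. F-model marker simulators and log-normal
time-to-death bioassay simulators with known ground truth make every
estimator testable by parameter recovery.

## Worked example

The `analysis/` scripts run the whole pipeline on a simulated dataset with
the shape of the modelled survey (31 isolates, 8 multi-isolate + 5 singleton
geographic groups, 54 loci from 7 primers; 31 strains × 3 replicates × 30
larvae observed for 10 days):

```sh
Rscript analysis/01_simulate.R        # synthetic band matrix + bioassay records
Rscript analysis/02_diversity.R       # Na, Ne, He, Is, %polymorphic
Rscript analysis/03_differentiation.R # HT, HS, GST, Nm
Rscript analysis/04_distance_clustering.R
Rscript analysis/05_bioassay.R        # probit LT50 + Kaplan-Meier
```

Stage 3 prints, for the default simulation (F = 0.35, seed 101):

```
Gene-diversity partition over 52 loci, 8 populations
  mean HT = 0.3829 (SD 0.1092), mean HS = 0.1748 (SD 0.0843)
  GST = 0.5436  Nm = 0.4198 (c = 0.50)
  variation among groups 54.36%, within groups 45.64%
published means give GST = 0.3481, Nm = 0.9360
```

Reading: just over half of the simulated gene diversity lies among
geographic groups, and Nm < 1 flags limited gene exchange. The estimated
GST (0.54) sits far above the generating F = 0.35 because groups of 2–8
isolates inflate the among-group variance — the reason the package's
parameter-recovery tests use 50 isolates per group, where the estimate
lands near 0.33. The final line recomputes the differentiation worked
example from the published across-locus means bundled under
`inst/extdata/` (`reference_table("diversity_partition")`).

Stage 5 prints per-strain virulence summaries, e.g.:

```
31 strains analysed
5 strains at 100% mean mortality; minimum mean mortality 18.9%
LT50 estimable for 30 strains; probit LT50 range 3.52-7.56 d
strains with LT50 < 4 d: FQMD200805, MDXZ200803, SZBLT201010, XSBN200920
```

LT50 entries are reported only for strains whose mortality reached 50%,
mirroring the "-" convention of published virulence tables.

Equivalent results for arbitrary inputs come from `run_full_pipeline()`,
which accepts a band-matrix CSV (`isolate,population,<locus>,...` with cells
0/1/NA) and a bioassay CSV
(`strain,replicate,n_exposed,day,cum_dead,mycosed`) and writes the full
report bundle.

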