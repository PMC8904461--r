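# ssrid

Forensic individual identification and population genetics for diploid
microsatellite (SSR) genotype data.

## Who this is for

Conservation-forensics and population-genetics practitioners who genotype
individuals (trees, wildlife, timber seizures) at a panel of SSR loci and
need to answer two questions:

1. **How discriminating is the panel?** Per-locus statistics (allele count
   *A*, observed/expected heterozygosity *Ho*/*He*, polymorphism
   information content *PIC*, power of discrimination *PD*, probability of
   identity *P<sub>I</sub>*, Hardy–Weinberg tests), linkage-aware
   accumulation of loci into the combined probability of identity
   *CP<sub>I</sub> = ∏ P<sub>I</sub>* over one representative locus per
   linkage group, and the largest population identifiable at a stated
   confidence level, *N<sub>max</sub> = ⌊ln CL\* / ln(1 − CP<sub>I</sub>)⌋*
   with *CL = (1 − CP<sub>I</sub>)<sup>N</sup>*.
2. **Where does a sample come from?** Per-population diversity and
   inbreeding (*F<sub>is</sub> = 1 − Ho/He*), pairwise differentiation
   (*F<sub>st</sub> = (H<sub>t</sub> − H<sub>s</sub>)/H<sub>t</sub>*, with
   Weir–Cockerham θ as an option), island-model gene flow
   (*Nm = (1 − F<sub>st</sub>)/4F<sub>st</sub>*), Evanno ΔK post-processing
   of clustering run likelihoods, and leave-one-out frequency-method
   provenance assignment.

The package reads and writes the three community text formats (GenAlEx
codominant CSV, Genepop, STRUCTURE) and ships a Balding–Nichols genotype
simulator (inbreeding, perfect-linkage groups, null alleles, missing data)
so that every stage is testable at desk scale. The motivating design — 4
populations of 20/25/23/24 individuals at 36 SSR loci with 2–27 alleles
per locus — is frozen in `cypress_sim_config()`.

## Worked example

```r
library(ssrid)
cfg <- cypress_sim_config(seed = 7)      # 92 individuals, 36 loci, 4 pops
sim <- simulate_dataset(cfg)
report <- run_full_analysis(sim$matrix, ld_reps = 1999, seed = 7)
print(report)
```

```
==== ssrid analysis report ====
loci: 36 | mean A = 4.750, Ho = 0.355, He = 0.498, PIC = 0.464
linkage_structure: alpha = 0.001 ( component )
   31 groups ( 2 multi-locus )
   { L05, L12, L20 }
   { L07, L15, L24, L31 }
  usable loci: 31
forensic_profile: 31 loci accumulated
  final CPI = 1.804e-18, CPD = 1
  N_max@0.95 = 2.842556e+16
  N_max@0.99 = 5.569663e+15
  N_max@0.9999 = 5.542046e+13
pop_diff_matrix (nei Fst):
      MM    HV    GW    SY
MM 0.000 0.051 0.046 0.050
HV 0.051 0.000 0.054 0.052
GW 0.046 0.054 0.000 0.038
SY 0.050 0.052 0.038 0.000
assignment_result (leave-one-out: TRUE )
 population  N correct pct_correct
         MM 20      18    90.00000
         HV 25      21    84.00000
         GW 23      20    86.95652
         SY 24      20    83.33333
overall correct: 85.87%
```

Reading the output: the linkage scan recovered exactly the two linkage
groups planted by the simulator, so 31 of 36 loci enter the forensic
product. After accumulating all 31 (sorted by ascending *P<sub>I</sub>*)
the combined probability that two random individuals share a full profile
is ~1.8 × 10⁻¹⁸, enough to discriminate ~5.5 × 10¹³ individuals even at
the strictest court-style 99.99% confidence level. Pairwise
*F<sub>st</sub>* around 0.04–0.05 and ~86% leave-one-out self-assignment
match what the simulator was told to generate (moderate differentiation,
*F<sub>st</sub>* = 0.06 with inbreeding 0.2).

A small simulated GenAlEx fixture (synthetic data, not real genotypes) is
included at `inst/extdata/synthetic_cypress_92x36.genalex.csv`:

```r
m <- read_genalex(system.file("extdata", "synthetic_cypress_92x36.genalex.csv",
                              package = "ssrid"))
summarize_loci(m)
```

A command-line front-end with verbs `simulate`, `locus-stats`, `deltak`
and `run-all` is installed at `inst/cli/ssrid.R`.

## Scope notes

The package post-processes genotype matrices only: no fragment sizing or
allele binning, no clustering MCMC (only the ΔK statistic over run
likelihoods), no null-allele frequency estimators, no kinship or
likelihood-ratio match statistics. See the methods vignette
(`vignettes/ssr-identification.Rmd`) for the model, parameter defaults,
and known limitations.
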