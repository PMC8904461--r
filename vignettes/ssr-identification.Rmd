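---
title: "Individual identification and population genetics with SSR markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual identification and population genetics with SSR markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrid)
```

## The problem

Microsatellites (simple sequence repeats, SSRs) are short tandem-repeat loci
whose alleles are PCR fragment lengths. Because they are codominant and highly
polymorphic they support two workflows that this package implements end to
end for diploid genotype matrices:

1. **Forensic individual identification** — deciding whether two samples
   (say, a seized timber and the stump of a felled tree) come from the same
   individual, and quantifying how large a population the marker panel can
   discriminate at a stated confidence level.
2. **Population genetics** — diversity, inbreeding, differentiation, gene
   flow and provenance (population-of-origin) assignment across the sampled
   geographic areas.

The motivating design is a conifer study: 4 geographic populations of
20/25/23/24 diploid individuals genotyped at 36 SSR loci with 2–27 alleles
per locus. The raw genotype table of such studies is usually not published,
so the package ships a statistically faithful simulator and validates the
pipeline by parameter recovery rather than by re-analysing a private
dataset.

## Per-locus statistics

For each locus with allele frequencies $p_i$ over $n$ typed individuals:

* observed heterozygosity $H_o$ = fraction of typed individuals carrying two
  distinct alleles;
* expected heterozygosity $H_e = 1 - \sum_i p_i^2$, with the unbiased
  variant $uH_e = H_e \cdot 2n/(2n-1)$ reported alongside;
* polymorphism information content (Botstein's form, the PowerMarker
  definition)
  $PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$;
* power of discrimination $PD = 1 - \sum_g P_g^2$ where $P_g$ are
  **observed** genotype frequencies (the literal reading of the defining
  formula; an HWE-expected mode is available via `pd_mode = "expected"` for
  sensitivity analysis); and probability of identity $P_I = 1 - PD$.

Hardy–Weinberg testing defaults to the chi-squared goodness-of-fit statistic
over all $A(A+1)/2$ genotype classes with $A(A-1)/2$ degrees of freedom (the
GenAlEx convention, no pooling and no multiple-testing correction — the
analyses this mirrors apply none; the flagging threshold defaults to
$\alpha = 0.001$). The asymptotic far tail is accurate for biallelic loci at
$n \approx 100$ (measured null rejection at $\alpha = 0.001$: ~0.003) but
inflates with allele count as expected genotype counts shrink (~0.02 at
$A$ drawn 2–27); for highly multiallelic loci use
`hwe_test(..., method = "exact_mc")`, a seeded Guo–Thompson-style
Monte-Carlo exact test that re-pairs the observed allele copies.

## Linkage and the forensic accumulation

Loci in linkage disequilibrium carry redundant identification information,
so only one locus per linkage group may enter the combined product.
`ld_test_pair()` runs a genotypic G-test on the two-locus contingency table
with a permutation null (one genotype column shuffled across individuals),
the approach of the Genepop lineage; `linkage_groups()` merges significant
pairs ($p < \alpha$, default 0.001) into connected components. The stricter
reading in which *every* within-group pair must be significant is available
as `method = "clique"` (greedy maximal-clique peeling); components are the
default because linkage-group reasoning is transitive. With the six
multi-locus groups of sizes 3, 2, 4, 2, 2, 3 reported for the motivating
36-locus panel, the component rule leaves 26 usable loci (36 − 16 grouped +
6 representatives); published counts of "28 loci without linkage" for that
panel imply not all within-group pairs were significant there, which the
clique option accommodates.

Each group is represented by its member with the smallest $P_I$ (ties break
to the lexicographically smallest locus id). `cumulative_profile()` sorts
the usable loci by $P_I$ ascending and accumulates
$CP_I^{(k)} = \prod_{j \le k} P_{I,j}$ in log space;
$CPD = 1 - CP_I$. The confidence level of an identification against a
population of $N$ individuals is $CL = (1 - CP_I)^N$, evaluated with
`log1p` so that $CP_I \sim 10^{-12}$ keeps full precision, and the largest
identifiable population at confidence $CL^*$ is
$N_{max} = \lfloor \ln CL^* / \ln(1 - CP_I) \rfloor$, with a correction
step against the defining inequality because the log ratio can land a hair
below an integer when $(1-CP_I)^k$ equals $CL^*$ exactly. $N_{max}$ is
floored (conservative); `floor = FALSE` reports the real-valued bound.

## Population structure

Per population, per-locus $A$, $H_o$, $H_e$ are averaged over loci and the
inbreeding coefficient is $F_{is} = 1 - \bar H_o / \bar H_e$ from the
unrounded means. Pairwise differentiation defaults to the Nei/GenAlEx
frequency form $F_{st} = (H_t - H_s)/H_t$ with $H_t$ and $H_s$ summed over
loci before the ratio; gene flow uses the island-model estimator
$N_m = \tfrac{1}{4}(1 - F_{st})/F_{st}$ (not printed in the motivating
study, but its published $F_{st}$/$N_m$ pairs are mutually consistent with
this form within rounding). **Caveat:** with $k$ populations the Nei form
converges to $\theta (k-1)/k$ of the simulation parameter $\theta$ — for a
pair of populations roughly $\theta/2$. It is kept as the default because
it reproduces the GenAlEx-style tables the package mirrors, but parameter
recovery and any reading of the estimate as "the" $F_{st}$ should use
`method = "wc"` (Weir–Cockerham $\theta$), which targets $\theta$ with any
$k$.

`delta_k()` post-processes a table of clustering run log-likelihoods
(columns `K`, `run`, `lnP`) with the Evanno second-difference statistic
$\Delta K = |L''(K)| / \mathrm{sd}(L(K))$; the package never invokes any
clustering program itself.

## Provenance assignment

`assign_all()` implements the frequency (Paetkau-style) assignment
criterion: an individual's genotype log-likelihood under each candidate
population's allele frequencies, $\log p_a^2$ for homozygotes and
$\log 2 p_a p_b$ for heterozygotes, summed over its non-missing loci.
Alleles unseen in a reference population are substituted with `zero_freq`
(default 0.01, the conventional "frequency for missing alleles").
Self-assignment accuracy uses leave-one-out: the individual's own alleles
are removed from its own population's reference counts. Ties count as
misassignments (a conservative forensic posture). The Bayesian
(Rannala–Mountain) criterion of some assignment programs is out of scope;
the frequency method is the simplest defensible choice for the published
accuracy regime.

## The synthetic-data generator

`simulate_dataset()` draws, per locus, ancestral allele frequencies from a
symmetric Dirichlet and population frequencies from the Balding–Nichols law
$\mathrm{Dir}(\bar p (1-F_{st})/F_{st})$ — chosen over coalescent machinery
because it is directly parameterised by $F_{st}$ and adequate for an
island-model design. Genotypes are drawn with inbreeding ($P(i,i) = p_i^2 +
F_{is} p_i(1-p_i)$, $P(i,j) = 2 p_i p_j (1-F_{is})$; strongly negative
$F_{is}$ that would make a genotype probability negative is a config
error). Planted linkage groups are *perfect* copies of a head locus with
relabelled alleles — the forensic rule only needs linked/unlinked status,
so partial LD is deliberately not modelled. Null alleles are one hidden
extra allele per affected locus at frequency `null_rate`: null/null
surfaces as missing, null/visible as a visible homozygote. An independent
missing mask is applied last. Allele labels are distinct even integers in
100–400 (fragment-size cosmetics only; all statistics treat labels as
opaque categories).

`cypress_sim_config()` freezes the stated world used throughout the tests:
4 populations (20/25/23/24), 36 loci, allele counts
$\min(2 + \mathrm{Pois}(5.9), 27)$ — matching the published range 2–27 and
mean 7.9, where a uniform draw would average 14.5 — Dirichlet
concentration 0.25, chosen once so the implied mean $H_e$ at those allele
counts sits near the published 0.565 (a Dirichlet(1) law would give ~0.73,
unrealistically even for SSR panels; measured mean $H_e$ over 20 seeds:
0.57), $F_{st} = 0.06$ and $F_{is} = 0.2$ inside the published ranges
0.035–0.074 and 0.132–0.242, two planted linkage groups (sizes 3 and 4),
null rate 0.02, missing rate 0.01.

What a green synthetic test does **not** establish: the generator has no
stepwise mutation structure, no spatial sampling, no partial LD and no
locus-specific null-allele biology, so it validates the estimators and the
pipeline plumbing, not the biological claims of any particular dataset.

## Numerical and design choices

* All probability products run in log space; `log1p` guards the
  $(1-CP_I)^N$ evaluation.
* Permutation p-values use the add-one rule $(1+\text{hits})/(1+\text{reps})$,
  so the smallest attainable p is $1/(1+\text{reps})$ — at $\alpha = 0.001$
  a scan needs reps $\ge 1000$; the tests use 1999 where the full 10,000
  would not fit the budget.
* Genepop files cannot carry population names (named from each block's
  first individual) and STRUCTURE stores an integer pop column, so
  round-trips through those formats preserve the population partition, not
  the label strings.
* Complete-case handling per locus everywhere; a locus with zero typed
  individuals is flagged, never silently dropped.
* Determinism: every stochastic routine takes a seed and restores the
  caller's RNG state; the same `sim_config` yields byte-identical output
  files.

## Worked example

```{r example, eval = FALSE}
cfg <- cypress_sim_config(seed = 7)
sim <- simulate_dataset(cfg)
report <- run_full_analysis(sim$matrix, ld_reps = 999, seed = 7)
print(report)
```

## Known limitations

* The chi-squared HWE far tail is anti-conservative for sparse multiallelic
  tables (see above); the exact MC test is the remedy.
* Nei pairwise $F_{st}$ understates $\theta$ for small numbers of
  populations by the $(k-1)/k$ factor; use `method = "wc"` for parameter
  interpretation.
* The assignment module implements only the frequency criterion; exclusion
  probabilities and Bayesian criteria are out of scope.
* No null-allele frequency estimators (Brookfield etc.) and no rarefied
  allelic richness.
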