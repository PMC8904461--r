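Package: ssrid
Title: Microsatellite Individual Identification and Population Genetics
Version: 0.1.0
Authors@R: person("SSR", "Tools", email = "ssrid@example.org", role = c("aut", "cre"))
Description: Forensic individual-identification and population-genetics
    statistics for diploid microsatellite (SSR) genotype data. Reads and
    writes GenAlEx, Genepop and STRUCTURE text formats; computes per-locus
    diversity and forensic statistics (A, Ho, He, PIC, power of
    discrimination, probability of identity, Hardy-Weinberg tests);
    performs permutation-based genotypic linkage-disequilibrium testing
    and linkage-aware locus selection; accumulates non-linked loci into
    combined probability of identity with confidence-level and
    identifiable-population-size calculations; estimates per-population
    diversity, Fis, pairwise Nei Fst and gene flow (Nm); post-processes
    clustering run likelihoods with the Evanno delta-K statistic; and
    assigns individuals to populations of origin by leave-one-out
    genotype-likelihood. Includes a Balding-Nichols genotype simulator
    with inbreeding, perfect-linkage groups, null alleles and missing data
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
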