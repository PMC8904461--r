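# Shared fixtures built in code.

# tiny deterministic matrix: 4 individuals, 2 loci, 2 populations
toy_matrix <- function() {
  genotype_matrix(
    a1 = rbind(c(100L, 1L), c(100L, 1L), c(102L, 2L), c(NA, 3L)),
    a2 = rbind(c(100L, 1L), c(102L, 2L), c(102L, 3L), c(NA, 3L)),
    individual_ids = c("i1", "i2", "i3", "i4"),
    locus_ids = c("LA", "LB"),
    populations = c("P1", "P1", "P2", "P2"))
}

# single-locus matrix from a list of allele pairs (NULL entries = missing)
locus_from_pairs <- function(pairs, pop = "P1") {
  a1 <- vapply(pairs, function(p) if (is.null(p)) NA_integer_
               else as.integer(p[1]), integer(1))
  a2 <- vapply(pairs, function(p) if (is.null(p)) NA_integer_
               else as.integer(p[2]), integer(1))
  genotype_matrix(matrix(a1), matrix(a2),
                  paste0("i", seq_along(pairs)), "L1",
                  rep(pop, length(pairs)))
}

# small random matrix for round-trip properties
random_matrix <- function(seed, n_pops = 2, pop_size = 5, n_loci = 4,
                          missing_rate = 0.1) {
  cfg <- sim_config(n_pops = n_pops, pop_sizes = rep(pop_size, n_pops),
                    n_loci = n_loci, alleles_per_locus = 4,
                    missing_rate = missing_rate, seed = seed)
  simulate_dataset(cfg)$matrix
}

# plain Dirichlet draw for oracles, independent of package internals
rdirichlet_test <- function(A, alpha = 1) {
  g <- rgamma(A, alpha)
  g / sum(g)
}
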