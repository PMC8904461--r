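test_that("perfect linkage is detected, degenerate tables are not", {
  cfg <- sim_config(n_pops = 1, pop_sizes = 50, n_loci = 2,
                    alleles_per_locus = 3, linked_groups = list(c(1L, 2L)),
                    seed = 21)
  m <- simulate_dataset(cfg)$matrix
  t <- ld_test_pair(m, 1, 2, reps = 10000, seed = 9)
  expect_lte(t$p_value, 0.001)

  # single occupied cell: G = 0, p = 1
  m1 <- genotype_matrix(cbind(rep(1L, 5), rep(3L, 5)),
                        cbind(rep(2L, 5), rep(3L, 5)),
                        paste0("i", 1:5), c("L1", "L2"), rep("P", 5))
  t1 <- ld_test_pair(m1, 1, 2, reps = 100, seed = 1)
  expect_equal(t1$G, 0)
  expect_equal(t1$p_value, 1)

  few <- genotype_matrix(cbind(c(1L, NA), c(NA, 1L)),
                         cbind(c(1L, NA), c(NA, 2L)),
                         c("a", "b"), c("L1", "L2"), c("P", "P"))
  expect_error(ld_test_pair(few, 1, 2, reps = 100, seed = 1),
               "fewer than 2")
})

test_that("LD permutation p-values are approximately uniform under the null", {
  set.seed(314)
  reject <- 0L
  n_pairs <- 1000
  for (r in seq_len(n_pairs)) {
    cfg <- sim_config(n_pops = 1, pop_sizes = 40, n_loci = 2,
                      alleles_per_locus = 3, seed = 100000 + r)
    m <- simulate_dataset(cfg)$matrix
    p <- ld_test_pair(m, 1, 2, reps = 199, seed = 200000 + r)$p_value
    if (p < 0.05) reject <- reject + 1L
  }
  expect_gte(reject / n_pairs, 0.03)
  expect_lte(reject / n_pairs, 0.07)
})

test_that("linkage groups are connected components of significant pairs", {
  loci <- paste0("L", 1:5)
  pairs <- data.frame(locusA = c("L1", "L2", "L4"),
                      locusB = c("L2", "L3", "L5"),
                      p_value = c(1e-5, 1e-4, 0.5))
  lg <- linkage_groups(pairs, loci, alpha = 0.001)
  expect_equal(lg$groups, list(c("L1", "L2", "L3"), "L4", "L5"))

  none <- data.frame(locusA = "L1", locusB = "L2", p_value = 0.5)
  lg0 <- linkage_groups(none, loci, alpha = 0.001)
  expect_equal(lengths(lg0$groups), rep(1L, 5))

  # untestable pairs (NA) contribute no edge
  nap <- data.frame(locusA = "L1", locusB = "L2", p_value = NA_real_)
  expect_equal(lengths(linkage_groups(nap, loci)$groups), rep(1L, 5))
})

test_that("the six study linkage groups yield 26 usable loci from 36", {
  loci <- c("Cred35", "Cred47", "Cred211", "Cred220", "Cred225", "Cred229",
            "Cred231", "Cred236", "Cred242", "Cred248", "Cred249", "Cred250",
            "Cred253", "Cred260", "Cred262", "Cred276", "Cred277", "Cred280",
            "Cred281", "Cred297", "Cred298", "Cred603", "Cred610", "Cred628",
            "Cred640", "Cred641", "Cred674", "Cred678", "Cred682", "Cred683",
            "CredA", "CredB", "CredC", "CredD", "CredE", "CredF")
  grp <- list(c("Cred35", "Cred229", "Cred277"),
              c("Cred47", "Cred298"),
              c("Cred231", "Cred249", "Cred253", "Cred262"),
              c("Cred281", "Cred297"),
              c("Cred603", "Cred683"),
              c("Cred640", "Cred678", "Cred682"))
  edges <- do.call(rbind, lapply(grp, function(g)
    t(combn(g, 2))))
  pairs <- data.frame(locusA = edges[, 1], locusB = edges[, 2],
                      p_value = 1e-6)
  lg <- linkage_groups(pairs, loci, alpha = 0.001)
  multi <- Filter(function(g) length(g) > 1, lg$groups)
  expect_equal(sort(lengths(multi)), c(2, 2, 2, 3, 3, 4))
  expect_equal(length(lg$groups), 26)   # 36 - (16 grouped - 6 reps)
  pi_vals <- setNames(seq(0.1, by = 0.01, length.out = 36), loci)
  lg <- select_representatives(lg, pi_vals)
  expect_length(lg$usable_loci, 26)
})

test_that("representative selection minimises PI with deterministic ties", {
  loci <- c("a", "b", "c")
  pairs <- data.frame(locusA = "a", locusB = "b", p_value = 1e-9)
  lg <- linkage_groups(pairs, loci)
  lg1 <- select_representatives(lg, c(a = 0.3, b = 0.2, c = 0.9))
  expect_equal(lg1$representatives, c("b", "c"))
  # PI tie: lexicographically smallest id wins
  lg2 <- select_representatives(lg, c(a = 0.2, b = 0.2, c = 0.9))
  expect_equal(lg2$representatives[1], "a")
  expect_error(select_representatives(lg, c(a = 0.1, b = NA, c = 0.9)),
               "PI missing")
  # representative PI <= every member PI
  for (g in seq_along(lg1$groups)) {
    pis <- c(a = 0.3, b = 0.2, c = 0.9)
    expect_true(all(pis[lg1$representatives[g]] <= pis[lg1$groups[[g]]]))
  }
})

test_that("grouping is order-independent and merging is monotone", {
  loci <- paste0("L", 1:6)
  pairs <- data.frame(locusA = c("L5", "L1"), locusB = c("L6", "L2"),
                      p_value = c(1e-5, 1e-5))
  g1 <- linkage_groups(pairs, loci)
  g2 <- linkage_groups(pairs[2:1, ], loci)
  expect_equal(g1$groups, g2$groups)
  # adding an edge never increases the number of groups
  more <- rbind(pairs, data.frame(locusA = "L2", locusB = "L5",
                                  p_value = 1e-5))
  expect_lte(length(linkage_groups(more, loci)$groups),
             length(g1$groups))
})

test_that("clique method splits components whose pairs are not all significant", {
  loci <- c("x", "y", "z")
  # x-y and y-z significant, x-z not: component = {x,y,z}, cliques split
  pairs <- data.frame(locusA = c("x", "y"), locusB = c("y", "z"),
                      p_value = c(1e-5, 1e-5))
  comp <- linkage_groups(pairs, loci, method = "component")
  expect_equal(comp$groups, list(c("x", "y", "z")))
  clq <- linkage_groups(pairs, loci, method = "clique")
  expect_equal(sort(lengths(clq$groups)), c(1, 2))
})
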