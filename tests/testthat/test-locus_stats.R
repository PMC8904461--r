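test_that("observed heterozygosity counts distinct-allele individuals", {
  expect_equal(observed_heterozygosity(
    locus_from_pairs(list(c(100, 100), c(100, 102), c(102, 102))), 1), 1 / 3)
  expect_equal(observed_heterozygosity(
    locus_from_pairs(list(c(1, 2), c(3, 4), c(5, 6))), 1), 1)
  expect_equal(observed_heterozygosity(
    locus_from_pairs(list(c(1, 2), c(1, 1), c(1, 2), c(2, 2))), 1), 0.5)
  expect_error(observed_heterozygosity(
    locus_from_pairs(list(NULL, NULL)), 1), "no typed individuals")
})

test_that("expected heterozygosity and the unbiased correction", {
  expect_equal(expected_heterozygosity(c(0.5, 0.5))$He, 0.5)
  expect_equal(expected_heterozygosity(1)$He, 0)
  expect_equal(expected_heterozygosity(c(0.375, 0.25, 0.375))$He, 0.65625)
  eh <- expected_heterozygosity(c(0.5, 0.5), n_typed = 10)
  expect_equal(eh$uHe, 0.5 * 20 / 19)
  expect_error(expected_heterozygosity(c(0.5, 0.6)), "sum to 1")
})

test_that("PIC follows the Botstein form", {
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(rep(0.25, 4)), 0.703125)
})

test_that("PD uses observed genotype frequencies; PI is its complement", {
  same <- locus_from_pairs(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(power_of_discrimination(same, 1), 0)
  half <- locus_from_pairs(list(c(1, 1), c(1, 1), c(1, 2), c(1, 2)))
  expect_equal(power_of_discrimination(half, 1), 0.5)
  three <- locus_from_pairs(list(c(1, 1), c(1, 2), c(2, 2)))
  expect_equal(power_of_discrimination(three, 1), 2 / 3)

  expect_equal(probability_of_identity(0), 1)
  expect_equal(probability_of_identity(0.75), 0.25)
})

test_that("PD/PI equal brute-force genotype enumeration on simulated loci", {
  # independent oracle: tabulate genotype multiset counts by string key
  oracle_pd <- function(a1, a2) {
    ok <- !is.na(a1)
    key <- paste(pmin(a1[ok], a2[ok]), pmax(a1[ok], a2[ok]))
    counts <- table(key)
    1 - sum((counts / sum(counts))^2)
  }
  set.seed(42)
  for (r in 1:100) {
    n <- sample(5:40, 1)
    A <- sample(2:8, 1)
    p <- as.numeric(rdirichlet_test(A))
    a1 <- sample.int(A, n, TRUE, p); a2 <- sample.int(A, n, TRUE, p)
    m <- locus_from_pairs(Map(c, a1, a2))
    pd <- power_of_discrimination(m, 1)
    expect_equal(pd, oracle_pd(a1, a2))
    expect_equal(probability_of_identity(pd), 1 - oracle_pd(a1, a2))
  }
})

test_that("chi2 HWE test reproduces hand-computed statistics", {
  # exact HWE proportions: chi2 = 0, p = 1
  perfect <- locus_from_pairs(c(replicate(25, c(1, 1), simplify = FALSE),
                                replicate(50, c(1, 2), simplify = FALSE),
                                replicate(25, c(2, 2), simplify = FALSE)))
  h <- hwe_test(perfect, 1)
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)

  # AA=30 AB=40 BB=30 -> expected 25/50/25, chi2 = 4, df = 1
  skewed <- locus_from_pairs(c(replicate(30, c(1, 1), simplify = FALSE),
                               replicate(40, c(1, 2), simplify = FALSE),
                               replicate(30, c(2, 2), simplify = FALSE)))
  h <- hwe_test(skewed, 1)
  expect_equal(h$statistic, 4)
  expect_equal(h$df, 1)
  expect_equal(h$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(h$p_value, 0.0455, tolerance = 1e-3)

  mono <- locus_from_pairs(list(c(1, 1), c(1, 1)))
  expect_error(hwe_test(mono, 1), "monomorphic")
})

test_that("exact MC HWE agrees with exhaustive re-pairing on a toy locus", {
  # 6 individuals, 12 allele copies: enumerate all perfect matchings of the
  # allele positions (11!! = 10395) and compute the exact permutation p.
  pairs <- list(c(1, 1), c(1, 2), c(2, 2), c(1, 3), c(3, 3), c(2, 3))
  m <- locus_from_pairs(pairs)
  alleles <- unlist(pairs)

  tab_logp <- function(g1, g2) {
    key <- paste(pmin(g1, g2), pmax(g1, g2))
    sum(g1 != g2) * log(2) - sum(lgamma(as.numeric(table(key)) + 1))
  }
  obs <- tab_logp(alleles[c(1, 3, 5, 7, 9, 11)], alleles[c(2, 4, 6, 8, 10, 12)])

  match_stats <- c()
  enumerate <- function(pos, acc1, acc2) {
    if (length(pos) == 0) {
      match_stats <<- c(match_stats, tab_logp(acc1, acc2))
      return(invisible())
    }
    first <- pos[1]
    for (k in seq_along(pos)[-1])
      enumerate(pos[-c(1, k)], c(acc1, alleles[first]),
                c(acc2, alleles[pos[k]]))
  }
  enumerate(seq_along(alleles), integer(0), integer(0))
  expect_length(match_stats, 10395)
  exact_p <- mean(match_stats <= obs + 1e-9)

  mc <- hwe_test(m, 1, method = "exact_mc", mc_reps = 20000, seed = 5)
  se <- sqrt(exact_p * (1 - exact_p) / 20000)
  expect_lt(abs(mc$p_value - exact_p), 4 * se + 1e-4)
})

test_that("summarize_loci composes per-locus operations with means", {
  m <- toy_matrix()
  s <- summarize_loci(m)
  expect_equal(nrow(s), 2)
  expect_equal(s$Ho[1], observed_heterozygosity(m, 1))
  expect_equal(s$PD[2], power_of_discrimination(m, 2))
  expect_equal(s$PI, 1 - s$PD)

  sim <- simulate_dataset(cypress_sim_config(seed = 3))$matrix
  s <- summarize_loci(sim)
  expect_equal(nrow(s), 36)
  means <- attr(s, "means")
  expect_equal(unname(means["PD"] + means["PI"]), 1)
  # invariants per locus
  ok <- !is.na(s$A)
  expect_true(all(s$PD[ok] + s$PI[ok] == 1))
  expect_true(all(s$PIC[ok] <= s$He[ok] + 1e-12))
  expect_true(all(s$He[ok] <= 1 - 1 / s$A[ok] + 1e-12))
  expect_true(all(s$Ho[ok] >= 0 & s$Ho[ok] <= 1))
  expect_true(all(s$A[ok] >= 2 | s$He[ok] == 0))
})

test_that("Ho tracks He according to the simulated inbreeding level", {
  base <- list(n_pops = 1, pop_sizes = 500, n_loci = 30,
               alleles_per_locus = 6, seed = 77)
  m0 <- simulate_dataset(do.call(sim_config, c(base, fis = 0)))$matrix
  s0 <- summarize_loci(m0)
  expect_lt(abs(mean(s0$Ho - s0$He)), 0.02)

  mF <- simulate_dataset(do.call(sim_config, c(base, fis = 0.3)))$matrix
  sF <- summarize_loci(mF)
  expect_gt(mean(sF$He - sF$Ho), 0.1)   # Ho < He under inbreeding
})
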