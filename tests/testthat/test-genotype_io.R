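test_that("genotype_matrix validates and normalises unordered pairs", {
  m <- toy_matrix()
  expect_s3_class(m, "genotype_matrix")
  # storing (a,b) vs (b,a) yields the same object
  sw <- genotype_matrix(m$a2, m$a1, m$individual_ids, m$locus_ids,
                        m$populations)
  expect_true(genotypes_equal(m, sw))
  expect_error(genotype_matrix(matrix(1L), matrix(2L), c("a"), c("L", "L2"),
                               "P"), "individuals x loci")
  expect_error(genotype_matrix(rbind(1L, 1L), rbind(2L, 2L), c("a", "a"),
                               "L", c("P", "P")), "duplicate individual")
  expect_error(genotype_matrix(matrix(0L), matrix(2L), "a", "L", "P"),
               "positive")
  expect_error(genotype_matrix(matrix(NA_integer_), matrix(2L), "a", "L",
                               "P"), "half-missing")
})

test_that("allele_frequencies counts symmetric, complete-case, sums to 1", {
  m <- locus_from_pairs(list(c(100, 100), c(100, 102), c(102, 102)))
  af <- allele_frequencies(m)
  expect_equal(af$freqs$L1, c(`100` = 0.5, `102` = 0.5))
  expect_equal(unname(af$n_typed), 3L)

  m2 <- locus_from_pairs(list(c(1, 1), c(1, 2), c(2, 3), c(3, 3)))
  expect_equal(allele_frequencies(m2)$freqs$L1,
               c(`1` = 0.375, `2` = 0.25, `3` = 0.375))

  # one missing individual: frequencies over the remaining 4 allele copies
  m3 <- locus_from_pairs(list(c(100, 100), NULL, c(102, 102)))
  af3 <- allele_frequencies(m3)
  expect_equal(af3$freqs$L1, c(`100` = 0.5, `102` = 0.5))
  expect_equal(unname(af3$n_typed), 2L)

  expect_error(allele_frequencies(toy_matrix(), "nosuchpop"), "unknown")
})

test_that("frequencies sum to 1 and zero-typed loci are flagged not dropped", {
  for (s in 1:10) {
    m <- random_matrix(s, missing_rate = 0.3)
    af <- allele_frequencies(m)
    for (j in seq_along(af$freqs))
      if (af$n_typed[j] > 0) expect_equal(sum(af$freqs[[j]]), 1)
  }
  m <- locus_from_pairs(list(NULL, NULL))
  af <- allele_frequencies(m)
  expect_identical(af$zero_typed, "L1")
  expect_length(af$freqs$L1, 0)
})

test_that("GenAlEx read/write round-trips and maps 0 to missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  # hand-written 3-individual, 2-locus, 1-population fixture
  writeLines(c("2,3,1,3",
               "toy,,,popA",
               "Ind,Pop,L1,,L2,",
               "s1,popA,100,102,1,1",
               "s2,popA,0,0,1,2",
               "s3,popA,102,102,2,2"), path)
  m <- read_genalex(path)
  expect_equal(n_individuals(m), 3)
  expect_equal(n_loci(m), 2)
  expect_true(is.na(m$a1[2, 1]) && is.na(m$a2[2, 1]))  # "0 0" -> MISSING
  expect_equal(m$populations, rep("popA", 3))

  for (s in 1:50) {
    sim <- random_matrix(s)
    write_genalex(sim, path)
    expect_true(genotypes_equal(read_genalex(path), sim),
                label = paste("genalex round-trip, seed", s))
  }
})

test_that("GenAlEx reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("2,3,1,3", "t,,,p", "Ind,Pop,L1,,L2,",
               "s1,p,1,1,2,2"), path)               # 1 body row, header says 3
  expect_error(read_genalex(path), "3 individuals")
  writeLines(c("2,2,1,2", "t,,,p", "Ind,Pop,L1,,L2,",
               "s1,p,1,1,2,2", "s1,p,1,1,2,2"), path)
  expect_error(read_genalex(path), "duplicate individual")
})

test_that("Genepop coding rules, missing code and round-trip", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "L1", "L2", "Pop",
               "a1, 101103 000000",
               "a2, 101101 002002"), path)
  m <- read_genepop(path)
  expect_equal(c(m$a1[1, 1], m$a2[1, 1]), c(101L, 103L))  # "101103"
  expect_true(is.na(m$a1[1, 2]))                          # "000000"
  expect_equal(c(m$a1[2, 2], m$a2[2, 2]), c(2L, 2L))      # 3-digit "002"

  writeLines(c("t", "L1", "Pop", "a1, 101103", "a2, 0101"), path)
  expect_error(read_genepop(path), "mixed 2- and 3-digit")

  for (s in 1:20) {
    sim <- random_matrix(s)
    write_genepop(sim, path)
    # pop label strings are not representable in Genepop; partition must match
    expect_true(genotypes_equal(read_genepop(path), sim, labels = FALSE),
                label = paste("genepop round-trip, seed", s))
  }
})

test_that("STRUCTURE two-row layout, -9 missing, round-trip", {
  path <- withr::local_tempfile(fileext = ".str")
  writeLines(c("L1 L2",
               "a1 1 100 -9",
               "a1 1 102 -9",
               "a2 1 100 200",
               "a2 1 100 202"), path)
  m <- read_structure(path)
  expect_equal(c(m$a1[1, 1], m$a2[1, 1]), c(100L, 102L))
  expect_true(is.na(m$a1[1, 2]))                          # -9 -> MISSING
  expect_false(is.na(m$a1[2, 2]))

  writeLines(c("L1", "a1 1 100", "a1 1 102", "a2 1 100"), path)
  expect_error(read_structure(path), "odd number of rows")

  for (s in 1:20) {
    sim <- random_matrix(s)
    write_structure(sim, path)
    expect_true(genotypes_equal(read_structure(path), sim, labels = FALSE),
                label = paste("structure round-trip, seed", s))
  }
})

test_that("permuting allele columns leaves downstream statistics unchanged", {
  m <- random_matrix(11)
  sw <- genotype_matrix(m$a2, m$a1, m$individual_ids, m$locus_ids,
                        m$populations)
  expect_identical(summarize_loci(m), summarize_loci(sw))
  expect_identical(assign_all(m)$overall_pct, assign_all(sw)$overall_pct)
})
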