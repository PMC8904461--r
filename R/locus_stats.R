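#' Observed heterozygosity at a locus
#'
#' Proportion of typed individuals carrying two distinct alleles.
#'
#' @param x a [genotype_matrix].
#' @param locus locus id or column index.
#' @param subset optional population label(s) or individual ids.
#' @return Ho in `[0, 1]`.
#' @export
observed_heterozygosity <- function(x, locus, subset = NULL) {
  ii <- resolve_subset(x, subset)
  j <- locus_index(x, locus)
  a1 <- x$a1[ii, j]; a2 <- x$a2[ii, j]
  ok <- !is.na(a1)
  if (!any(ok)) stop("no typed individuals at locus ", x$locus_ids[j])
  mean(a1[ok] != a2[ok])
}

#' Expected heterozygosity from allele frequencies
#'
#' `He = 1 - sum(p^2)` (the GenAlEx definition) and the small-sample
#' unbiased version `uHe = He * 2n / (2n - 1)`.
#'
#' @param p numeric vector of allele frequencies (sums to 1).
#' @param n_typed number of diploid individuals behind `p` (needed for uHe).
#' @return list with `He` and `uHe` (`uHe` is `NA` when `n_typed` is missing).
#' @export
expected_heterozygosity <- function(p, n_typed = NA) {
  check_freqs(p)
  he <- 1 - sum(p^2)
  uhe <- if (is.na(n_typed)) NA_real_ else {
    if (n_typed < 1) stop("n_typed must be >= 1")
    he * 2 * n_typed / (2 * n_typed - 1)
  }
  list(He = he, uHe = uhe)
}

#' Polymorphism information content
#'
#' Botstein's PIC: `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. Computed via
#' power sums: with `S2 = sum(p^2)`, `S4 = sum(p^4)`, the cross term equals
#' `S2^2 - S4`.
#'
#' @param p numeric vector of allele frequencies.
#' @return PIC in `[0, 1)`.
#' @export
pic <- function(p) {
  check_freqs(p)
  s2 <- sum(p^2); s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

#' Power of discrimination at a locus
#'
#' `PD = 1 - sum(P_i^2)` where `P_i` are genotype frequencies among typed
#' individuals. The default uses observed unordered-genotype frequencies;
#' `mode = "expected"` substitutes Hardy-Weinberg expected genotype
#' frequencies computed from the allele frequencies (sensitivity option).
#'
#' @param x a [genotype_matrix].
#' @param locus locus id or index.
#' @param subset optional population label(s) or individual ids.
#' @param mode `"observed"` (default) or `"expected"`.
#' @return PD in `[0, 1)`.
#' @export
power_of_discrimination <- function(x, locus, subset = NULL,
                                    mode = c("observed", "expected")) {
  mode <- match.arg(mode)
  ii <- resolve_subset(x, subset)
  j <- locus_index(x, locus)
  a1 <- x$a1[ii, j]; a2 <- x$a2[ii, j]
  ok <- !is.na(a1)
  if (!any(ok)) stop("no typed individuals at locus ", x$locus_ids[j])
  if (mode == "observed") {
    g <- paste(a1[ok], a2[ok], sep = "/")
    f <- as.numeric(table(g)) / sum(ok)
    return(1 - sum(f^2))
  }
  p <- allele_frequencies(subset_genotypes(x, ii, j))$freqs[[1]]
  # HWE genotype frequencies: hom p_i^2, het 2 p_i p_j
  gp <- outer(p, p)
  1 - (sum(diag(gp)^2) + sum(4 * gp[upper.tri(gp)]^2))
}

#' Probability of identity
#'
#' The complement of the power of discrimination: `PI = 1 - PD`, the
#' probability that two random individuals share a genotype at the locus.
#'
#' @param pd power of discrimination in `[0, 1]`.
#' @return PI in `[0, 1]`.
#' @export
probability_of_identity <- function(pd) {
  if (any(pd < 0 | pd > 1)) stop("PD must lie in [0, 1]")
  1 - pd
}

#' Hardy-Weinberg equilibrium test at a locus
#'
#' `method = "chi2"` computes the classical goodness-of-fit statistic
#' `sum((obs - exp)^2 / exp)` over all `A(A+1)/2` genotype classes with
#' `df = A(A-1)/2` (the GenAlEx convention, no pooling of rare classes).
#' `method = "exact_mc"` is a Guo-Thompson style Monte-Carlo exact test:
#' the 2n observed alleles are randomly re-paired into diploids `mc_reps`
#' times and the conditional probability of each permuted genotype table is
#' compared with the observed one;
#' `p = (1 + #(P_perm <= P_obs)) / (1 + mc_reps)`.
#'
#' @param x a [genotype_matrix].
#' @param locus locus id or index.
#' @param subset optional population label(s) or individual ids.
#' @param method `"chi2"` or `"exact_mc"`.
#' @param mc_reps Monte-Carlo replicates for `"exact_mc"`.
#' @param seed integer seed (required for `"exact_mc"`).
#' @return list with `p_value`, and for chi2 also `statistic` and `df`.
#' @export
hwe_test <- function(x, locus, subset = NULL,
                     method = c("chi2", "exact_mc"),
                     mc_reps = 10000, seed = NULL) {
  method <- match.arg(method)
  ii <- resolve_subset(x, subset)
  j <- locus_index(x, locus)
  a1 <- x$a1[ii, j]; a2 <- x$a2[ii, j]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n == 0) stop("no typed individuals at locus ", x$locus_ids[j])
  alleles <- sort(unique(c(a1, a2)))
  A <- length(alleles)
  if (A < 2)
    stop("monomorphic locus ", x$locus_ids[j], ": HWE test not applicable")
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)

  if (method == "chi2") {
    obs <- matrix(0, A, A)
    for (k in seq_len(n)) obs[i1[k], i2[k]] <- obs[i1[k], i2[k]] + 1
    p <- tabulate(c(i1, i2), A) / (2 * n)
    expd <- matrix(0, A, A)
    for (a in seq_len(A)) for (b in a:A)
      expd[a, b] <- if (a == b) n * p[a]^2 else 2 * n * p[a] * p[b]
    keep <- upper.tri(expd, diag = TRUE) & expd > 0
    stat <- sum((obs[keep] - expd[keep])^2 / expd[keep])
    df <- A * (A - 1) / 2
    return(list(p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                statistic = stat, df = df, method = "chi2"))
  }

  if (is.null(seed)) stop("exact_mc requires a seed for reproducibility")
  # table log-probability up to the constant shared by all re-pairings:
  # h*log(2) - sum(log(genotype count!))  (allele counts are invariant)
  tab_logp <- function(g1, g2) {
    key <- pmin.int(g1, g2) + A * pmax.int(g1, g2)
    cnt <- table(key)
    sum(g1 != g2) * log(2) - sum(lgamma(as.numeric(cnt) + 1))
  }
  obs_lp <- tab_logp(i1, i2)
  pool <- c(i1, i2)
  hits <- 0L
  with_seed(seed, {
    for (r in seq_len(mc_reps)) {
      s <- sample(pool)
      h1 <- s[seq_len(n)]; h2 <- s[n + seq_len(n)]
      if (tab_logp(h1, h2) <= obs_lp + 1e-9) hits <- hits + 1L
    }
  })
  list(p_value = (1 + hits) / (1 + mc_reps), method = "exact_mc",
       reps = mc_reps)
}

#' Per-locus summary table
#'
#' One row per locus with A, Ho, He, uHe, PIC, PD, PI, the HWE p-value and
#' the number of typed individuals, plus column means over defined entries
#' (stored in `attr(, "means")` and appended by [write_locus_summary]).
#' Monomorphic loci get `NA` for the HWE p-value; loci with no data get
#' `NA` throughout.
#'
#' @param x a [genotype_matrix].
#' @param subset optional population label(s) or individual ids.
#' @param hwe_method `"chi2"` (default) or `"exact_mc"`.
#' @param mc_reps,seed passed to [hwe_test] for `"exact_mc"`.
#' @param pd_mode passed to [power_of_discrimination].
#' @return a data.frame of class `locus_summary`.
#' @export
summarize_loci <- function(x, subset = NULL, hwe_method = "chi2",
                           mc_reps = 10000, seed = NULL,
                           pd_mode = "observed") {
  ii <- resolve_subset(x, subset)
  af <- allele_frequencies(x, ii)
  L <- n_loci(x)
  out <- data.frame(locus = x$locus_ids,
                    A = NA_integer_, Ho = NA_real_, He = NA_real_,
                    uHe = NA_real_, PIC = NA_real_, PD = NA_real_,
                    PI = NA_real_, HWE_p = NA_real_,
                    n_typed = as.integer(af$n_typed),
                    stringsAsFactors = FALSE)
  for (j in seq_len(L)) {
    if (af$n_typed[j] == 0) next
    p <- af$freqs[[j]]
    out$A[j] <- length(p)
    out$Ho[j] <- observed_heterozygosity(x, j, ii)
    eh <- expected_heterozygosity(p, af$n_typed[j])
    out$He[j] <- eh$He; out$uHe[j] <- eh$uHe
    out$PIC[j] <- pic(p)
    out$PD[j] <- power_of_discrimination(x, j, ii, mode = pd_mode)
    out$PI[j] <- 1 - out$PD[j]
    if (out$A[j] >= 2) {
      ht <- hwe_test(x, j, ii, method = hwe_method,
                     mc_reps = mc_reps, seed = seed)
      out$HWE_p[j] <- ht$p_value
    }
  }
  num <- c("A", "Ho", "He", "uHe", "PIC", "PD", "PI", "HWE_p", "n_typed")
  attr(out, "means") <- vapply(out[num], function(v) mean(v, na.rm = TRUE),
                               numeric(1))
  class(out) <- c("locus_summary", "data.frame")
  out
}

#' Write a locus summary as CSV with a footer row of means
#' @param summary a `locus_summary` from [summarize_loci].
#' @param path output path.
#' @param sep field separator (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_locus_summary <- function(summary, path, sep = ",") {
  df <- as.data.frame(summary)
  means <- attr(summary, "means")
  footer <- data.frame(locus = "mean", t(means), stringsAsFactors = FALSE)
  names(footer) <- names(df)
  utils::write.table(rbind(df, footer), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# -- helpers ------------------------------------------------------------

locus_index <- function(x, locus) {
  if (is.character(locus)) {
    j <- match(locus, x$locus_ids)
    if (is.na(j)) stop("unknown locus id: ", locus)
    j
  } else as.integer(locus)
}

check_freqs <- function(p) {
  if (length(p) < 1 || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("allele frequencies must be non-negative and sum to 1")
  invisible(TRUE)
}

# Run code with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
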