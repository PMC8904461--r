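#' Genotype log-likelihood under a population's allele frequencies
#'
#' Sums, over non-missing loci, the log probability of the individual's
#' genotype given the population's allele frequencies: `p_a^2` for a
#' homozygote and `2 p_a p_b` for a heterozygote. Any allele absent from
#' (or at frequency zero in) the reference population is substituted with
#' `zero_freq` before the term is computed; missing loci contribute 0.
#'
#' @param a1,a2 integer vectors of the individual's two allele labels per
#'   locus (`NA` for missing loci).
#' @param freqs list per locus of named allele-frequency vectors (as in the
#'   `freqs` field of [allele_frequencies]).
#' @param zero_freq substitute frequency for unseen alleles, in `(0, 0.1]`.
#' @return the summed log-likelihood.
#' @export
genotype_log_likelihood <- function(a1, a2, freqs, zero_freq = 0.01) {
  if (zero_freq <= 0 || zero_freq > 0.1)
    stop("zero_freq must lie in (0, 0.1]")
  if (all(is.na(a1))) stop("individual is missing at all loci")
  ll <- 0
  for (j in seq_along(freqs)) {
    if (is.na(a1[j])) next
    p <- freqs[[j]]
    pa <- p[as.character(a1[j])]
    pb <- p[as.character(a2[j])]
    if (is.na(pa) || pa == 0) pa <- zero_freq
    if (is.na(pb) || pb == 0) pb <- zero_freq
    ll <- ll + if (a1[j] == a2[j]) log(pa * pb) else log(2 * pa * pb)
  }
  unname(ll)
}

#' Population-of-origin assignment for every individual
#'
#' Frequency-method assignment (Paetkau style): each individual is assigned
#' to the candidate population maximising its genotype log-likelihood. With
#' `leave_one_out = TRUE` (the self-assignment protocol) the individual's
#' own alleles are removed from its own population's reference frequencies
#' before scoring. Log-likelihood ties are counted as misassignments:
#' among tied populations the individual's own population is considered
#' last, remaining ties break lexicographically.
#'
#' @param x a [genotype_matrix] with at least two populations (one is
#'   allowed and trivially yields 100%).
#' @param zero_freq substitute frequency for unseen alleles.
#' @param leave_one_out exclude each individual from its own reference?
#' @return an `assignment_result`: list with `individuals` (data.frame:
#'   `individual`, `population`, `assigned`, `correct`, one `ll_<pop>`
#'   column per candidate), `populations` (data.frame: `population`, `N`,
#'   `correct`, `pct_correct`), and `overall_pct` (total correct / total
#'   scored x 100).
#' @export
assign_all <- function(x, zero_freq = 0.01, leave_one_out = TRUE) {
  pops <- population_levels(x)
  k <- length(pops)
  n <- n_individuals(x)
  L <- n_loci(x)
  # per-locus allele count tables per population
  counts <- vector("list", L)
  for (j in seq_len(L)) {
    alleles <- sort(unique(c(x$a1[, j], x$a2[, j])))
    alleles <- alleles[!is.na(alleles)]
    cm <- matrix(0L, length(alleles), k,
                 dimnames = list(as.character(alleles), pops))
    for (p in seq_len(k)) {
      ii <- which(x$populations == pops[p])
      ok <- ii[!is.na(x$a1[ii, j])]
      if (length(ok))
        cm[, p] <- tabulate(factor(c(x$a1[ok, j], x$a2[ok, j]),
                                   levels = alleles), length(alleles))
    }
    counts[[j]] <- cm
  }
  pop_sizes <- tabulate(factor(x$populations, levels = pops))
  ll <- matrix(NA_real_, n, k, dimnames = list(x$individual_ids, pops))
  excluded <- logical(n)
  for (i in seq_len(n)) {
    own <- match(x$populations[i], pops)
    if (leave_one_out && pop_sizes[own] == 1L) {
      excluded[i] <- TRUE
      warning("population '", pops[own], "' has a single individual; '",
              x$individual_ids[i], "' excluded from leave-one-out accuracy")
    }
    for (p in seq_len(k)) {
      s <- 0
      skip <- FALSE
      for (j in seq_len(L)) {
        if (is.na(x$a1[i, j])) next
        cm <- counts[[j]][, p]
        names(cm) <- rownames(counts[[j]])  # 1-allele loci drop names
        tot <- sum(cm)
        if (leave_one_out && p == own) {
          ka <- as.character(x$a1[i, j]); kb <- as.character(x$a2[i, j])
          cm[ka] <- cm[ka] - 1L
          cm[kb] <- cm[kb] - 1L
          tot <- tot - 2L
        }
        if (tot <= 0) { pa <- zero_freq; pb <- zero_freq }
        else {
          pa <- cm[as.character(x$a1[i, j])] / tot
          pb <- cm[as.character(x$a2[i, j])] / tot
          if (pa == 0) pa <- zero_freq
          if (pb == 0) pb <- zero_freq
        }
        s <- s + if (x$a1[i, j] == x$a2[i, j]) log(pa * pb)
                 else log(2 * pa * pb)
      }
      ll[i, p] <- s
    }
  }
  top <- apply(ll, 1, max)
  assigned <- character(n); correct <- logical(n)
  for (i in seq_len(n)) {
    tied <- pops[ll[i, ] >= top[i] - 1e-9]
    own <- x$populations[i]
    if (length(tied) == 1) {
      assigned[i] <- tied
      correct[i] <- tied == own
    } else {
      others <- setdiff(tied, own)
      assigned[i] <- if (length(others)) sort(others)[1] else own
      correct[i] <- FALSE    # ties are conservative misassignments
    }
  }
  ind <- data.frame(individual = x$individual_ids,
                    population = x$populations,
                    assigned = assigned, correct = correct,
                    excluded = excluded, stringsAsFactors = FALSE)
  for (p in seq_len(k)) ind[[paste0("ll_", pops[p])]] <- ll[, p]
  scored <- !excluded
  per_pop <- do.call(rbind, lapply(pops, function(p) {
    sel <- scored & x$populations == p
    data.frame(population = p, N = sum(sel), correct = sum(correct[sel]),
               pct_correct = if (sum(sel)) 100 * mean(correct[sel])
                             else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(individuals = ind, populations = per_pop,
                 overall_pct = 100 * sum(correct[scored]) / sum(scored),
                 zero_freq = zero_freq, leave_one_out = leave_one_out),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("assignment_result (leave-one-out:", x$leave_one_out, ")\n")
  print(x$populations, row.names = FALSE)
  cat(sprintf("overall correct: %.2f%%\n", x$overall_pct))
  invisible(x)
}
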