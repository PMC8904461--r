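#' Inbreeding coefficient from heterozygosities
#'
#' `Fis = 1 - Ho / He`; positive under inbreeding, zero at random mating.
#'
#' @param ho observed heterozygosity.
#' @param he expected heterozygosity (> 0).
#' @return Fis.
#' @export
fis <- function(ho, he) {
  if (any(he <= 0)) stop("Fis undefined for He <= 0")
  1 - ho / he
}

#' Per-population diversity summaries
#'
#' For each population, per-locus A, Ho and He are computed from that
#' population's individuals only (complete-case per locus) and averaged
#' over loci with data; `Fis = 1 - mean(Ho) / mean(He)` from the unrounded
#' means. Populations whose loci are all monomorphic or untyped get a
#' flagged `NA` Fis.
#'
#' @param x a [genotype_matrix].
#' @return data.frame with columns `population`, `N`, `A`, `Ho`, `He`,
#'   `Fis`; one row per population in order of first appearance.
#' @export
population_summaries <- function(x) {
  pops <- population_levels(x)
  rows <- lapply(pops, function(p) {
    ii <- which(x$populations == p)
    af <- allele_frequencies(x, ii)
    typed <- which(af$n_typed > 0)
    A <- vapply(af$freqs[typed], length, integer(1))
    He <- vapply(af$freqs[typed], function(q) 1 - sum(q^2), numeric(1))
    Ho <- vapply(typed, function(j) observed_heterozygosity(x, j, ii),
                 numeric(1))
    mHo <- mean(Ho); mHe <- mean(He)
    data.frame(population = p, N = length(ii),
               A = mean(A), Ho = mHo, He = mHe,
               Fis = if (length(typed) == 0 || mHe <= 0) NA_real_
                     else 1 - mHo / mHe,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise Fst between two populations
#'
#' The default (`method = "nei"`) is the frequency-based Nei estimator used
#' by GenAlEx-style pairwise Fst: per locus `Hs` is the mean of the two
#' within-population expected heterozygosities and `Ht` the expected
#' heterozygosity of the mean allele-frequency vector; locus values are
#' combined by summing `Ht` and `Hs` over loci before taking
#' `Fst = (sum Ht - sum Hs) / sum Ht`. Note that with only two populations
#' this quantity converges to roughly half the Balding-Nichols theta
#' (the classical Gst `(k-1)/k` factor). `method = "wc"` computes the
#' Weir-Cockerham theta estimator, which targets theta itself with any
#' number of populations and is the right choice for parameter recovery.
#'
#' @param x a [genotype_matrix].
#' @param popA,popB population labels.
#' @param method `"nei"` (default) or `"wc"`.
#' @return Fst estimate (clamped to `[0, 1]` for `"nei"`; `"wc"` may be
#'   slightly negative by construction and is returned as-is).
#' @export
pairwise_fst <- function(x, popA, popB, method = c("nei", "wc")) {
  method <- match.arg(method)
  if (method == "wc") return(wc_theta(x, c(popA, popB)))
  fa <- allele_frequencies(x, popA)
  fb <- allele_frequencies(x, popB)
  ht_sum <- 0; hs_sum <- 0
  for (j in seq_along(fa$freqs)) {
    pa <- fa$freqs[[j]]; pb <- fb$freqs[[j]]
    if (length(pa) == 0 || length(pb) == 0) next
    alleles <- sort(unique(c(names(pa), names(pb))))
    va <- setNames(numeric(length(alleles)), alleles)
    vb <- va
    va[names(pa)] <- pa; vb[names(pb)] <- pb
    hs <- ((1 - sum(va^2)) + (1 - sum(vb^2))) / 2
    q <- (va + vb) / 2
    ht <- 1 - sum(q^2)
    hs_sum <- hs_sum + hs; ht_sum <- ht_sum + ht
  }
  if (ht_sum <= 0) return(0)  # both monomorphic and identical everywhere
  max(0, min(1, (ht_sum - hs_sum) / ht_sum))
}

# Weir & Cockerham (1984) theta over the given populations, summing the
# a, b, c variance components over alleles and loci.
wc_theta <- function(x, pops) {
  r <- length(pops)
  if (r < 2) stop("need at least two populations")
  idx <- lapply(pops, function(p) resolve_subset(x, p))
  a_sum <- 0; abc_sum <- 0
  for (j in seq_len(n_loci(x))) {
    ni <- numeric(r)
    pmat <- list(); hmat <- list()
    alleles <- integer(0)
    for (k in seq_len(r)) {
      a1 <- x$a1[idx[[k]], j]; a2 <- x$a2[idx[[k]], j]
      ok <- !is.na(a1)
      ni[k] <- sum(ok)
      pmat[[k]] <- c(a1[ok], a2[ok])
      hmat[[k]] <- cbind(a1[ok], a2[ok])
      alleles <- union(alleles, pmat[[k]])
    }
    if (any(ni < 2) || length(alleles) < 2) next
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (al in alleles) {
      p_i <- vapply(seq_len(r), function(k) mean(pmat[[k]] == al), numeric(1))
      h_i <- vapply(seq_len(r), function(k)
        mean(xor(hmat[[k]][, 1] == al, hmat[[k]][, 2] == al)), numeric(1))
      pbar <- sum(ni * p_i) / (r * nbar)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / (r * nbar)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      a_sum <- a_sum + a; abc_sum <- abc_sum + a + b + cc
    }
  }
  if (abc_sum == 0) return(0)
  a_sum / abc_sum
}

#' Pairwise Fst and Nm matrices over all populations
#'
#' @param x a [genotype_matrix].
#' @param method Fst estimator, see [pairwise_fst].
#' @return a `pop_diff_matrix`: list with `populations`, symmetric `fst`
#'   matrix (diagonal 0) and the derived `nm` matrix.
#' @export
fst_matrix <- function(x, method = "nei") {
  pops <- population_levels(x)
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    fst[i, j] <- fst[j, i] <- pairwise_fst(x, pops[i], pops[j],
                                           method = method)
  }
  nm <- matrix(Inf, k, k, dimnames = list(pops, pops))
  pos <- fst > 0
  nm[pos] <- nm_from_fst(fst[pos])
  diag(nm) <- NA_real_
  structure(list(populations = pops, fst = fst, nm = nm, method = method),
            class = "pop_diff_matrix")
}

#' Gene flow from Fst (island model)
#'
#' `Nm = 0.25 * (1 - Fst) / Fst`, the effective number of migrants per
#' generation under the infinite-island model (the GenAlEx convention).
#'
#' @param fst Fst in `(0, 1]`.
#' @return Nm; `Inf` for `Fst = 0`.
#' @export
nm_from_fst <- function(fst) {
  if (any(fst < 0 | fst > 1)) stop("Fst must lie in [0, 1]")
  ifelse(fst == 0, Inf, 0.25 * (1 - fst) / fst)
}

#' @export
print.pop_diff_matrix <- function(x, ...) {
  cat("pop_diff_matrix (", x$method, " Fst):\n", sep = "")
  print(round(x$fst, 3))
  invisible(x)
}

#' Evanno delta-K from clustering run likelihoods
#'
#' Post-processes a table of log-probabilities of the data from repeated
#' clustering runs at successive K: `L'(K) = L(K) - L(K-1)` on run means,
#' `|L''(K)| = |L'(K+1) - L'(K)|`, and `deltaK = |L''(K)| / sd(L(K))` with
#' the standard deviation taken across runs at K. deltaK is defined only at
#' interior K with at least two runs and positive sd.
#'
#' @param ktable data.frame with columns `K`, `run`, `lnP`.
#' @return data.frame with one row per K: `K`, `n_runs`, `mean_lnP`,
#'   `sd_lnP`, `Lp` (first difference), `Lpp` (|second difference|),
#'   `deltaK`; the K maximising deltaK is in `attr(, "best_K")`.
#' @export
delta_k <- function(ktable) {
  need <- c("K", "run", "lnP")
  if (!all(need %in% names(ktable)))
    stop("ktable needs columns K, run, lnP")
  ks <- sort(unique(ktable$K))
  if (length(ks) < 3) stop("need at least 3 consecutive K values")
  m <- vapply(ks, function(k) mean(ktable$lnP[ktable$K == k]), numeric(1))
  s <- vapply(ks, function(k) stats::sd(ktable$lnP[ktable$K == k]),
              numeric(1))
  nr <- vapply(ks, function(k) sum(ktable$K == k), integer(1))
  lp <- c(NA, diff(m))                       # L'(K), defined from 2nd K
  lpp <- c(NA, abs(diff(lp[-1])), NA)        # |L''(K)| at interior K
  dk <- lpp / s
  dk[is.na(lpp) | nr < 2 | !is.finite(s) | s == 0] <- NA_real_
  out <- data.frame(K = ks, n_runs = nr, mean_lnP = m, sd_lnP = s,
                    Lp = lp, Lpp = lpp, deltaK = dk)
  attr(out, "best_K") <-
    if (all(is.na(dk))) NA_integer_ else ks[which.max(dk)]
  out
}
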