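#' Simulation configuration
#'
#' Fully parameterises the Balding-Nichols genotype simulator: population
#' layout, target differentiation (Fst) and inbreeding (Fis), the allele
#' law at each locus, perfectly linked locus groups, null-allele and
#' missing-data rates, and the mandatory seed.
#'
#' @param n_pops number of populations.
#' @param pop_sizes integer vector (length `n_pops`) of diploid individuals
#'   per population.
#' @param n_loci number of loci.
#' @param alleles_per_locus scalar or length-`n_loci` integer vector of
#'   allele counts; ignored when `allele_range` is given.
#' @param allele_range optional `c(min, max)`: allele counts drawn uniformly
#'   in the range, per locus.
#' @param dirichlet_alpha concentration of the symmetric Dirichlet ancestral
#'   allele-frequency law.
#' @param fst target Balding-Nichols Fst in `[0, 1)`; 0 means all
#'   populations share the ancestral frequencies exactly.
#' @param fis target inbreeding coefficient in `(-1, 1)`.
#' @param linked_groups list of integer vectors of locus indices; members of
#'   a group copy the group head's genotypes (perfect linkage) with
#'   relabelled alleles.
#' @param null_rate per-locus hidden null-allele frequency in `[0, 1)`.
#' @param missing_rate independent genotype dropout rate in `[0, 1)`.
#' @param pop_names optional population labels (default `pop1`, ...).
#' @param seed integer seed (mandatory).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_pops, pop_sizes, n_loci,
                       alleles_per_locus = 6, allele_range = NULL,
                       dirichlet_alpha = 1, fst = 0, fis = 0,
                       linked_groups = list(), null_rate = 0,
                       missing_rate = 0, pop_names = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (length(pop_sizes) != n_pops) stop("pop_sizes must have length n_pops")
  if (any(pop_sizes < 1)) stop("populations must be non-empty")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (fis <= -1 || fis > 1) stop("fis must lie in (-1, 1]")
  for (r in c(null_rate, missing_rate))
    if (r < 0 || r >= 1) stop("rates must lie in [0, 1)")
  if (!is.null(allele_range)) {
    if (length(allele_range) != 2 || allele_range[1] < 2 ||
        allele_range[2] < allele_range[1])
      stop("allele_range must be c(min >= 2, max >= min)")
  } else {
    if (!length(alleles_per_locus) %in% c(1L, n_loci))
      stop("alleles_per_locus must be scalar or length n_loci")
    if (any(alleles_per_locus < 1)) stop("allele counts must be >= 1")
  }
  for (g in linked_groups) {
    if (length(g) < 2 || any(g < 1 | g > n_loci) || anyDuplicated(g))
      stop("each linked group needs >= 2 distinct locus indices in range")
  }
  if (anyDuplicated(unlist(linked_groups)))
    stop("linked groups must be disjoint")
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(n_pops))
  structure(list(n_pops = n_pops, pop_sizes = as.integer(pop_sizes),
                 n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 allele_range = allele_range,
                 dirichlet_alpha = dirichlet_alpha,
                 fst = fst, fis = fis, linked_groups = linked_groups,
                 null_rate = null_rate, missing_rate = missing_rate,
                 pop_names = pop_names, seed = as.integer(seed)),
            class = "sim_config")
}

#' Canonical 4-population Taiwan-cypress-like configuration
#'
#' The stated world the rest of the package is exercised against: 4
#' populations named MM, HV, GW, SY of 20/25/23/24 diploid individuals, 36
#' loci with allele counts drawn as `min(2 + Poisson(5.9), 27)` (range 2-27,
#' mean near 7.9), a skewed ancestral allele law (symmetric Dirichlet with
#' concentration 0.25, giving expected heterozygosity near 0.55-0.6 at the
#' mean allele count, as typical of SSR panels), Fst 0.06, Fis 0.2, two
#' planted perfect-linkage groups of sizes 3 and 4, null-allele rate 0.02,
#' missing rate 0.01.
#'
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
cypress_sim_config <- function(seed = 1) {
  a <- with_seed(seed, pmin(2L + stats::rpois(36, 5.9), 27L))
  sim_config(n_pops = 4, pop_sizes = c(20, 25, 23, 24), n_loci = 36,
             alleles_per_locus = a, dirichlet_alpha = 0.25,
             fst = 0.06, fis = 0.2,
             linked_groups = list(c(5L, 12L, 20L), c(7L, 15L, 24L, 31L)),
             null_rate = 0.02, missing_rate = 0.01,
             pop_names = c("MM", "HV", "GW", "SY"), seed = seed)
}

#' Simulate a genotype dataset
#'
#' Balding-Nichols simulation: (1) ancestral allele frequencies per locus
#' from a symmetric Dirichlet; (2) population frequencies from
#' `Dirichlet(p_bar * (1 - Fst) / Fst)` (shared exactly when `Fst = 0`);
#' (3) genotypes drawn with inbreeding — homozygote `(i,i)` with
#' probability `p_i^2 + Fis * p_i (1 - p_i)`, heterozygote `(i,j)` with
#' `2 p_i p_j (1 - Fis)`; (4) linked-group members copy the head locus's
#' genotypes with per-locus relabelled alleles; (5) a hidden null allele of
#' frequency `null_rate` joins the sampling at each affected locus —
#' null/null becomes missing, null/visible is recorded as a visible
#' homozygote; (6) an independent missing mask at `missing_rate`.
#'
#' Allele labels are distinct even integers in 100-400 (SSR fragment-size
#' cosmetics). The result is byte-for-byte reproducible from the config.
#'
#' @param cfg a [sim_config].
#' @return list with `matrix` (a [genotype_matrix]) and `truth` (hidden
#'   parameters: the config, per-locus ancestral and per-population allele
#'   frequencies, allele labels, linked groups as locus ids).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  L <- cfg$n_loci; k <- cfg$n_pops
  n <- sum(cfg$pop_sizes)
  pop_of <- rep(cfg$pop_names, cfg$pop_sizes)
  ids <- sprintf("%s_%02d", pop_of,
                 unlist(lapply(cfg$pop_sizes, seq_len)))
  locus_ids <- sprintf("L%02d", seq_len(L))
  A <- if (!is.null(cfg$allele_range))
    sample(seq(cfg$allele_range[1], cfg$allele_range[2]), L, replace = TRUE)
  else rep_len(cfg$alleles_per_locus, L)
  group_head <- integer(L)          # 0 for independent loci
  for (g in cfg$linked_groups) {
    A[g] <- A[g[1]]                 # members share the head's allele count
    group_head[g[-1]] <- g[1]
  }
  labels <- lapply(A, function(a) sort(sample(seq(100L, 400L, 2L), a)))
  anc <- vector("list", L); pf <- vector("list", L)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  idx1 <- matrix(NA_integer_, n, L); idx2 <- matrix(NA_integer_, n, L)
  pop_index <- rep(seq_len(k), cfg$pop_sizes)
  for (j in seq_len(L)) {
    if (group_head[j] > 0) {        # perfect linkage: copy head's indices
      h <- group_head[j]
      anc[[j]] <- anc[[h]]; pf[[j]] <- pf[[h]]
      idx1[, j] <- idx1[, h]; idx2[, j] <- idx2[, h]
      next
    }
    p_bar <- rdirichlet(rep(cfg$dirichlet_alpha, A[j]))
    anc[[j]] <- p_bar
    pf[[j]] <- matrix(NA_real_, A[j], k)
    for (p in seq_len(k)) {
      pf[[j]][, p] <- if (cfg$fst == 0) p_bar
      else rdirichlet(p_bar * (1 - cfg$fst) / cfg$fst)
    }
    for (p in seq_len(k)) {
      ii <- which(pop_index == p)
      freq <- pf[[j]][, p]
      if (cfg$null_rate > 0)
        freq <- c(freq * (1 - cfg$null_rate), cfg$null_rate)
      g <- sample_genotypes(length(ii), freq, cfg$fis, locus_ids[j])
      idx1[ii, j] <- g[, 1]; idx2[ii, j] <- g[, 2]
    }
  }
  null_idx <- if (cfg$null_rate > 0) A + 1L else rep(0L, L)
  for (j in seq_len(L)) {
    i1 <- idx1[, j]; i2 <- idx2[, j]
    if (cfg$null_rate > 0) {
      both_null <- i1 == null_idx[j] & i2 == null_idx[j]
      one_null <- xor(i1 == null_idx[j], i2 == null_idx[j])
      vis <- pmin(ifelse(i1 == null_idx[j], i2, i1),
                  ifelse(i2 == null_idx[j], i1, i2))
      i1[one_null] <- vis[one_null]; i2[one_null] <- vis[one_null]
      i1[both_null] <- NA_integer_; i2[both_null] <- NA_integer_
    }
    a1[, j] <- labels[[j]][i1]; a2[, j] <- labels[[j]][i2]
  }
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  gm <- genotype_matrix(a1, a2, ids, locus_ids, pop_of)
  truth <- list(config = cfg,
                ancestral_freqs = stats::setNames(anc, locus_ids),
                pop_freqs = stats::setNames(pf, locus_ids),
                allele_labels = stats::setNames(labels, locus_ids),
                linked_groups = lapply(cfg$linked_groups,
                                       function(g) locus_ids[g]))
  list(matrix = gm, truth = truth)
}

# one symmetric/asymmetric Dirichlet draw via gammas
rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1   # guard vanishing draws
  g / sum(g)
}

# n diploid genotypes (allele-index pairs) with inbreeding coefficient fis
sample_genotypes <- function(n, p, fis, locus_id) {
  A <- length(p)
  hom <- p^2 + fis * p * (1 - p)
  if (any(hom < -1e-12))
    stop("negative homozygote probability at locus ", locus_id,
         ": fis = ", fis, " too negative for its rarest allele")
  if (fis >= 0) {
    # draw first allele, then copy it with probability fis (IBD event)
    i1 <- sample.int(A, n, replace = TRUE, prob = p)
    ibd <- stats::runif(n) < fis
    i2 <- ifelse(ibd, i1, sample.int(A, n, replace = TRUE, prob = p))
  } else {
    # explicit genotype distribution over A(A+1)/2 unordered classes
    pairs <- which(upper.tri(diag(A), diag = TRUE), arr.ind = TRUE)
    w <- ifelse(pairs[, 1] == pairs[, 2], hom[pairs[, 1]],
                2 * p[pairs[, 1]] * p[pairs[, 2]] * (1 - fis))
    g <- sample.int(nrow(pairs), n, replace = TRUE, prob = w)
    i1 <- pairs[g, 1]; i2 <- pairs[g, 2]
  }
  cbind(pmin(i1, i2), pmax(i1, i2))
}
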