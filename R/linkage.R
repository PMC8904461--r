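#' Genotypic linkage-disequilibrium test for a locus pair
#'
#' Log-likelihood-ratio (G) test on the two-locus genotypic contingency
#' table built from individuals typed at both loci, with the null
#' distribution obtained by permuting one locus's genotype column across
#' individuals (the genotypic LD test of the Genepop lineage):
#' `p = (1 + #(G_perm >= G_obs)) / (1 + reps)`.
#'
#' @param x a [genotype_matrix].
#' @param locusA,locusB locus ids or indices.
#' @param reps permutation replicates (>= 1000 recommended).
#' @param seed integer seed.
#' @return list with `p_value`, `G`, `n` (shared typed individuals).
#' @export
ld_test_pair <- function(x, locusA, locusB, reps = 10000, seed = 1) {
  ja <- locus_index(x, locusA); jb <- locus_index(x, locusB)
  ok <- !is.na(x$a1[, ja]) & !is.na(x$a1[, jb])
  n <- sum(ok)
  if (n < 2)
    stop("fewer than 2 individuals typed at both ", x$locus_ids[ja],
         " and ", x$locus_ids[jb])
  ga <- genotype_codes(x$a1[ok, ja], x$a2[ok, ja])
  gb <- genotype_codes(x$a1[ok, jb], x$a2[ok, jb])
  ka <- max(ga); kb <- max(gb)
  # the row/column margins - hence the expected counts - are invariant
  # under permutation of one column, so precompute everything but the
  # joint table: G = 2 * (sum_c O_c log O_c - sum_i log E_cell(i))
  loge <- log(as.vector(outer(tabulate(ga, ka), tabulate(gb, kb))) / n)
  xlx <- c(0, seq_len(n) * log(seq_len(n)))   # x log x lookup, x = 0..n
  g_of <- function(gbp) {
    cell <- ga + ka * (gbp - 1L)
    o <- tabulate(cell, ka * kb)
    2 * (sum(xlx[o + 1L]) - sum(loge[cell]))
  }
  g_obs <- g_of(gb)
  exceed <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      if (g_of(gb[sample.int(n)]) >= g_obs - 1e-9) exceed <- exceed + 1L
    }
  })
  list(p_value = (1 + exceed) / (1 + reps), G = g_obs, n = n)
}

# integer genotype codes 1..k for unordered diploid calls
genotype_codes <- function(a1, a2) {
  as.integer(factor(paste(a1, a2)))
}

#' All-pairs linkage-disequilibrium scan
#'
#' Runs [ld_test_pair] for every testable locus pair. Pairs with fewer than
#' 2 shared typed individuals are reported with `NA` p-values (treated as
#' non-significant downstream) rather than failing the scan.
#'
#' @param x a [genotype_matrix].
#' @param reps permutation replicates per pair.
#' @param seed integer seed; each pair gets a sub-seed derived from it.
#' @return data.frame with columns `locusA`, `locusB`, `p_value`, `G`, `n`.
#' @export
ld_test_all <- function(x, reps = 10000, seed = 1) {
  L <- n_loci(x)
  pairs <- utils::combn(L, 2)
  m <- ncol(pairs)
  res <- data.frame(locusA = x$locus_ids[pairs[1, ]],
                    locusB = x$locus_ids[pairs[2, ]],
                    p_value = NA_real_, G = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(m)) {
    t <- tryCatch(
      ld_test_pair(x, pairs[1, k], pairs[2, k], reps = reps,
                   seed = (seed + k) %% .Machine$integer.max),
      error = function(e) NULL)
    if (!is.null(t)) {
      res$p_value[k] <- t$p_value; res$G[k] <- t$G; res$n[k] <- t$n
    }
  }
  res
}

#' Build linkage groups from pairwise p-values
#'
#' Loci joined by a significant pair (`p < alpha`) are merged into groups.
#' The default treats groups as connected components of the significance
#' graph (the transitive reading of "same linkage group"); `method =
#' "clique"` instead peels maximal fully-connected cliques greedily, for the
#' stricter reading in which every within-group pair must itself be
#' significant. Untestable pairs (`NA` p) contribute no edge.
#'
#' @param pairs data.frame from [ld_test_all] (columns `locusA`, `locusB`,
#'   `p_value`).
#' @param loci character vector of all locus ids (singletons included).
#' @param alpha significance threshold, default 0.001.
#' @param method `"component"` (default) or `"clique"`.
#' @return a `linkage_structure`: list with `alpha`, `significant_pairs`
#'   (two-column character matrix), `groups` (list of character vectors,
#'   partitioning `loci`), `representatives` (filled by
#'   [select_representatives]), `method`.
#' @export
linkage_groups <- function(pairs, loci, alpha = 0.001,
                           method = c("component", "clique")) {
  method <- match.arg(method)
  sig <- pairs[!is.na(pairs$p_value) & pairs$p_value < alpha, , drop = FALSE]
  edges <- cbind(as.character(sig$locusA), as.character(sig$locusB))
  L <- length(loci)
  parent <- seq_len(L)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  adj <- matrix(FALSE, L, L, dimnames = list(loci, loci))
  if (nrow(edges) > 0) for (k in seq_len(nrow(edges))) {
    ia <- match(edges[k, 1], loci); ib <- match(edges[k, 2], loci)
    if (is.na(ia) || is.na(ib))
      stop("significant pair names a locus not in `loci`")
    adj[ia, ib] <- adj[ib, ia] <- TRUE
    ra <- find(ia); rb <- find(ib)
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_len(L), find, integer(1))
  groups <- split(loci, comp)
  if (method == "clique") {
    # within each component, peel greedy maximal cliques (largest first,
    # ties by lexicographically smallest member set)
    groups <- unlist(lapply(groups, function(g) {
      peel_cliques(g, adj[g, g, drop = FALSE])
    }), recursive = FALSE)
  }
  # deterministic order: by first member's position in `loci`
  groups <- unname(groups[order(vapply(groups,
                                       function(g) min(match(g, loci)),
                                       numeric(1)))])
  groups <- lapply(groups, function(g) g[order(match(g, loci))])
  structure(list(alpha = alpha, significant_pairs = edges, groups = groups,
                 representatives = NULL, method = method),
            class = "linkage_structure")
}

# greedy clique cover of one component
peel_cliques <- function(members, adj) {
  out <- list()
  remaining <- members
  while (length(remaining) > 0) {
    sub <- adj[remaining, remaining, drop = FALSE]
    cl <- largest_clique(remaining, sub)
    out[[length(out) + 1L]] <- cl
    remaining <- setdiff(remaining, cl)
  }
  out
}

# exact branch-and-bound; component sizes here are tiny (<= dozens)
largest_clique <- function(v, adj) {
  best <- v[1]
  vs <- sort(v)
  rec <- function(clique, cand) {
    if (length(clique) > length(best)) best <<- clique
    while (length(cand) > 0) {
      u <- cand[1]; cand <- cand[-1]
      if (length(clique) + 1 + length(cand) <= length(best)) break
      if (all(adj[u, clique])) rec(c(clique, u), cand[adj[cand, u]])
    }
  }
  rec(character(0), vs)
  sort(best)
}

#' Choose the representative locus of each linkage group
#'
#' For every group the member with the smallest probability of identity is
#' selected (singletons represent themselves); PI ties break to the
#' lexicographically smallest locus id. The representative set is the
#' usable-locus set for the forensic accumulation.
#'
#' @param structure a `linkage_structure` from [linkage_groups].
#' @param pi_values named numeric vector of per-locus PI.
#' @return the structure with `representatives` filled (character vector,
#'   one per group) and `usable_loci` (all representatives).
#' @export
select_representatives <- function(structure, pi_values) {
  reps <- vapply(structure$groups, function(g) {
    pis <- pi_values[g]
    if (anyNA(pis))
      stop("PI missing for grouped locus: ",
           paste(g[is.na(pis)], collapse = ", "))
    g[order(pis, g)][1]
  }, character(1))
  structure$representatives <- reps
  structure$usable_loci <- reps
  structure
}

#' @export
print.linkage_structure <- function(x, ...) {
  multi <- Filter(function(g) length(g) > 1, x$groups)
  cat("linkage_structure: alpha =", x$alpha, "(", x$method, ")\n")
  cat("  ", length(x$groups), "groups (", length(multi), "multi-locus )\n")
  for (g in multi) cat("   {", paste(g, collapse = ", "), "}\n")
  if (!is.null(x$representatives))
    cat("  usable loci:", length(x$representatives), "\n")
  invisible(x)
}
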