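#' Diploid SSR genotype matrix
#'
#' The universal input container of the package: unordered pairs of
#' positive-integer allele labels (typically PCR fragment sizes in bp) for
#' `n` individuals at `L` loci, with one population label per individual.
#' Missing genotypes are stored as `NA` in both allele slots.
#'
#' Internally the calls are two integer matrices `a1`, `a2` (individuals x
#' loci) normalised so that `a1 <= a2` elementwise; storing `(a, b)` or
#' `(b, a)` therefore yields identical objects.
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele labels;
#'   `NA` in both marks a missing genotype. Any orientation is accepted.
#' @param individual_ids character vector of unique individual identifiers.
#' @param locus_ids character vector of unique locus identifiers.
#' @param populations character vector, one population label per individual.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, individual_ids, locus_ids, populations) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(individual_ids); L <- length(locus_ids)
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices have different dimensions")
  if (nrow(a1) != n || ncol(a1) != L)
    stop("allele matrices must be individuals x loci (",
         n, " x ", L, "), got ", nrow(a1), " x ", ncol(a1))
  if (anyDuplicated(individual_ids))
    stop("duplicate individual id: ",
         individual_ids[anyDuplicated(individual_ids)])
  if (anyDuplicated(locus_ids))
    stop("duplicate locus id: ", locus_ids[anyDuplicated(locus_ids)])
  if (length(populations) != n)
    stop("need exactly one population label per individual")
  if (xor(any(is.na(a1)), any(is.na(a2))) ||
      !identical(which(is.na(a1)), which(is.na(a2))))
    stop("half-missing genotype: NA must occupy both allele slots")
  ok <- !is.na(a1)
  if (any(a1[ok] <= 0L) || any(a2[ok] <= 0L))
    stop("allele labels must be positive integers")
  # unordered-pair normalisation
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- list(individual_ids, locus_ids)
  structure(
    list(a1 = lo, a2 = hi,
         individual_ids = as.character(individual_ids),
         locus_ids = as.character(locus_ids),
         populations = as.character(populations)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individual_ids), "individuals x",
      length(x$locus_ids), "loci,",
      length(unique(x$populations)), "population(s)\n")
  miss <- sum(is.na(x$a1))
  cat(sprintf("  missing genotypes: %d (%.1f%%)\n", miss,
              100 * miss / length(x$a1)))
  cat("  populations:", paste(sprintf("%s (%d)", unique(x$populations),
      tabulate(factor(x$populations, levels = unique(x$populations)))),
      collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals / loci
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(x) length(x$individual_ids)

#' @rdname n_individuals
#' @export
n_loci <- function(x) length(x$locus_ids)

#' Population labels in order of first appearance
#' @param x a `genotype_matrix`.
#' @return character vector of distinct population labels.
#' @export
population_levels <- function(x) unique(x$populations)

# Resolve a subset argument to an integer index of individuals.
# NULL -> everyone; character matching population labels -> those pops;
# otherwise character individual ids; integer/logical passed through.
resolve_subset <- function(x, subset) {
  if (is.null(subset)) return(seq_along(x$individual_ids))
  if (is.logical(subset)) return(which(subset))
  if (is.numeric(subset)) return(as.integer(subset))
  subset <- as.character(subset)
  pops <- unique(x$populations)
  if (all(subset %in% pops)) return(which(x$populations %in% subset))
  if (all(subset %in% x$individual_ids))
    return(match(subset, x$individual_ids))
  bad <- setdiff(subset, c(pops, x$individual_ids))
  stop("unknown population label or individual id: ",
       paste(bad, collapse = ", "))
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param individuals population label(s), individual ids, or an index.
#' @param loci locus ids or index; `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, individuals = NULL, loci = NULL) {
  ii <- resolve_subset(x, individuals)
  jj <- if (is.null(loci)) seq_along(x$locus_ids)
        else if (is.character(loci)) {
          m <- match(loci, x$locus_ids)
          if (anyNA(m)) stop("unknown locus id: ",
                             paste(loci[is.na(m)], collapse = ", "))
          m
        } else as.integer(loci)
  if (length(ii) == 0) stop("empty individual subset")
  genotype_matrix(x$a1[ii, jj, drop = FALSE], x$a2[ii, jj, drop = FALSE],
                  x$individual_ids[ii], x$locus_ids[jj], x$populations[ii])
}

#' Test two genotype matrices for equality
#'
#' Compares individual ids, locus ids, all calls (as unordered pairs) and the
#' missing mask. With `labels = TRUE` (default) population labels must match
#' exactly; with `labels = FALSE` only the population partition must agree
#' (needed for formats such as Genepop or STRUCTURE that cannot store label
#' strings).
#'
#' @param x,y `genotype_matrix` objects.
#' @param labels compare population label strings, or just the partition?
#' @return `TRUE` or `FALSE`.
#' @export
genotypes_equal <- function(x, y, labels = TRUE) {
  if (!identical(x$individual_ids, y$individual_ids)) return(FALSE)
  if (!identical(x$locus_ids, y$locus_ids)) return(FALSE)
  if (!identical(x$a1, y$a1) || !identical(x$a2, y$a2)) return(FALSE)
  if (labels) return(identical(x$populations, y$populations))
  px <- as.integer(factor(x$populations, levels = unique(x$populations)))
  py <- as.integer(factor(y$populations, levels = unique(y$populations)))
  identical(px, py)
}

#' Per-locus allele frequencies
#'
#' Counts the two alleles of every non-missing individual at each locus
#' (complete-case per locus) and normalises to relative frequencies.
#' Loci with zero typed individuals are kept and flagged, never dropped.
#'
#' @param x a `genotype_matrix`.
#' @param subset optional population label(s) or individual ids.
#' @return an `allele_freq_table`: list with `freqs` (per locus a named
#'   numeric vector of frequencies, allele labels sorted numerically),
#'   `n_typed` (named integer, diploid individuals used per locus) and
#'   `zero_typed` (locus ids with no data).
#' @export
allele_frequencies <- function(x, subset = NULL) {
  ii <- resolve_subset(x, subset)
  if (length(ii) == 0) stop("empty subset")
  a1 <- x$a1[ii, , drop = FALSE]; a2 <- x$a2[ii, , drop = FALSE]
  freqs <- vector("list", length(x$locus_ids))
  names(freqs) <- x$locus_ids
  n_typed <- integer(length(x$locus_ids))
  names(n_typed) <- x$locus_ids
  for (j in seq_along(x$locus_ids)) {
    ok <- !is.na(a1[, j])
    n_typed[j] <- sum(ok)
    if (n_typed[j] == 0) { freqs[[j]] <- numeric(0); next }
    tab <- table(c(a1[ok, j], a2[ok, j]))
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)
    freqs[[j]] <- p[order(as.integer(names(p)))]
  }
  structure(list(freqs = freqs, n_typed = n_typed,
                 zero_typed = x$locus_ids[n_typed == 0]),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("allele_freq_table:", length(x$freqs), "loci\n")
  if (length(x$zero_typed))
    cat("  loci with zero typed individuals:",
        paste(x$zero_typed, collapse = ", "), "\n")
  invisible(x)
}
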