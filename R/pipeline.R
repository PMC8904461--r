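#' Run the full identification-and-population-genetics analysis
#'
#' Orchestrates the pipeline on one genotype matrix: per-locus summary
#' statistics, pairwise linkage-disequilibrium scan and linkage groups,
#' representative selection, cumulative forensic profile, per-population
#' summaries, pairwise Fst/Nm, and leave-one-out provenance assignment.
#'
#' @param x a [genotype_matrix] (use [read_genalex] and friends, or
#'   [simulate_dataset]).
#' @param alpha significance threshold for HWE flagging and LD grouping.
#' @param ld_reps permutation replicates per locus pair.
#' @param seed integer seed driving all permutation tests.
#' @param cl_levels confidence levels for the forensic profile.
#' @param zero_freq assignment substitute frequency for unseen alleles.
#' @param fst_method `"nei"` or `"wc"`, see [pairwise_fst].
#' @param verbose print stage-by-stage progress?
#' @return an `ssrid_report` list with elements `locus_summary`, `linkage`,
#'   `forensic`, `population_summary`, `differentiation`, `assignment`,
#'   `settings`.
#' @export
run_full_analysis <- function(x, alpha = 0.001, ld_reps = 10000, seed = 1,
                              cl_levels = c(0.95, 0.99, 0.9999),
                              zero_freq = 0.01, fst_method = "nei",
                              verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("locus statistics: ", n_loci(x), " loci, ", n_individuals(x),
      " individuals")
  ls <- summarize_loci(x)
  say("linkage scan: ", choose(n_loci(x), 2), " pairs, reps = ", ld_reps)
  ld <- ld_test_all(x, reps = ld_reps, seed = seed)
  lg <- linkage_groups(ld, x$locus_ids, alpha = alpha)
  pi_all <- stats::setNames(ls$PI, ls$locus)
  lg <- select_representatives(lg, pi_all)
  say("forensic accumulation over ", length(lg$usable_loci), " usable loci")
  fp <- cumulative_profile(pi_all[lg$usable_loci], cl_levels = cl_levels)
  say("population structure: ", length(population_levels(x)), " populations")
  ps <- population_summaries(x)
  fm <- if (length(population_levels(x)) >= 2)
    fst_matrix(x, method = fst_method) else NULL
  say("provenance assignment (leave-one-out)")
  as <- if (length(population_levels(x)) >= 1)
    assign_all(x, zero_freq = zero_freq, leave_one_out = TRUE) else NULL
  structure(list(locus_summary = ls, linkage = lg, forensic = fp,
                 population_summary = ps, differentiation = fm,
                 assignment = as,
                 settings = list(alpha = alpha, ld_reps = ld_reps,
                                 seed = seed, cl_levels = cl_levels,
                                 zero_freq = zero_freq,
                                 fst_method = fst_method,
                                 version = as.character(
                                   utils::packageVersion("ssrid")))),
            class = "ssrid_report")
}

#' Write an analysis report as JSON
#'
#' Self-contained machine-readable report: re-running
#' [run_full_analysis] with the recorded settings reproduces every number.
#'
#' @param report an `ssrid_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    settings = report$settings,
    locus_summary = as.data.frame(report$locus_summary),
    locus_means = as.list(attr(report$locus_summary, "means")),
    linkage = list(alpha = report$linkage$alpha,
                   groups = report$linkage$groups,
                   representatives = report$linkage$representatives),
    forensic = as.data.frame(report$forensic),
    population_summary = report$population_summary,
    fst = if (!is.null(report$differentiation))
      report$differentiation$fst,
    nm = if (!is.null(report$differentiation)) report$differentiation$nm,
    assignment = if (!is.null(report$assignment))
      list(populations = report$assignment$populations,
           overall_pct = report$assignment$overall_pct))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.ssrid_report <- function(x, ...) {
  cat("==== ssrid analysis report ====\n")
  m <- attr(x$locus_summary, "means")
  cat(sprintf("loci: %d | mean A = %.3f, Ho = %.3f, He = %.3f, PIC = %.3f\n",
              nrow(x$locus_summary), m["A"], m["Ho"], m["He"], m["PIC"]))
  print(x$linkage)
  print(x$forensic)
  if (!is.null(x$differentiation)) print(x$differentiation)
  if (!is.null(x$assignment)) print(x$assignment)
  invisible(x)
}
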