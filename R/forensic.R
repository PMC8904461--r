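#' Cumulative forensic discrimination profile
#'
#' Sorts the usable loci by probability of identity (PI) ascending (ties by
#' locus id) and accumulates them: after `k` loci the combined probability
#' of identity is `CPI_k = prod(PI_1..PI_k)` (computed in log space) and the
#' combined power of discrimination is `CPD_k = 1 - CPI_k`. For each
#' requested confidence level `CL*` the largest population size that can be
#' identified with `(1 - CPI)^N >= CL*` is reported.
#'
#' @param pi_values named numeric vector of per-locus PI, all in `(0, 1]`
#'   (typically the linkage representatives plus singleton loci).
#' @param cl_levels confidence levels for the identifiable-N columns.
#' @return a data.frame of class `forensic_profile`: columns `k`, `locus`,
#'   `PI`, `CPI`, `CPD`, then one `N_max@<cl>` column per confidence level.
#' @export
cumulative_profile <- function(pi_values,
                               cl_levels = c(0.95, 0.99, 0.9999)) {
  if (length(pi_values) < 1) stop("need at least one usable locus")
  if (is.null(names(pi_values)) || any(!nzchar(names(pi_values))))
    stop("pi_values must be named by locus id")
  if (any(pi_values <= 0 | pi_values > 1))
    stop("every PI must lie in (0, 1]; offending locus: ",
         paste(names(pi_values)[pi_values <= 0 | pi_values > 1],
               collapse = ", "))
  ord <- order(pi_values, names(pi_values))
  pi_sorted <- pi_values[ord]
  logcpi <- cumsum(log(pi_sorted))
  out <- data.frame(k = seq_along(pi_sorted),
                    locus = names(pi_sorted),
                    PI = unname(pi_sorted),
                    CPI = exp(logcpi),
                    CPD = 1 - exp(logcpi),
                    stringsAsFactors = FALSE)
  for (cl in cl_levels)
    out[[sprintf("N_max@%g", cl)]] <-
      vapply(out$CPI, max_identifiable, numeric(1), cl_star = cl)
  class(out) <- c("forensic_profile", "data.frame")
  out
}

#' Confidence level of an identification system
#'
#' `CL = (1 - CPI)^N`: the probability that none of `N` random individuals
#' matches a given profile. Evaluated as `exp(N * log1p(-CPI))` so that
#' CPI values around 1e-12 do not lose precision.
#'
#' @param cpi combined probability of identity in `[0, 1]`.
#' @param n population size (non-negative).
#' @return CL in `[0, 1]`.
#' @export
confidence_level <- function(cpi, n) {
  if (any(cpi < 0 | cpi > 1)) stop("CPI must lie in [0, 1]")
  if (any(n < 0)) stop("N must be non-negative")
  ifelse(cpi == 1, as.numeric(n == 0), exp(n * log1p(-cpi)))
}

#' Maximum identifiable population size
#'
#' The largest integer `N` with `(1 - CPI)^N >= CL*`, i.e.
#' `floor(log(CL*) / log1p(-CPI))`. `floor = FALSE` returns the unfloored
#' real bound. `CPI = 0` yields infinite capacity (`Inf`).
#'
#' @param cpi combined probability of identity in `[0, 1)`.
#' @param cl_star required confidence level in `(0, 1)`.
#' @param floor round down to a whole number of individuals (default)?
#' @return N, possibly `Inf`.
#' @export
max_identifiable <- function(cpi, cl_star, floor = TRUE) {
  if (cpi < 0 || cpi >= 1) stop("CPI must lie in [0, 1)")
  if (cl_star <= 0 || cl_star >= 1) stop("CL* must lie in (0, 1)")
  if (cpi == 0) return(Inf)
  n_real <- log(cl_star) / log1p(-cpi)
  if (!floor) return(n_real)
  n <- base::floor(n_real)
  # the log ratio can land a hair under an integer when (1 - CPI)^k hits
  # CL* exactly; nudge against the defining inequality. The floor is off by
  # at most one step, and beyond 2^53 a unit step is not even representable.
  if (n < 2^53) {
    if (confidence_level(cpi, n + 1) >= cl_star) n <- n + 1
    else if (n > 0 && confidence_level(cpi, n) < cl_star) n <- n - 1
  }
  n
}

#' @export
print.forensic_profile <- function(x, ...) {
  cat("forensic_profile:", nrow(x), "loci accumulated\n")
  last <- x[nrow(x), ]
  cat(sprintf("  final CPI = %.4g, CPD = %.15g\n", last$CPI, last$CPD))
  for (nm in grep("^N_max@", names(x), value = TRUE))
    cat(sprintf("  %s = %s\n", nm, format(last[[nm]], big.mark = ",")))
  invisible(x)
}
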