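#' Read a GenAlEx codominant genotype file
#'
#' Parses the GenAlEx codominant CSV layout: row 1 holds
#' `n_loci, n_individuals, n_pops, size_1, ..., size_k`; row 2 a title cell
#' followed (from column 4) by the population names; row 3 the column header
#' (`id`, `pop`, then two columns per locus, the locus name over the first);
#' then one row per individual. The GenAlEx missing code `0` maps to missing.
#'
#' @param path path to a UTF-8 text file (either line-ending convention).
#' @return a [genotype_matrix].
#' @export
read_genalex <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) < 4) stop("GenAlEx file too short: ", path)
  row1 <- csv_fields(lines[1])
  hdr <- suppressWarnings(as.integer(row1))
  if (length(hdr) < 3 || anyNA(hdr[1:3]))
    stop("malformed GenAlEx header (line 1): expected n_loci, n_individuals, ",
         "n_pops counts, got '", lines[1], "'")
  nl <- hdr[1]; ni <- hdr[2]; np <- hdr[3]
  sizes <- hdr[seq(4, length.out = np)]
  if (anyNA(sizes) || sum(sizes) != ni)
    stop("malformed GenAlEx header (line 1): population sizes ",
         paste(sizes, collapse = "+"), " do not sum to n_individuals ", ni)
  row2 <- csv_fields(lines[2])
  pop_names <- row2[seq(4, length.out = np)]
  pop_names[is.na(pop_names) | pop_names == ""] <-
    paste0("pop", which(is.na(pop_names) | pop_names == ""))
  row3 <- csv_fields(lines[3])
  locus_ids <- row3[seq(3, by = 2, length.out = nl)]
  if (anyNA(locus_ids) || any(locus_ids == ""))
    stop("malformed GenAlEx locus header (line 3)")
  body <- lines[-(1:3)]
  body <- body[!grepl("^,*$", body)]          # drop trailing blank rows
  if (length(body) != ni)
    stop("GenAlEx body has ", length(body), " data rows but header ",
         "declares ", ni, " individuals (first body line 4)")
  ids <- character(ni); pops <- character(ni)
  a1 <- matrix(NA_integer_, ni, nl); a2 <- matrix(NA_integer_, ni, nl)
  for (i in seq_len(ni)) {
    f <- csv_fields(body[i])
    if (length(f) < 2 + 2 * nl)
      stop("GenAlEx data row ", i + 3, " has ", length(f),
           " fields, expected ", 2 + 2 * nl)
    ids[i] <- f[1]; pops[i] <- f[2]
    al <- suppressWarnings(as.integer(f[3:(2 + 2 * nl)]))
    if (anyNA(al))
      stop("non-integer allele call on GenAlEx data row ", i + 3)
    x1 <- al[seq(1, by = 2, length.out = nl)]
    x2 <- al[seq(2, by = 2, length.out = nl)]
    miss <- x1 == 0L | x2 == 0L          # 0 is the GenAlEx missing code
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  genotype_matrix(a1, a2, ids, locus_ids, pops)
}

#' Write a GenAlEx codominant genotype file
#'
#' @param x a [genotype_matrix].
#' @param path output file path.
#' @param title title cell for row 2.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(x, path, title = "ssrid export") {
  pops <- population_levels(x)
  sizes <- tabulate(factor(x$populations, levels = pops))
  nl <- n_loci(x); ni <- n_individuals(x)
  l1 <- paste(c(nl, ni, length(pops), sizes), collapse = ",")
  l2 <- paste(c(title, "", "", pops), collapse = ",")
  l3 <- paste(c("Ind", "Pop",
                as.vector(rbind(x$locus_ids, ""))), collapse = ",")
  a1 <- x$a1; a2 <- x$a2
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  # keep individuals grouped by population, in population order
  ord <- order(match(x$populations, pops))
  rows <- vapply(ord, function(i) {
    paste(c(x$individual_ids[i], x$populations[i],
            as.vector(rbind(a1[i, ], a2[i, ]))), collapse = ",")
  }, character(1))
  writeLines(c(l1, l2, l3, rows), path)
  invisible(path)
}

#' Read a Genepop genotype file
#'
#' Supports the 2- and 3-digit diallelic coding (4 or 6 characters per call);
#' `00`/`000` codes map to missing. Locus names may be one per line or a
#' single comma-separated line. Populations are delimited by `Pop` lines and
#' named after their first individual's label (Genepop files carry no
#' population names of their own).
#'
#' @param path path to a Genepop text file.
#' @return a [genotype_matrix].
#' @export
read_genepop <- function(path) {
  lines <- trimws(read_text_lines(path))
  lines <- lines[lines != ""]
  if (length(lines) < 3) stop("Genepop file too short: ", path)
  is_pop <- toupper(lines) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' line in Genepop file: ", path)
  locus_block <- lines[2:(first_pop - 1)]
  locus_ids <- trimws(unlist(strsplit(locus_block, ",")))
  locus_ids <- locus_ids[locus_ids != ""]
  nl <- length(locus_ids)
  ids <- character(0); pops <- character(0)
  rows1 <- list(); rows2 <- list()
  pop_label <- NA_character_; pop_ord <- 0L
  width <- rep(NA_integer_, nl)   # per-locus digit width, must be consistent
  for (ln in lines[first_pop:length(lines)]) {
    if (toupper(ln) == "POP") { pop_label <- NA_character_; pop_ord <- pop_ord + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop("malformed Genepop individual line (no comma): '", ln, "'")
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                      "[[:space:]]+")[[1]]
    if (length(codes) != nl)
      stop("Genepop line for '", id, "' has ", length(codes),
           " calls, expected ", nl)
    if (is.na(pop_label))
      pop_label <- if (nzchar(id)) id else paste0("pop", pop_ord)
    x1 <- integer(nl); x2 <- integer(nl)
    for (j in seq_len(nl)) {
      nc <- nchar(codes[j])
      if (!nc %in% c(4L, 6L))
        stop("Genepop call '", codes[j], "' at locus ", locus_ids[j],
             " is not 4 or 6 characters")
      w <- nc %/% 2L
      if (is.na(width[j])) width[j] <- w
      else if (width[j] != w)
        stop("mixed 2- and 3-digit coding within locus ", locus_ids[j])
      b1 <- as.integer(substr(codes[j], 1, w))
      b2 <- as.integer(substr(codes[j], w + 1, nc))
      if (is.na(b1) || is.na(b2))
        stop("non-numeric Genepop call '", codes[j], "'")
      if (b1 == 0L || b2 == 0L) { b1 <- NA_integer_; b2 <- NA_integer_ }
      x1[j] <- b1; x2[j] <- b2
    }
    ids <- c(ids, id); pops <- c(pops, pop_label)
    rows1[[length(rows1) + 1L]] <- x1; rows2[[length(rows2) + 1L]] <- x2
  }
  genotype_matrix(do.call(rbind, rows1), do.call(rbind, rows2),
                  ids, locus_ids, pops)
}

#' Write a Genepop genotype file
#'
#' Uses 3-digit coding (allele labels must be < 1000); missing is `000000`.
#'
#' @param x a [genotype_matrix].
#' @param path output file path.
#' @param title first line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "ssrid export") {
  if (any(x$a2 > 999L, na.rm = TRUE))
    stop("Genepop 3-digit coding cannot represent allele labels > 999")
  pops <- population_levels(x)
  out <- c(title, x$locus_ids)
  a1 <- x$a1; a2 <- x$a2
  for (p in pops) {
    out <- c(out, "Pop")
    for (i in which(x$populations == p)) {
      c1 <- ifelse(is.na(a1[i, ]), 0L, a1[i, ])
      c2 <- ifelse(is.na(a2[i, ]), 0L, a2[i, ])
      out <- c(out, paste0(x$individual_ids[i], ", ",
                           paste(sprintf("%03d%03d", c1, c2), collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a STRUCTURE genotype file
#'
#' Two-row-per-individual layout: an optional first header line of locus
#' names, then per individual two whitespace-separated rows of
#' `id pop allele_1 ... allele_L` (one allele per locus per row). The
#' STRUCTURE missing code is `-9`. Population labels are the integer tokens
#' of the pop column, as characters.
#'
#' @param path path to a STRUCTURE text file.
#' @return a [genotype_matrix].
#' @export
read_structure <- function(path) {
  lines <- trimws(read_text_lines(path))
  lines <- lines[lines != ""]
  tok <- strsplit(lines, "[[:space:]]+")
  # header line = all tokens non-numeric
  has_header <- length(tok) > 0 &&
    all(is.na(suppressWarnings(as.numeric(tok[[1]]))))
  locus_ids <- if (has_header) tok[[1]] else NULL
  body <- if (has_header) tok[-1] else tok
  if (length(body) %% 2L != 0L)
    stop("STRUCTURE body has an odd number of rows (", length(body),
         "); each individual needs exactly two rows")
  nl <- length(body[[1]]) - 2L
  if (nl < 1) stop("STRUCTURE rows need at least 3 columns (id, pop, alleles)")
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(nl))
  if (length(locus_ids) != nl)
    stop("STRUCTURE header names ", length(locus_ids), " loci but rows carry ",
         nl)
  ni <- length(body) %/% 2L
  ids <- character(ni); pops <- character(ni)
  a1 <- matrix(NA_integer_, ni, nl); a2 <- matrix(NA_integer_, ni, nl)
  for (i in seq_len(ni)) {
    r1 <- body[[2 * i - 1L]]; r2 <- body[[2 * i]]
    if (length(r1) != nl + 2L || length(r2) != nl + 2L)
      stop("STRUCTURE rows for individual ", i, " have wrong field counts")
    if (r1[1] != r2[1])
      stop("STRUCTURE row pair mismatch: '", r1[1], "' vs '", r2[1], "'")
    ids[i] <- r1[1]; pops[i] <- r1[2]
    x1 <- as.integer(r1[-(1:2)]); x2 <- as.integer(r2[-(1:2)])
    miss <- x1 == -9L | x2 == -9L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  genotype_matrix(a1, a2, ids, locus_ids, pops)
}

#' Write a STRUCTURE genotype file
#'
#' @param x a [genotype_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  pops <- population_levels(x)
  pop_idx <- match(x$populations, pops)
  a1 <- x$a1; a2 <- x$a2
  a1[is.na(a1)] <- -9L; a2[is.na(a2)] <- -9L
  out <- paste(x$locus_ids, collapse = " ")
  for (i in seq_len(n_individuals(x))) {
    out <- c(out,
             paste(c(x$individual_ids[i], pop_idx[i], a1[i, ]), collapse = " "),
             paste(c(x$individual_ids[i], pop_idx[i], a2[i, ]), collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

# -- helpers ------------------------------------------------------------

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

csv_fields <- function(line) {
  trimws(strsplit(sub("\r$", "", line), ",", fixed = TRUE)[[1]])
}
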