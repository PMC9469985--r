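# STRUCTURE matrix format, both layouts: two rows per individual (one allele
# copy per row) or one row per individual with paired columns.

#' Read a STRUCTURE-format genotype file
#'
#' Whitespace-delimited; first column is the individual ID, an optional
#' second column a population label (`has_pop_column`), remaining columns
#' allele codes.  In the two-rows-per-individual layout each individual
#' occupies two consecutive rows (one per allele copy, loci across columns);
#' in the one-row layout each locus occupies two adjacent columns.
#'
#' @param path path to the file.
#' @param one_row_per_individual logical; layout switch (default two-row).
#' @param missing integer code for missing alleles (default `-9`).
#' @param header logical; whether the first line holds locus names.  When
#'   `FALSE`, loci are named `L1`, `L2`, ...
#' @param has_pop_column logical; whether column 2 is a group label.
#' @return A [genotype_table()].
#' @export
read_structure <- function(path, one_row_per_individual = FALSE,
                           missing = -9L, header = TRUE,
                           has_pop_column = FALSE) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) < 1 + header) stop("STRUCTURE file too short: ", path)
  toks <- lapply(raw, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
  loci <- NULL
  if (header) {
    loci <- toks[[1]]
    toks <- toks[-1]
  }
  meta_cols <- 1L + has_pop_column
  ncols <- unique(lengths(toks))
  if (length(ncols) != 1) stop("ragged rows in STRUCTURE file ", path)
  ncols <- ncols - meta_cols
  parse_block <- function(cols) {
    m <- suppressWarnings(
      matrix(as.integer(unlist(cols)), nrow = length(cols), byrow = TRUE))
    if (anyNA(m)) stop("non-numeric allele code in STRUCTURE file ", path)
    m
  }
  if (one_row_per_individual) {
    if (ncols %% 2L != 0L) {
      stop("one-row layout needs an even number of allele columns in ", path)
    }
    L <- ncols %/% 2L
    ids <- vapply(toks, `[`, "", 1L)
    grp <- if (has_pop_column) vapply(toks, `[`, "", 2L)
    m <- parse_block(lapply(toks, function(t) t[-seq_len(meta_cols)]))
    a1 <- m[, 2L * seq_len(L) - 1L, drop = FALSE]
    a2 <- m[, 2L * seq_len(L), drop = FALSE]
  } else {
    if (length(toks) %% 2L != 0L) {
      stop("two-row layout needs an even number of data rows in ", path)
    }
    L <- ncols
    odd <- seq(1L, length(toks), by = 2L)
    ids <- vapply(toks[odd], `[`, "", 1L)
    ids2 <- vapply(toks[odd + 1L], `[`, "", 1L)
    if (!identical(ids, ids2)) {
      stop("consecutive row IDs disagree in two-row STRUCTURE file ", path)
    }
    grp <- if (has_pop_column) vapply(toks[odd], `[`, "", 2L)
    m <- parse_block(lapply(toks, function(t) t[-seq_len(meta_cols)]))
    a1 <- m[odd, , drop = FALSE]
    a2 <- m[odd + 1L, , drop = FALSE]
  }
  a1[a1 == missing] <- NA_integer_
  a2[a2 == missing] <- NA_integer_
  # unordered pair: a half-missing call is invalid, mirror the constructor
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  if (length(loci) != L) {
    stop("header names ", length(loci), " loci but rows hold ", L, " in ", path)
  }
  genotype_table(ids, loci, a1, a2,
                 group = if (has_pop_column) as.character(grp))
}

#' Write a STRUCTURE-format genotype file
#'
#' Deterministic output; see [read_structure()] for the layouts.
#'
#' @inheritParams read_structure
#' @param x a [genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, one_row_per_individual = FALSE,
                            missing = -9L, header = TRUE) {
  enc <- function(m) {
    m[is.na(m)] <- as.integer(missing)
    m
  }
  a1 <- enc(x$a1)
  a2 <- enc(x$a2)
  out <- if (header) paste(x$loci, collapse = " ") else character()
  if (one_row_per_individual) {
    L <- length(x$loci)
    inter <- matrix(NA_integer_, nrow(a1), 2L * L)
    inter[, 2L * seq_len(L) - 1L] <- a1
    inter[, 2L * seq_len(L)] <- a2
    body <- paste(x$ids, apply(inter, 1L, paste, collapse = " "))
  } else {
    body <- as.vector(rbind(
      paste(x$ids, apply(a1, 1L, paste, collapse = " ")),
      paste(x$ids, apply(a2, 1L, paste, collapse = " "))))
  }
  writeLines(c(out, body), path)
  invisible(path)
}
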