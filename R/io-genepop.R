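# GENEPOP format: title line, locus names (one per line or comma-separated),
# then POP blocks of "id , 0101 0202 ..." rows with 2- or 3-digit allele
# encoding; "00"/"000" pairs are missing.

#' Read a GENEPOP file
#'
#' Supports the 2-digit and 3-digit allele encodings, locus names given one
#' per line or comma-separated, case-insensitive `POP` separators, and is
#' insensitive to trailing whitespace and blank lines.  POP blocks become
#' `group` labels `pop1`, `pop2`, ...
#'
#' @param path path to a GENEPOP file.
#' @param coords optional path to a coordinates CSV (`id,x,y`); if given the
#'   result is a [spatial_genotypes()] object via [attach_coords()].
#' @param coord_mode passed to [read_coords_csv()] when `coords` is given.
#' @return A [genotype_table()], or [spatial_genotypes()] when `coords` is
#'   supplied.
#' @export
read_genepop <- function(path, coords = NULL, coord_mode = "planar_km") {
  raw <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", raw)
  keep <- nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) < 3) stop("GENEPOP file too short: ", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP separator found in ", path)
  loci <- trimws(unlist(strsplit(lines[2:(first_pop - 1)], ",")))
  loci <- loci[nzchar(loci)]
  pop_idx <- cumsum(is_pop)
  ids <- character()
  groups <- character()
  rows <- list()
  width <- NA_integer_
  for (k in seq_along(lines)) {
    if (k < first_pop || is_pop[k]) next
    parts <- strsplit(lines[k], ",")[[1]]
    if (length(parts) < 2) {
      stop("line ", lineno[k], ": expected 'id , genotypes' in ", path)
    }
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    if (length(toks) != length(loci)) {
      stop("line ", lineno[k], ": ", length(toks), " genotype field(s) for ",
           length(loci), " loci (ragged row) in ", path)
    }
    w <- unique(nchar(toks))
    if (length(w) != 1 || !(w %in% c(4L, 6L)) || any(grepl("[^0-9]", toks))) {
      stop("line ", lineno[k], ": unknown allele encoding width (expected ",
           "4 or 6 digits per genotype) in ", path)
    }
    if (is.na(width)) width <- w / 2L
    if (w / 2L != width) {
      stop("line ", lineno[k], ": mixed allele encoding widths in ", path)
    }
    a1 <- as.integer(substr(toks, 1L, width))
    a2 <- as.integer(substr(toks, width + 1L, 2L * width))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    bad <- xor(is.na(a1), is.na(a2))
    if (any(bad)) {
      stop("line ", lineno[k], ": half-missing genotype (one allele 0) in ",
           path)
    }
    ids <- c(ids, id)
    groups <- c(groups, paste0("pop", pop_idx[k]))
    rows[[length(rows) + 1L]] <- rbind(a1, a2)
  }
  if (length(rows) == 0) stop("no genotype rows found in ", path)
  a1 <- do.call(rbind, lapply(rows, function(r) r[1, ]))
  a2 <- do.call(rbind, lapply(rows, function(r) r[2, ]))
  gt <- genotype_table(ids, loci, a1, a2, group = groups)
  if (is.null(coords)) return(gt)
  attach_coords(gt, read_coords_csv(coords, mode = coord_mode))
}

#' Write a GENEPOP file
#'
#' Output is byte-stable for a fixed input: loci one per line, groups (POP
#' blocks) in order of first appearance of `group` labels, individuals in
#' table order.  The allele encoding width is 2 digits when all codes are
#' <= 99, else 3 digits.
#'
#' @param x a [genotype_table()].
#' @param path output path.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "sibpop export") {
  codes <- c(x$a1, x$a2)
  mx <- suppressWarnings(max(codes, na.rm = TRUE))
  if (!is.finite(mx)) mx <- 1L
  if (mx > 999L) stop("allele code ", mx, " exceeds 3-digit GENEPOP encoding")
  width <- if (mx > 99L) 3L else 2L
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = width, flag = "0")
  }
  group <- x$group %||% rep("pop1", length(x$ids))
  out <- c(title, x$loci)
  for (g in unique(group)) {
    out <- c(out, "POP")
    for (i in which(group == g)) {
      geno <- paste0(fmt(x$a1[i, ]), fmt(x$a2[i, ]), collapse = " ")
      out <- c(out, paste0(x$ids[i], " , ", geno))
    }
  }
  writeLines(out, path)
  invisible(path)
}
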