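#' Diploid codominant genotype table
#'
#' The universal input container: `n` individuals typed at `L` codominant
#' loci (e.g. microsatellites).  Each call is an unordered pair of positive
#' integer allele codes; a missing call has both alleles `NA`.  Calls are
#' stored canonically with the smaller allele first, so two tables with the
#' same calls are `identical()` regardless of input allele order.
#'
#' @param ids character vector of unique individual identifiers.
#' @param loci character vector of unique locus names.
#' @param a1,a2 integer matrices (`n x L`) of allele codes; `NA` for missing.
#'   A call must be either both-present or both-missing.
#' @param group optional character vector (length `n`) of group labels
#'   (e.g. lek or state of origin).
#' @return An object of class `genotype_table`.
#' @export
#' @examples
#' gt <- genotype_table(
#'   ids = c("i1", "i2"), loci = c("locA", "locB"),
#'   a1 = rbind(c(1L, 2L), c(1L, NA)), a2 = rbind(c(1L, 3L), c(2L, NA))
#' )
#' gt
genotype_table <- function(ids, loci, a1, a2, group = NULL) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  n <- length(ids)
  L <- length(loci)
  if (!all(dim(a1) == c(n, L)) || !all(dim(a2) == c(n, L))) {
    stop("allele matrices must be ", n, " x ", L)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate individual IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(loci)) stop("duplicate locus names")
  half <- which(is.na(a1) != is.na(a2))
  if (length(half) > 0) {
    stop("half-missing calls (one allele NA) at ", length(half), " cell(s)")
  }
  if (any(a1 < 1L, na.rm = TRUE) || any(a2 < 1L, na.rm = TRUE)) {
    stop("allele codes must be positive integers (0 is reserved for missing)")
  }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != n) stop("`group` must have one label per individual")
  }
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2, group = group),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat("<genotype_table> ", length(x$ids), " individuals x ", length(x$loci),
      " loci; ", sprintf("%.1f%%", 100 * miss), " missing calls",
      if (!is.null(x$group)) paste0("; ", length(unique(x$group)), " groups"),
      "\n", sep = "")
  invisible(x)
}

#' Number of individuals / loci in a genotype table
#' @param x a [genotype_table()].
#' @return Integer count.
#' @export
n_ind <- function(x) length(x$ids)

#' @rdname n_ind
#' @export
n_loci <- function(x) length(x$loci)

#' Observed allele sets per locus
#'
#' @param x a [genotype_table()].
#' @return Named list; per locus the sorted vector of observed allele codes.
#' @export
locus_alleles <- function(x) {
  stats::setNames(lapply(seq_along(x$loci), function(l) {
    sort(unique(c(x$a1[, l], x$a2[, l])))
  }), x$loci)
}

#' Subset a genotype table
#'
#' @param x a [genotype_table()].
#' @param i individual selector (indices, logical, or IDs).
#' @param j locus selector (indices, logical, or names).
#' @param ... unused.
#' @return A `genotype_table` restricted to the selected rows/columns.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$ids)
  if (missing(j)) j <- seq_along(x$loci)
  if (is.character(i)) i <- match(i, x$ids)
  if (is.character(j)) j <- match(j, x$loci)
  if (anyNA(i)) stop("unknown individual ID in subset")
  if (anyNA(j)) stop("unknown locus in subset")
  genotype_table(x$ids[i], x$loci[j],
                 x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                 group = if (!is.null(x$group)) x$group[i])
}

# Equality helper used by round-trip tests and the pipeline manifest.
#' @method all.equal genotype_table
#' @export
all.equal.genotype_table <- function(target, current, ...) {
  msgs <- character()
  if (!identical(target$ids, current$ids)) msgs <- c(msgs, "ids differ")
  if (!identical(target$loci, current$loci)) msgs <- c(msgs, "loci differ")
  if (!identical(unname(target$a1), unname(current$a1)) ||
      !identical(unname(target$a2), unname(current$a2))) {
    msgs <- c(msgs, "calls differ")
  }
  if (length(msgs) == 0) TRUE else msgs
}

#' Spatially referenced genotypes
#'
#' Joins a genotype table to planar coordinates (km).  This is the input to
#' thinning, kriging, and the bifurcation process.
#'
#' @param geno a [genotype_table()].
#' @param coords numeric matrix (`n x 2`, columns x/y) in km, rows aligned
#'   with `geno$ids`.
#' @return An object of class `spatial_genotypes`.
#' @export
spatial_genotypes <- function(geno, coords) {
  stopifnot(inherits(geno, "genotype_table"))
  coords <- as.matrix(coords)
  if (nrow(coords) != length(geno$ids) || ncol(coords) != 2) {
    stop("`coords` must be an n x 2 matrix aligned with the genotype table")
  }
  if (anyNA(coords)) stop("coordinates contain NA")
  storage.mode(coords) <- "double"
  dimnames(coords) <- list(geno$ids, c("x", "y"))
  structure(list(geno = geno, coords = coords, coord_mode = "planar_km"),
            class = "spatial_genotypes")
}

#' @export
print.spatial_genotypes <- function(x, ...) {
  print(x$geno)
  rx <- range(x$coords[, 1])
  ry <- range(x$coords[, 2])
  cat(sprintf("  coordinates (planar km): x in [%.1f, %.1f], y in [%.1f, %.1f]\n",
              rx[1], rx[2], ry[1], ry[2]))
  invisible(x)
}

#' Subset spatially referenced genotypes by individual
#' @param x a [spatial_genotypes()] object.
#' @param i individual selector (indices, logical, or IDs).
#' @param ... unused.
#' @return A `spatial_genotypes` object restricted to the selection.
#' @export
`[.spatial_genotypes` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$geno$ids)
  if (anyNA(i)) stop("unknown individual ID in subset")
  spatial_genotypes(x$geno[i, ], x$coords[i, , drop = FALSE])
}
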