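# CSV genotype tables (id[,group],locus.1,locus.2,...) and coordinate
# tables (id,x,y), plus the join that produces spatially referenced data.

#' Read / write a CSV genotype table
#'
#' Layout: column `id`, optional column `group`, then two columns per locus
#' named `<locus>.1` and `<locus>.2`.  Empty cells or `0` are missing.
#'
#' @param path file path.
#' @return A [genotype_table()].
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("genotype CSV needs an 'id' column: ", path)
  group <- if ("group" %in% names(df)) as.character(df$group)
  acols <- setdiff(names(df), c("id", "group"))
  if (length(acols) %% 2L != 0L) {
    stop("odd number of allele columns in ", path)
  }
  base <- sub("\\.[12]$", "", acols)
  loci <- unique(base)
  need <- c(paste0(loci, ".1"), paste0(loci, ".2"))
  if (!all(need %in% acols)) {
    stop("allele columns must come in '<locus>.1'/'<locus>.2' pairs in ", path)
  }
  grab <- function(suffix) {
    m <- as.matrix(df[paste0(loci, ".", suffix)])
    storage.mode(m) <- "integer"
    m[m == 0L] <- NA_integer_
    m
  }
  genotype_table(df$id, loci, grab(1), grab(2), group = group)
}

#' @rdname read_genotype_csv
#' @param x a [genotype_table()].
#' @export
write_genotype_csv <- function(x, path) {
  df <- data.frame(id = x$ids, stringsAsFactors = FALSE)
  if (!is.null(x$group)) df$group <- x$group
  for (l in seq_along(x$loci)) {
    df[[paste0(x$loci[l], ".1")]] <- x$a1[, l]
    df[[paste0(x$loci[l], ".2")]] <- x$a2[, l]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "0")
  invisible(path)
}

#' Read a coordinate table
#'
#' Columns `id,x,y`.  `mode = "planar_km"` takes x/y as projected km;
#' `mode = "lonlat"` takes x = longitude, y = latitude in degrees, which
#' [attach_coords()] projects to planar km with a Lambert azimuthal
#' equal-area projection centered on the sample centroid.
#'
#' @param path file path.
#' @param mode coordinate mode, `"planar_km"` or `"lonlat"`.
#' @return A `geo_table` data frame with attribute `coord_mode`.
#' @export
read_coords_csv <- function(path, mode = c("planar_km", "lonlat")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "x", "y") %in% names(df))) {
    stop("coordinate CSV needs columns id,x,y: ", path)
  }
  geo_table(df$id, df$x, df$y, mode = mode)
}

#' Construct a coordinate table
#'
#' @param id individual identifiers (must be unique).
#' @param x,y numeric coordinates (km, or degrees under `mode = "lonlat"`).
#' @param mode coordinate mode; see [read_coords_csv()].
#' @return A data frame of class `geo_table`.
#' @export
geo_table <- function(id, x, y, mode = c("planar_km", "lonlat")) {
  mode <- match.arg(mode)
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate IDs in coordinate table")
  if (anyNA(x) || anyNA(y)) stop("coordinates contain NA")
  structure(data.frame(id = id, x = as.numeric(x), y = as.numeric(y),
                       stringsAsFactors = FALSE),
            coord_mode = mode, class = c("geo_table", "data.frame"))
}

# Lambert azimuthal equal-area projection of lon/lat degrees to planar km,
# centered at the sample centroid.  Adequate at sub-continental extents; all
# downstream distances are Euclidean on this plane.
project_lonlat <- function(lon, lat, center = NULL) {
  R <- 6371
  rad <- pi / 180
  c0 <- center %||% c(mean(lon), mean(lat))
  l0 <- c0[1] * rad
  f0 <- c0[2] * rad
  l <- lon * rad
  f <- lat * rad
  k <- sqrt(2 / (1 + sin(f0) * sin(f) + cos(f0) * cos(f) * cos(l - l0)))
  cbind(x = R * k * cos(f) * sin(l - l0),
        y = R * k * (cos(f0) * sin(f) - sin(f0) * cos(f) * cos(l - l0)))
}

#' Join genotypes to coordinates
#'
#' Order-aligns a coordinate table to a genotype table.  Extra coordinates
#' are ignored (with a message); genotyped individuals without coordinates
#' raise an error naming them (`policy = "error"`) or are dropped with a
#' message (`policy = "drop"`).  Lon/lat input is projected to planar km.
#'
#' @param geno a [genotype_table()].
#' @param geo a [geo_table()] (or data frame with `id,x,y`).
#' @param policy what to do with genotyped individuals lacking coordinates.
#' @return A [spatial_genotypes()] object.
#' @export
attach_coords <- function(geno, geo, policy = c("error", "drop")) {
  policy <- match.arg(policy)
  stopifnot(inherits(geno, "genotype_table"))
  if (!all(c("id", "x", "y") %in% names(geo))) {
    stop("`geo` needs columns id, x, y")
  }
  mode <- attr(geo, "coord_mode") %||% "planar_km"
  m <- match(geno$ids, geo$id)
  absent <- geno$ids[is.na(m)]
  if (length(absent) > 0) {
    if (policy == "error") {
      stop("no coordinates for: ", paste(absent, collapse = ", "))
    }
    message("dropping ", length(absent), " individual(s) without coordinates")
    geno <- geno[!is.na(m), ]
    m <- m[!is.na(m)]
  }
  extra <- setdiff(geo$id, geno$ids)
  if (length(extra) > 0) {
    message("ignoring ", length(extra), " coordinate row(s) with no genotype")
  }
  xy <- cbind(geo$x[m], geo$y[m])
  if (mode == "lonlat") xy <- project_lonlat(xy[, 1], xy[, 2])
  spatial_genotypes(geno, xy)
}
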