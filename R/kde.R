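# Maximum-posterior group assignment and utilization-distribution contours
# (home-range convention): the v-level region is the smallest-area set
# holding fraction v of the estimated kernel density mass.

#' Assign individuals to their maximum-posterior group
#'
#' @param Q `n x K` membership matrix (rows sum to 1).
#' @return A data frame with columns `id`, `group` (argmax column index;
#'   ties broken toward the lowest index) and `tie` (logical tie flag).
#' @export
assign_max_posterior <- function(Q) {
  Q <- as.matrix(Q)
  grp <- max.col(Q, ties.method = "first")
  mx <- Q[cbind(seq_len(nrow(Q)), grp)]
  tie <- rowSums(abs(Q - mx) < 1e-12) > 1
  data.frame(id = rownames(Q) %||% as.character(seq_len(nrow(Q))),
             group = as.integer(grp), tie = tie, stringsAsFactors = FALSE)
}

# Bivariate normal KDE on a regular grid via separable Gaussian products.
kde_grid <- function(xy, h, grid_n, margin) {
  rx <- range(xy[, 1])
  ry <- range(xy[, 2])
  pad <- function(r) {
    w <- max(diff(r) * margin, 3 * h)
    r + c(-w, w)
  }
  gx <- seq(pad(rx)[1], pad(rx)[2], length.out = grid_n)
  gy <- seq(pad(ry)[1], pad(ry)[2], length.out = grid_n)
  Gx <- exp(-outer(gx, xy[, 1], `-`)^2 / (2 * h^2))
  Gy <- exp(-outer(gy, xy[, 2], `-`)^2 / (2 * h^2))
  z <- (Gx %*% t(Gy)) / (2 * pi * h^2 * nrow(xy))
  list(x = gx, y = gy, z = z)
}

#' Kernel-density subpopulation-center contours
#'
#' Estimates a bivariate normal kernel density per group with the reference
#' bandwidth `h = sigma * n^(-1/6)`, `sigma = sqrt((var(x) + var(y)) / 2)`,
#' and extracts the 25/50/75% utilization-distribution polygons: the
#' v-level contour encloses the smallest-area region containing fraction v
#' of the (grid-normalized) density mass, so the regions nest by
#' construction.
#'
#' @param coords `n x 2` matrix of planar coordinates (km).
#' @param groups group label per row (default: one group).
#' @param levels probability-volume levels (default `c(0.25, 0.50, 0.75)`).
#' @param bandwidth kernel bandwidth in km; default the reference bandwidth.
#' @param grid_n grid resolution per axis (default 200).
#' @param margin grid expansion per side as a fraction of the range
#'   (default 0.10; never less than 3 bandwidths).
#' @param min_group smallest group size contoured (default 5).
#' @return An object of class `kde_contours`: per group a list with the
#'   bandwidth, grid, and per level the density threshold, attained mass,
#'   total polygon area (km^2) and polygon rings.
#' @export
kde_contours <- function(coords, groups = NULL,
                         levels = c(0.25, 0.50, 0.75), bandwidth = NULL,
                         grid_n = 200, margin = 0.10, min_group = 5) {
  coords <- as.matrix(coords)
  groups <- groups %||% rep("all", nrow(coords))
  levels <- sort(levels)
  out <- list()
  for (g in unique(as.character(groups))) {
    xy <- coords[groups == g, , drop = FALSE]
    if (nrow(xy) < min_group) {
      stop("group '", g, "' has fewer than ", min_group, " points")
    }
    if (stats::var(xy[, 1]) + stats::var(xy[, 2]) <= 0) {
      stop("group '", g, "' has zero spatial spread; jitter the points")
    }
    sigma <- sqrt((stats::var(xy[, 1]) + stats::var(xy[, 2])) / 2)
    h <- bandwidth %||% (sigma * nrow(xy)^(-1 / 6))
    grid <- kde_grid(xy, h, grid_n, margin)
    cell <- diff(grid$x[1:2]) * diff(grid$y[1:2])
    mass <- grid$z * cell
    mass <- mass / sum(mass)
    ord <- order(grid$z, decreasing = TRUE)
    cum <- cumsum(mass[ord])
    lev_out <- lapply(levels, function(v) {
      k <- which(cum >= v)[1]
      thr <- grid$z[ord[k]]
      rings <- grDevices::contourLines(grid$x, grid$y, grid$z, levels = thr)
      area <- sum(vapply(rings, function(r) {
        abs(sum(r$x * c(r$y[-1], r$y[1]) - c(r$x[-1], r$x[1]) * r$y)) / 2
      }, 0))
      list(level = v, threshold = thr, mass = sum(mass[grid$z >= thr]),
           area = area, rings = rings)
    })
    names(lev_out) <- paste0(levels * 100, "%")
    out[[g]] <- list(group = g, n = nrow(xy), bandwidth = h,
                     grid = grid, contours = lev_out)
  }
  structure(out, levels = levels, class = "kde_contours")
}

#' @export
print.kde_contours <- function(x, ...) {
  cat("<kde_contours> ", length(x), " group(s) at levels ",
      paste(attr(x, "levels") * 100, collapse = "/"), "%\n", sep = "")
  for (g in x) {
    cat("  ", g$group, ": n = ", g$n, ", h = ", sprintf("%.2f", g$bandwidth),
        " km; areas ", paste(sprintf("%.0f", vapply(g$contours, `[[`, 0,
                                                    "area")),
                             collapse = " < "), " km^2\n", sep = "")
  }
  invisible(x)
}

#' Export KDE contour polygons as GeoJSON
#'
#' One feature per (group, level); ring coordinates are in the planar km
#' frame of the input.
#'
#' @param x a [kde_contours()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
kde_to_geojson <- function(x, path) {
  feats <- list()
  for (g in x) {
    for (cl in g$contours) {
      rings <- lapply(cl$rings, function(r) {
        cbind(c(r$x, r$x[1]), c(r$y, r$y[1]))
      })
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(group = g$group, level = cl$level,
                          area_km2 = cl$area),
        geometry = list(type = "MultiPolygon",
                        coordinates = lapply(rings, list)))
    }
  }
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
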