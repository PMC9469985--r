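# Spatial interpolation of cluster memberships: a thin-plate spline
# f(x) = d0 + d1 x + d2 y + sum_i c_i phi(|x - x_i|), phi(r) = r^2 log r,
# with smoothing weight lambda chosen by generalized cross-validation.
# lambda = 0 gives exact interpolation; affine fields are reproduced exactly
# at any lambda.  Predictions of membership surfaces are clipped to [0, 1].

tps_basis <- function(r) {
  out <- r * r * log(r)
  out[r == 0] <- 0
  out
}

#' Fit a membership interpolation surface
#'
#' Fits a thin-plate spline to membership values observed at sample
#' coordinates.  The smoothing weight is chosen by minimizing the GCV score
#' over lambda unless `lambda` is given (use `lambda = 0` for exact
#' interpolation).  Duplicate coordinates are perturbed by a seeded jitter
#' of 1e-6 km before fitting.
#'
#' @param coords `n x 2` matrix of planar coordinates (km); `n >= 3`,
#'   not all collinear.
#' @param values membership values in `[0, 1]`, one per row of `coords`.
#' @param lambda smoothing weight; `NULL` (default) selects it by GCV.
#' @param seed seed for the duplicate-coordinate jitter.
#' @return An object of class `kriged_surface`; evaluate it anywhere with
#'   [predict.kriged_surface()].
#' @export
fit_surface <- function(coords, values, lambda = NULL, seed = NULL) {
  coords <- as.matrix(coords)
  values <- as.numeric(values)
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 points to fit a surface")
  if (length(values) != n) stop("one value per coordinate row required")
  if (any(values < -1e-9) || any(values > 1 + 1e-9)) {
    stop("membership values must lie in [0, 1]")
  }
  dup <- duplicated(coords)
  if (any(dup)) {
    jit <- with_seed(seed %||% 0L,
                     matrix(stats::runif(2 * sum(dup), -1e-6, 1e-6),
                            ncol = 2))
    coords[dup, ] <- coords[dup, , drop = FALSE] + jit
  }
  Tm <- cbind(1, coords)
  qrT <- qr(Tm)
  if (qrT$rank < 3) {
    stop("sample coordinates are collinear; jitter them or add points")
  }
  Qfull <- qr.Q(qrT, complete = TRUE)
  Q1 <- Qfull[, 1:3, drop = FALSE]
  Q2 <- Qfull[, -(1:3), drop = FALSE]
  Rm <- qr.R(qrT)
  Phi <- tps_basis(as.matrix(stats::dist(coords)))
  if (ncol(Q2) == 0) {
    # three non-collinear points: the plane through them, no radial part
    dvec <- backsolve(Rm, crossprod(Q1, values))
    return(structure(list(knots = coords, c = rep(0, n),
                          d = as.vector(dvec), lambda = lambda %||% 0,
                          bbox = rbind(range(coords[, 1]),
                                       range(coords[, 2]))),
                     class = "kriged_surface"))
  }
  B <- crossprod(Q2, Phi %*% Q2)
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  a <- crossprod(eg$vectors, crossprod(Q2, values))[, 1]
  gcv <- function(log_nl) {
    nl <- exp(log_nl)
    shrink <- nl / (d + nl)
    rss <- sum((a * shrink)^2)
    tr <- 3 + sum(d / (d + nl))
    n * rss / (n - tr)^2
  }
  if (is.null(lambda)) {
    # GCV degenerates as the effective degrees of freedom approach n (the
    # denominator (n - tr A)^2 vanishes), which would select near-exact
    # interpolation for pure noise; bound the search to df <= 3 + 0.85(n-3).
    dpos <- d[d > 0]
    scale <- if (length(dpos) > 0) stats::median(dpos) else 1
    tr_excess <- function(nl) sum(d / (d + nl)) - 0.85 * (n - 3)
    lo <- min(dpos) * 1e-9
    hi <- max(dpos) * 1e6
    if (tr_excess(lo) > 0) {
      lo <- stats::uniroot(tr_excess, lower = lo, upper = hi)$root
    }
    opt <- stats::optimize(gcv, interval = log(c(lo, hi)))
    lambda <- exp(opt$minimum) / n
  }
  nl <- lambda * n
  gamma <- if (all(d + nl > 0)) a / (d + nl) else {
    ifelse(d + nl > 0, a / (d + nl), 0)
  }
  cvec <- as.vector(Q2 %*% (eg$vectors %*% gamma))
  resid <- values - Phi %*% cvec
  dvec <- backsolve(Rm, crossprod(Q1, resid))
  structure(list(knots = coords, c = cvec, d = as.vector(dvec),
                 lambda = lambda,
                 bbox = rbind(range(coords[, 1]), range(coords[, 2]))),
            class = "kriged_surface")
}

#' Evaluate a kriged surface
#'
#' @param object a [fit_surface()] result.
#' @param newdata `m x 2` matrix of coordinates.
#' @param clip clip predictions into `[0, 1]` (default `TRUE`)?
#' @param ... unused.
#' @return Numeric vector of surface values at `newdata`.
#' @export
predict.kriged_surface <- function(object, newdata, clip = TRUE, ...) {
  newdata <- matrix(as.numeric(as.matrix(newdata)), ncol = 2)
  dx <- outer(newdata[, 1], object$knots[, 1], `-`)
  dy <- outer(newdata[, 2], object$knots[, 2], `-`)
  Phi <- tps_basis(sqrt(dx * dx + dy * dy))
  f <- object$d[1] + object$d[2] * newdata[, 1] + object$d[3] * newdata[, 2] +
    as.vector(Phi %*% object$c)
  if (clip) f <- pmin(1, pmax(0, f))
  f
}

#' @export
print.kriged_surface <- function(x, ...) {
  cat("<kriged_surface> ", nrow(x$knots), " knots; lambda = ",
      format(x$lambda, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Rasterize a kriged surface on a regular grid
#'
#' @param surface a [fit_surface()] result.
#' @param n grid resolution per axis (default 200).
#' @param margin bounding-box expansion per side as a fraction of the range.
#' @param clip passed to [predict.kriged_surface()].
#' @return A list `x`, `y` (axis vectors) and `z` (`n x n` value matrix,
#'   rows indexed by `x`).
#' @export
surface_grid <- function(surface, n = 200, margin = 0.05, clip = TRUE) {
  bb <- surface$bbox
  ex <- function(r) r + c(-1, 1) * margin * diff(r)
  xs <- seq(ex(bb[1, ])[1], ex(bb[1, ])[2], length.out = n)
  ys <- seq(ex(bb[2, ])[1], ex(bb[2, ])[2], length.out = n)
  pts <- cbind(rep(xs, times = n), rep(ys, each = n))
  z <- matrix(predict(surface, pts, clip = clip), n, n)
  list(x = xs, y = ys, z = z)
}

#' Select individuals inside membership isoclines
#'
#' Evaluates each cluster's surface at every sample's own coordinates and
#' retains an individual for cluster k iff its value is `>= threshold`
#' (boundary values retained).  With `threshold > 0.5` the retained sets are
#' disjoint; in the numerically impossible event that both surfaces clear
#' the threshold at one sample, the larger value wins (ties to cluster 1).
#'
#' @param surfaces list of two [fit_surface()] results fitted to
#'   complementary membership columns.
#' @param coords `n x 2` sample coordinates.
#' @param threshold isocline level in (0.5, 1); default 0.70.  Values
#'   `<= 0.5` are allowed with a warning (disjointness no longer guaranteed).
#' @param ids optional individual IDs (default row names or indices).
#' @return An object of class `isocline_selection`: `retained` (list of two
#'   id vectors), `values` (`n x 2` surface values), `threshold`.
#' @export
select_by_isocline <- function(surfaces, coords, threshold = 0.70,
                               ids = NULL) {
  stopifnot(length(surfaces) == 2)
  coords <- as.matrix(coords)
  if (threshold <= 0.5) {
    warning("threshold <= 0.5: retained sets may overlap")
  }
  if (threshold >= 1) stop("`threshold` must be < 1")
  ids <- ids %||% rownames(coords) %||% as.character(seq_len(nrow(coords)))
  v <- vapply(surfaces, predict, numeric(nrow(coords)), newdata = coords)
  v <- matrix(v, ncol = 2)
  in1 <- v[, 1] >= threshold
  in2 <- v[, 2] >= threshold
  both <- in1 & in2
  if (any(both)) {
    prefer2 <- both & (v[, 2] > v[, 1])
    in1[both] <- !prefer2[both]
    in2[both] <- prefer2[both]
  }
  structure(list(retained = list(ids[in1], ids[in2]),
                 values = v, threshold = threshold, ids = ids),
            class = "isocline_selection")
}

#' @export
print.isocline_selection <- function(x, ...) {
  cat("<isocline_selection> threshold ", x$threshold, ": ",
      length(x$retained[[1]]), " + ", length(x$retained[[2]]),
      " of ", nrow(x$values), " retained\n", sep = "")
  invisible(x)
}

#' Export a surface grid as an ESRI ASCII raster
#'
#' @param grid a [surface_grid()] result (requires equal x/y spacing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  dx <- diff(grid$x[1:2])
  dy <- diff(grid$y[1:2])
  if (abs(dx - dy) > 1e-9 * max(dx, dy)) {
    stop("ASCII grid export needs square cells; refit the grid")
  }
  hdr <- c(paste("ncols", length(grid$x)),
           paste("nrows", length(grid$y)),
           paste("xllcorner", grid$x[1] - dx / 2),
           paste("yllcorner", grid$y[1] - dy / 2),
           paste("cellsize", dx),
           "NODATA_value -9999")
  rows <- apply(t(grid$z)[rev(seq_along(grid$y)), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
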