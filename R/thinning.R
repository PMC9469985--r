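# Spatial sample thinning: agglomerative clustering of locations cut at a
# threshold distance, then uniform subsampling within each cluster.

#' Cluster sample locations by threshold distance
#'
#' Agglomerative hierarchical clustering (Lance-Williams updates via
#' [stats::hclust()]) of planar coordinates, cut so that distinct clusters
#' are separated by more than `cut_km`.  Individuals are ordered internally
#' by (x, y, id) before clustering so the partition is invariant to input
#' order; cluster labels are assigned by first appearance in input order.
#'
#' @param x a [spatial_genotypes()] object, or an `n x 2` coordinate matrix.
#' @param cut_km threshold distance in km (default 50): merges at height
#'   `<= cut_km` are collapsed, so clusters are separated by `> cut_km`.
#' @param linkage linkage method understood by [stats::hclust()]
#'   (default `"complete"`).
#' @return Integer vector of cluster memberships (1-based, one per
#'   individual, in input order).
#' @export
cluster_locations <- function(x, cut_km = 50, linkage = "complete") {
  coords <- if (inherits(x, "spatial_genotypes")) x$coords else as.matrix(x)
  if (!is.numeric(cut_km) || cut_km <= 0) stop("`cut_km` must be > 0")
  ok <- c("complete", "single", "average", "mcquitty", "ward.D", "ward.D2",
          "centroid", "median")
  if (!linkage %in% ok) {
    stop("unknown linkage '", linkage, "'; use one of: ",
         paste(ok, collapse = ", "))
  }
  n <- nrow(coords)
  if (n == 0) stop("no locations to cluster")
  if (n == 1) return(1L)
  ids <- rownames(coords) %||% as.character(seq_len(n))
  ord <- order(coords[, 1], coords[, 2], ids)
  hc <- stats::hclust(stats::dist(coords[ord, , drop = FALSE]),
                      method = linkage)
  cl_sorted <- stats::cutree(hc, h = cut_km)
  cl <- integer(n)
  cl[ord] <- cl_sorted
  as.integer(match(cl, unique(cl)))
}

#' Thin a dataset to homogenize sampling intensity
#'
#' Clusters locations with [cluster_locations()] and retains at most
#' `max_per_cluster` individuals per cluster, subsampled uniformly at random
#' without replacement; clusters at or below the cap are kept whole.
#'
#' @param x a [spatial_genotypes()] object.
#' @param cut_km,linkage passed to [cluster_locations()].
#' @param max_per_cluster retention cap per spatial cluster (default 10).
#' @param seed integer seed for the subsampling.
#' @return A list of class `thinning_result` with elements `data` (the
#'   thinned [spatial_genotypes()]), `kept_ids`, `cluster` (full-length
#'   cluster vector), and `report` (per-cluster n/kept/dropped counts).
#' @export
thin <- function(x, cut_km = 50, max_per_cluster = 10, linkage = "complete",
                 seed = NULL) {
  stopifnot(inherits(x, "spatial_genotypes"))
  if (max_per_cluster < 1) stop("`max_per_cluster` must be >= 1")
  cl <- cluster_locations(x, cut_km = cut_km, linkage = linkage)
  ids <- x$geno$ids
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_along(ids), cl), function(idx) {
      if (length(idx) > max_per_cluster) {
        sort(sample(idx, max_per_cluster))
      } else {
        idx
      }
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  sizes <- tabulate(cl)
  kept_sizes <- tabulate(cl[keep], nbins = length(sizes))
  report <- data.frame(cluster = seq_along(sizes), n = sizes,
                       kept = kept_sizes, dropped = sizes - kept_sizes)
  structure(list(data = x[keep], kept_ids = ids[keep], cluster = cl,
                 report = report, cut_km = cut_km,
                 max_per_cluster = max_per_cluster),
            class = "thinning_result")
}

#' @export
print.thinning_result <- function(x, ...) {
  cat("<thinning_result> ", sum(x$report$n), " -> ", sum(x$report$kept),
      " individuals in ", nrow(x$report), " spatial cluster(s); cut ",
      x$cut_km, " km, cap ", x$max_per_cluster, "\n", sep = "")
  invisible(x)
}
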