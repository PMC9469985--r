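# Multivariate Mantel correlogram: per geographic distance class, the
# Pearson correlation between the genetic-distance matrix and the class
# indicator matrix (each unordered pair once), permutation-tested and
# progressively Bonferroni-corrected (class k corrected for k tests).

#' Mantel correlogram over geographic distance classes
#'
#' Distance classes are equal-width over `[0, max(geo)]`.  By default
#' (`cutoff = TRUE`) classes are tested only up to the class containing the
#' largest nearest-neighbor distance, so every individual participates in
#' some tested class.  Significance is assessed by permuting individual
#' labels of the genetic matrix (two-sided on |r|), and the class-k p-value
#' is corrected by the factor k (progressive Bonferroni).
#'
#' @param geo_dist,gen_dist symmetric distance matrices (or `dist`
#'   objects) over the same `n >= 10` individuals.
#' @param n_classes number of equal-width classes (default 80).
#' @param reps permutations (default 999).
#' @param seed integer seed.
#' @param alpha significance level for the `signif` flag (default 0.05).
#' @param cutoff restrict testing to the all-points-included classes?
#' @return A data frame of class `mantel_correlogram`: one row per tested
#'   class with bounds, pair count, Mantel `r`, `p_raw`, `p_corr`, `signif`.
#' @export
mantel_correlog <- function(geo_dist, gen_dist, n_classes = 80, reps = 999,
                            seed = NULL, alpha = 0.05, cutoff = TRUE) {
  G <- as.matrix(geo_dist)
  D <- as.matrix(gen_dist)
  n <- nrow(G)
  if (!all(dim(D) == c(n, n))) stop("distance matrices differ in size")
  if (n < 10) stop("need at least 10 individuals")
  if (max(abs(G - t(G))) > 1e-8 || max(abs(D - t(D)), na.rm = TRUE) > 1e-8) {
    stop("distance matrices must be symmetric")
  }
  ut <- upper.tri(G)
  gvec <- G[ut]
  breaks <- seq(0, max(gvec), length.out = n_classes + 1)
  cls <- findInterval(gvec, breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
  cls[cls == 0L] <- 1L  # zero-distance pairs fall in the first class
  cls <- pmin(cls, n_classes)
  n_tested <- n_classes
  if (cutoff) {
    diag(G) <- Inf
    max_nn <- max(apply(G, 1, min))
    diag(G) <- 0
    k <- findInterval(max_nn, breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
    n_tested <- min(n_classes, max(1L, k))
  }
  counts <- tabulate(cls, n_classes)
  keep_class <- which(counts[seq_len(n_tested)] >= 2 &
                        counts[seq_len(n_tested)] < length(gvec))
  if (length(keep_class) == 0) stop("no distance class holds >= 2 pairs")
  Ind <- vapply(keep_class, function(k) as.numeric(cls == k),
                numeric(length(gvec)))
  Ind <- scale(Ind)
  dvec <- D[ut]
  if (anyNA(dvec)) stop("genetic distances contain NA")
  np <- length(gvec)
  # sign convention of the Legendre Mantel correlogram (model matrix codes
  # within-class pairs 0): positive r = genetic similarity in the class
  r_of <- function(v) {
    v <- (v - mean(v)) / stats::sd(v)
    -as.vector(crossprod(Ind, v)) / (np - 1)
  }
  r_obs <- r_of(dvec)
  exceed <- rep(0L, length(keep_class))
  with_seed(seed, {
    for (b in seq_len(reps)) {
      p <- sample.int(n)
      r_perm <- r_of(D[p, p][ut])
      exceed <- exceed + (abs(r_perm) >= abs(r_obs) - 1e-12)
    }
  })
  p_raw <- (exceed + 1) / (reps + 1)
  p_corr <- pmin(1, p_raw * seq_along(keep_class))
  out <- data.frame(class = keep_class,
                    d_lower = breaks[keep_class],
                    d_upper = breaks[keep_class + 1],
                    d_mid = (breaks[keep_class] + breaks[keep_class + 1]) / 2,
                    n_pairs = tabulate(cls, n_classes)[keep_class],
                    mantel_r = r_obs, p_raw = p_raw, p_corr = p_corr,
                    signif = p_corr <= alpha)
  structure(out, n_classes = n_classes, n_tested = n_tested,
            reps = reps, class = c("mantel_correlogram", "data.frame"))
}
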