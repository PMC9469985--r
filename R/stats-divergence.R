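# Divergence among groups: the Weir-Cockerham variance-components estimator
# of FST (theta) for multiallelic codominant data, and Jost's D with
# Nei-Chesser unbiased heterozygosities.

# Per-locus group summaries shared by both estimators: sample sizes, allele
# frequencies and heterozygote frequencies per allele, for groups with data.
locus_group_summary <- function(gt, gl, l) {
  alleles <- sort(unique(c(gt$a1[, l], gt$a2[, l])))
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0) return(NULL)
  stats_per_group <- lapply(gl, function(ids) {
    i <- match(ids, gt$ids)
    a1 <- gt$a1[i, l]
    a2 <- gt$a2[i, l]
    typed <- !is.na(a1)
    a1 <- a1[typed]
    a2 <- a2[typed]
    n <- length(a1)
    if (n == 0) return(NULL)
    p <- (tabulate(match(a1, alleles), length(alleles)) +
          tabulate(match(a2, alleles), length(alleles))) / (2 * n)
    het <- a1 != a2
    hfreq <- (tabulate(match(a1[het], alleles), length(alleles)) +
              tabulate(match(a2[het], alleles), length(alleles))) / n
    list(n = n, p = p, h = hfreq)
  })
  keep <- !vapply(stats_per_group, is.null, TRUE)
  if (sum(keep) < 2) return(NULL)
  list(alleles = alleles, groups = stats_per_group[keep])
}

#' Weir-Cockerham theta (FST) between groups
#'
#' Per-allele variance components a (among groups), b (among individuals
#' within groups) and c (within individuals) are computed per locus and
#' summed; the multilocus estimate is `sum(a) / sum(a + b + c)`.  Small
#' negative estimates are possible by construction.
#'
#' @param gt a [genotype_table()].
#' @param groups group labels per individual or a named list of id vectors
#'   (>= 2 groups, each with >= 2 individuals).
#' @return A list of class `divergence_estimate`: `per_locus` (named
#'   vector), `overall`, and the summed `components`.
#' @export
theta_st <- function(gt, groups) {
  gl <- as_group_list(gt, groups)
  if (length(gl) < 2) stop("need at least 2 groups")
  if (any(lengths(gl) < 2)) stop("each group needs >= 2 individuals")
  per_locus <- rep(NA_real_, length(gt$loci))
  names(per_locus) <- gt$loci
  A_sum <- B_sum <- C_sum <- 0
  comp_loc <- matrix(0, length(gt$loci), 3,
                     dimnames = list(gt$loci, c("a", "b", "c")))
  for (l in seq_along(gt$loci)) {
    su <- locus_group_summary(gt, gl, l)
    if (is.null(su)) next
    r <- length(su$groups)
    ni <- vapply(su$groups, `[[`, 0, "n")
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    if (nbar <= 1 || nc <= 0) next
    for (ai in seq_along(su$alleles)) {
      pi <- vapply(su$groups, function(gs) gs$p[ai], 0)
      hi <- vapply(su$groups, function(gs) gs$h[ai], 0)
      pbar <- sum(ni * pi) / (r * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) * s2 / r -
           (2 * nbar - 1) * hbar / (4 * nbar))
      cc <- hbar / 2
      comp_loc[l, ] <- comp_loc[l, ] + c(a, b, cc)
    }
    tot <- sum(comp_loc[l, ])
    if (tot != 0) per_locus[l] <- comp_loc[l, 1] / tot
    A_sum <- A_sum + comp_loc[l, 1]
    B_sum <- B_sum + comp_loc[l, 2]
    C_sum <- C_sum + comp_loc[l, 3]
  }
  denom <- A_sum + B_sum + C_sum
  if (denom == 0) {
    warning("no variance at any locus; theta undefined")
    overall <- NA_real_
  } else {
    overall <- A_sum / denom
  }
  structure(list(per_locus = per_locus, overall = overall,
                 components = c(a = A_sum, b = B_sum, c = C_sum),
                 statistic = "theta_st"),
            class = "divergence_estimate")
}

#' Jost's D between groups
#'
#' Per locus, with `r` groups of harmonic-mean size `n~`:
#' `Hs = mean_i(1 - sum(p_i^2))`, unbiased `Hs' = 2n~/(2n~-1) Hs`,
#' `Ht = 1 - sum(pbar^2)` over unweighted mean frequencies,
#' `Ht' = Ht + Hs'/(2 n~ r)`, and
#' `D = (Ht' - Hs')/(1 - Hs') * r/(r-1)`, clipped to `[0, 1]`.
#' Loci monomorphic across all groups are excluded; the multilocus value is
#' the arithmetic mean over the remaining loci.
#'
#' @inheritParams theta_st
#' @return A list of class `divergence_estimate` with `per_locus` and
#'   `overall`.
#' @export
jost_d <- function(gt, groups) {
  gl <- as_group_list(gt, groups)
  if (length(gl) < 2) stop("need at least 2 groups")
  per_locus <- rep(NA_real_, length(gt$loci))
  names(per_locus) <- gt$loci
  for (l in seq_along(gt$loci)) {
    su <- locus_group_summary(gt, gl, l)
    if (is.null(su) || length(su$alleles) < 2) next
    r <- length(su$groups)
    ni <- vapply(su$groups, `[[`, 0, "n")
    nh <- r / sum(1 / ni)
    P <- vapply(su$groups, `[[`, numeric(length(su$alleles)), "p")
    P <- matrix(P, ncol = r)
    hs <- mean(1 - colSums(P^2))
    hs_u <- 2 * nh / (2 * nh - 1) * hs
    pbar <- rowMeans(P)
    ht <- 1 - sum(pbar^2)
    ht_u <- ht + hs_u / (2 * nh * r)
    if (ht_u <= 0) next  # monomorphic in the pooled sample
    d <- (ht_u - hs_u) / (1 - hs_u) * r / (r - 1)
    per_locus[l] <- min(1, max(0, d))
  }
  ok <- !is.na(per_locus)
  structure(list(per_locus = per_locus,
                 overall = if (any(ok)) mean(per_locus[ok]) else NA_real_,
                 statistic = "jost_d"),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat("<divergence_estimate> ", x$statistic, " = ",
      format(x$overall, digits = 4), " (", sum(!is.na(x$per_locus)),
      " locus/loci)\n", sep = "")
  invisible(x)
}

#' Pairwise divergence matrix among groups
#'
#' @inheritParams theta_st
#' @param statistic `"theta_st"` or `"jost_d"`.
#' @return A symmetric matrix of multilocus pairwise estimates with zero
#'   diagonal.
#' @export
divergence_matrix <- function(gt, groups, statistic = c("theta_st", "jost_d")) {
  statistic <- match.arg(statistic)
  fun <- if (statistic == "theta_st") theta_st else jost_d
  gl <- as_group_list(gt, groups)
  k <- length(gl)
  if (k < 2) stop("need at least 2 groups")
  m <- matrix(0, k, k, dimnames = list(names(gl), names(gl)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      est <- fun(gt, gl[c(i, j)])
      m[i, j] <- m[j, i] <- est$overall
    }
  }
  m
}
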