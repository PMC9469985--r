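# Independent from-scratch oracles for the divergence estimators, coded via
# a different algebraic route than the package (per-copy indicator ANOVA
# mean squares for theta; direct textbook evaluation for Jost's D), plus
# small fixture builders.

# Weir-Cockerham theta via nested ANOVA on allele-copy indicators:
# for each allele, y_ijk = 1 if copy k of individual j in group i is that
# allele.  sigma2_P = (MS_P - MS_I) / (2 n_c), sigma2_I = (MS_I - MS_G)/2,
# sigma2_G = MS_G; theta = sum sigma2_P / sum(all components).
oracle_theta <- function(gt, group_list) {
  num <- 0
  den <- 0
  for (l in seq_along(gt$loci)) {
    copies <- list()
    for (g in seq_along(group_list)) {
      i <- match(group_list[[g]], gt$ids)
      a1 <- gt$a1[i, l]
      a2 <- gt$a2[i, l]
      keep <- !is.na(a1)
      if (sum(keep) > 0) {
        copies[[length(copies) + 1L]] <- rbind(a1[keep], a2[keep])
      }
    }
    if (length(copies) < 2) next
    alleles <- sort(unique(unlist(copies)))
    ni <- vapply(copies, ncol, 0)
    r <- length(ni)
    ntot <- sum(ni)
    nbar <- ntot / r
    nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
    if (nbar <= 1 || nc <= 0) next
    for (al in alleles) {
      ybar_i <- vapply(copies, function(m) mean(m == al), 0)
      ybar <- sum(ni * ybar_i) / ntot
      ss_p <- 2 * sum(ni * (ybar_i - ybar)^2)
      ss_i <- 0
      ss_g <- 0
      for (g in seq_len(r)) {
        y <- copies[[g]] == al
        indbar <- colMeans(y)
        ss_i <- ss_i + 2 * sum((indbar - ybar_i[g])^2)
        ss_g <- ss_g + sum((y[1, ] - indbar)^2 + (y[2, ] - indbar)^2)
      }
      ms_p <- ss_p / (r - 1)
      ms_i <- ss_i / (ntot - r)
      ms_g <- ss_g / ntot
      s2_p <- (ms_p - ms_i) / (2 * nc)
      s2_i <- (ms_i - ms_g) / 2
      s2_g <- ms_g
      num <- num + s2_p
      den <- den + s2_p + s2_i + s2_g
    }
  }
  num / den
}

# Jost's D, textbook evaluation: Nei-Chesser unbiased Hs/Ht with the
# harmonic mean group size, D = (Ht' - Hs')/(1 - Hs') * r/(r-1), clipped to
# [0, 1] per locus, arithmetic mean over polymorphic loci.
oracle_jost_d <- function(gt, group_list) {
  vals <- c()
  for (l in seq_along(gt$loci)) {
    plist <- list()
    ns <- c()
    for (g in seq_along(group_list)) {
      i <- match(group_list[[g]], gt$ids)
      a <- c(gt$a1[i, l], gt$a2[i, l])
      a <- a[!is.na(a)]
      if (length(a) == 0) next
      plist[[length(plist) + 1L]] <- a
      ns <- c(ns, length(a) / 2)
    }
    if (length(plist) < 2) next
    alleles <- sort(unique(unlist(plist)))
    if (length(alleles) < 2) next
    r <- length(plist)
    P <- vapply(plist, function(a) {
      vapply(alleles, function(al) mean(a == al), 0)
    }, numeric(length(alleles)))
    P <- matrix(P, ncol = r)
    nharm <- 1 / mean(1 / ns)
    hs <- mean(apply(P, 2, function(p) 1 - sum(p^2)))
    hs_u <- (2 * nharm / (2 * nharm - 1)) * hs
    ht <- 1 - sum(rowMeans(P)^2)
    ht_u <- ht + hs_u / (2 * nharm * r)
    if (ht_u <= 0) next
    d <- (ht_u - hs_u) / (1 - hs_u) * r / (r - 1)
    vals <- c(vals, min(1, max(0, d)))
  }
  mean(vals)
}

# random genotype table with grouped structure for oracle comparisons
random_grouped_table <- function(n_groups = 2, n_per_group = 6, n_loci = 2,
                                 n_alleles = 4, missing_rate = 0,
                                 seed = 1) {
  set.seed(seed)
  n <- n_groups * n_per_group
  a1 <- matrix(sample.int(n_alleles, n * n_loci, TRUE), n, n_loci)
  a2 <- matrix(sample.int(n_alleles, n * n_loci, TRUE), n, n_loci)
  if (missing_rate > 0) {
    drop <- matrix(runif(n * n_loci) < missing_rate, n, n_loci)
    # keep at least one call per locus
    for (l in seq_len(n_loci)) if (all(drop[, l])) drop[1, l] <- FALSE
    a1[drop] <- NA_integer_
    a2[drop] <- NA_integer_
  }
  grp <- rep(paste0("g", seq_len(n_groups)), each = n_per_group)
  gt <- genotype_table(paste0("i", seq_len(n)), paste0("L", seq_len(n_loci)),
                       a1, a2, group = grp)
  list(gt = gt, groups = split(gt$ids, grp))
}

# two demes fixed for different alleles at every locus
fixed_demes_table <- function(n_per = 6, n_loci = 4) {
  a <- matrix(1L, n_per, n_loci)
  b <- matrix(2L, n_per, n_loci)
  gt <- genotype_table(paste0("i", seq_len(2 * n_per)),
                       paste0("L", seq_len(n_loci)),
                       rbind(a, b), rbind(a, b))
  list(gt = gt, groups = list(g1 = gt$ids[seq_len(n_per)],
                              g2 = gt$ids[n_per + seq_len(n_per)]))
}
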