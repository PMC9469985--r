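# Equilibrium tests: a Monte-Carlo exact test of Hardy-Weinberg proportions
# (allele shuffling, probability-ordering statistic) and a permutation
# likelihood-ratio test of gametic (genotypic) disequilibrium between loci.
# All permutation p-values use the (#extreme + 1) / (reps + 1) convention.

# log conditional probability of a diploid genotype table given its allele
# counts: P = n! 2^h prod(m_a!) / ((2n)! prod(n_jk!))
log_geno_table_prob <- function(a1, a2) {
  n <- length(a1)
  lo <- pmin(a1, a2)  # genotype categories are unordered pairs
  hi <- pmax(a1, a2)
  h <- sum(lo != hi)
  alleles <- sort(unique(c(lo, hi)))
  m <- tabulate(match(lo, alleles), length(alleles)) +
    tabulate(match(hi, alleles), length(alleles))
  code <- match(lo, alleles) * (length(alleles) + 1L) + match(hi, alleles)
  njk <- tabulate(match(code, unique(code)))
  lgamma(n + 1) + h * log(2) + sum(lgamma(m + 1)) -
    lgamma(2 * n + 1) - sum(lgamma(njk + 1))
}

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' The observed alleles at the locus are shuffled into random diploid
#' pairings (the exact-test null conditional on allele counts); a simulated
#' table counts as extreme when its conditional probability is less than or
#' equal to the observed table's (probability ordering).
#'
#' @param gt a [genotype_table()].
#' @param locus locus name or index.
#' @param individuals optional individual subset.
#' @param reps Monte-Carlo replicates (default 9999).
#' @param seed integer seed.
#' @return A list of class `hwp_test`: `p`, `skipped`, `n`, `reps`,
#'   `log_prob_obs`.  Monomorphic loci are skipped (`p = NA`).
#' @export
hwp_test <- function(gt, locus, individuals = NULL, reps = 9999,
                     seed = NULL) {
  sub <- if (is.null(individuals)) gt else gt[individuals, ]
  if (is.character(locus)) locus <- match(locus, sub$loci)
  a1 <- sub$a1[, locus]
  a2 <- sub$a2[, locus]
  typed <- !is.na(a1)
  a1 <- a1[typed]
  a2 <- a2[typed]
  if (length(unique(c(a1, a2))) < 2) {
    return(structure(list(p = NA_real_, skipped = TRUE, n = length(a1),
                          reps = reps, log_prob_obs = NA_real_),
                     class = "hwp_test"))
  }
  lp_obs <- log_geno_table_prob(a1, a2)
  pool <- c(a1, a2)
  n <- length(a1)
  extreme <- with_seed(seed, {
    sum(vapply(seq_len(reps), function(r) {
      s <- sample(pool)
      log_geno_table_prob(s[seq_len(n)], s[n + seq_len(n)]) <= lp_obs + 1e-9
    }, TRUE))
  })
  structure(list(p = (extreme + 1) / (reps + 1), skipped = FALSE, n = n,
                 reps = reps, log_prob_obs = lp_obs),
            class = "hwp_test")
}

# genotype codes (canonical pair index) for one locus, NA for missing
geno_codes <- function(a1, a2) {
  paste0(a1, "/", a2)
}

g2_statistic <- function(f1, f2) {
  tab <- table(f1, f2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- as.numeric(tab)
  e <- as.numeric(e)
  2 * sum(o[o > 0] * log(o[o > 0] / e[o > 0]))
}

#' Permutation test of gametic disequilibrium between two loci
#'
#' Log-likelihood-ratio (G^2) statistic for association between the
#' genotypes at two loci; the null distribution is obtained by permuting
#' one locus's genotypes among individuals.
#'
#' @param gt a [genotype_table()].
#' @param locus_pair two locus names or indices.
#' @param individuals optional individual subset.
#' @param reps permutation replicates (default 9999).
#' @param seed integer seed.
#' @return A list of class `ld_test`: `p`, `skipped`, `statistic`, `n`,
#'   `reps`.  Pairs with a monomorphic member are skipped.
#' @export
ld_test <- function(gt, locus_pair, individuals = NULL, reps = 9999,
                    seed = NULL) {
  sub <- if (is.null(individuals)) gt else gt[individuals, ]
  li <- locus_pair
  if (is.character(li)) li <- match(li, sub$loci)
  stopifnot(length(li) == 2)
  ok <- !is.na(sub$a1[, li[1]]) & !is.na(sub$a1[, li[2]])
  g1 <- geno_codes(sub$a1[ok, li[1]], sub$a2[ok, li[1]])
  g2 <- geno_codes(sub$a1[ok, li[2]], sub$a2[ok, li[2]])
  mono <- length(unique(c(sub$a1[ok, li[1]], sub$a2[ok, li[1]]))) < 2
  mono2 <- length(unique(c(sub$a1[ok, li[2]], sub$a2[ok, li[2]]))) < 2
  if (mono || mono2 || length(g1) < 2) {
    return(structure(list(p = NA_real_, skipped = TRUE,
                          statistic = NA_real_, n = length(g1), reps = reps),
                     class = "ld_test"))
  }
  g1 <- factor(g1)
  g2 <- factor(g2)
  obs <- g2_statistic(g1, g2)
  extreme <- with_seed(seed, {
    sum(vapply(seq_len(reps), function(r) {
      g2_statistic(g1, g2[sample.int(length(g2))]) >= obs - 1e-9
    }, TRUE))
  })
  structure(list(p = (extreme + 1) / (reps + 1), skipped = FALSE,
                 statistic = obs, n = length(g1), reps = reps),
            class = "ld_test")
}

#' Family-wise equilibrium testing with Bonferroni correction
#'
#' Runs [hwp_test()] for every (group, locus) combination, or [ld_test()]
#' for every (group, locus pair), and applies a Bonferroni correction
#' across the whole test family (skipped tests excluded).
#'
#' @param gt a [genotype_table()].
#' @param groups group labels or named list of id vectors (`NULL`: pooled).
#' @param reps,seed passed to the underlying test.
#' @param alpha family significance level for the `signif` flag.
#' @return A data frame with one row per test: `group`, locus column(s),
#'   `p_raw`, `p_bonf`, `signif`.
#' @export
hwp_tests <- function(gt, groups = NULL, reps = 999, seed = NULL,
                      alpha = 0.05) {
  gl <- as_group_list(gt, groups)
  rows <- list()
  for (g in names(gl)) {
    for (l in gt$loci) {
      t <- hwp_test(gt, l, individuals = gl[[g]], reps = reps,
                    seed = if (!is.null(seed)) derive_seed(seed, paste(g, l)))
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, locus = l, p_raw = t$p,
                   skipped = t$skipped, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- sum(!out$skipped)
  out$p_bonf <- pmin(1, out$p_raw * m)
  out$signif <- !out$skipped & out$p_bonf <= alpha
  out
}

#' @rdname hwp_tests
#' @export
ld_tests <- function(gt, groups = NULL, reps = 999, seed = NULL,
                     alpha = 0.05) {
  gl <- as_group_list(gt, groups)
  L <- length(gt$loci)
  rows <- list()
  for (g in names(gl)) {
    for (i in seq_len(L - 1)) {
      for (j in seq(i + 1, L)) {
        t <- ld_test(gt, c(i, j), individuals = gl[[g]], reps = reps,
                     seed = if (!is.null(seed))
                       derive_seed(seed, paste(g, i, j)))
        rows[[length(rows) + 1L]] <-
          data.frame(group = g, locus1 = gt$loci[i], locus2 = gt$loci[j],
                     p_raw = t$p, skipped = t$skipped,
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  m <- sum(!out$skipped)
  out$p_bonf <- pmin(1, out$p_raw * m)
  out$signif <- !out$skipped & out$p_bonf <= alpha
  out
}
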