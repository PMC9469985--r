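# Diversity, divergence, equilibrium tests, AMOVA distance, correlogram.

test_that("allele frequencies normalize and flag empty loci", {
  gt <- genotype_table(c("a", "b"), "L1", matrix(c(1L, 1L)),
                       matrix(c(1L, 2L)))
  fr <- allele_freqs(gt)
  expect_equal(unname(fr$L1), c(0.75, 0.25))
  gt2 <- genotype_table(c("a", "b"), c("L1", "L2"),
                        cbind(c(1L, 2L), c(NA, NA)),
                        cbind(c(1L, 2L), c(NA, NA)))
  fr2 <- allele_freqs(gt2)
  expect_null(fr2$L2)
  expect_identical(attr(fr2, "excluded"), "L2")
  for (s in 1:5) {
    rt <- random_grouped_table(seed = s, missing_rate = 0.2)
    sums <- vapply(Filter(Negate(is.null), allele_freqs(rt$gt)), sum, 0)
    expect_equal(unname(sums), rep(1, length(sums)), tolerance = 1e-12)
  }
})

test_that("equifrequent alleles hit the closed-form diversity values", {
  # four alleles, each at frequency 1/4
  gt <- genotype_table(paste0("i", 1:4), "L1",
                       matrix(c(1L, 3L, 1L, 2L)), matrix(c(2L, 4L, 3L, 4L)))
  ds <- diversity_summary(gt)
  expect_equal(ds$A, 4)
  expect_equal(ds$Ae, 4)
  expect_equal(ds$A95, 4)
  expect_equal(ds$He, 1 - 1 / 4)
  expect_equal(ds$FIS, 1 - ds$Ho / ds$He)
})

test_that("diversity invariants hold on random tables", {
  for (s in 1:4) {
    rt <- random_grouped_table(n_groups = 2, n_per_group = 10, n_loci = 4,
                               seed = 40 + s, missing_rate = 0.1)
    ds <- diversity_summary(rt$gt, rt$groups)
    expect_true(all(ds$Ho >= 0 & ds$Ho <= 1))
    expect_true(all(ds$He >= 0 & ds$He < 1))
    expect_true(all(ds$Ae <= ds$A + 1e-12))
    expect_true(all(ds$A95 <= ds$A))
    expect_true(all(ds$FIS <= 1))
  }
})

test_that("divergence hits the fixation and identity limits", {
  fx <- fixed_demes_table()
  expect_equal(theta_st(fx$gt, fx$groups)$overall, 1)
  expect_equal(jost_d(fx$gt, fx$groups)$overall, 1)
  # two groups that are exact copies of the same genotype multiset
  set.seed(9)
  m1 <- matrix(sample.int(4L, 24, TRUE), 6)
  m2 <- matrix(sample.int(4L, 24, TRUE), 6)
  gt <- genotype_table(paste0("i", 1:12), paste0("L", 1:4),
                       rbind(m1, m1), rbind(m2, m2))
  grp <- rep(c("g1", "g2"), each = 6)
  expect_lte(theta_st(gt, grp)$overall, 0)
  expect_equal(jost_d(gt, grp)$overall, 0)
})

test_that("estimators match the independent oracles on random instances", {
  for (s in 1:10) {
    rt <- random_grouped_table(n_groups = 2, n_per_group = 6, n_loci = 2,
                               seed = 100 + s,
                               missing_rate = ifelse(s %% 2, 0, 0.1))
    expect_equal(theta_st(rt$gt, rt$groups)$overall,
                 oracle_theta(rt$gt, rt$groups), tolerance = 1e-10)
    expect_equal(jost_d(rt$gt, rt$groups)$overall,
                 oracle_jost_d(rt$gt, rt$groups), tolerance = 1e-10)
  }
})

test_that("theta rises monotonically with simulated drift", {
  fs <- c(0.02, 0.05, 0.1, 0.2, 0.3)
  ths <- vapply(seq_along(fs), function(i) {
    s <- simulate_hierarchical(n_levels = 1, f = fs[i], n_per_deme = 50,
                               seed = 100 + i)
    theta_st(s$data$geno, s$truth$deme)$overall
  }, 0)
  expect_gte(stats::cor(fs, ths, method = "spearman"), 0.95)
})

test_that("divergence matrices are symmetric with zero diagonal", {
  rt <- random_grouped_table(n_groups = 3, n_per_group = 8, n_loci = 3,
                             seed = 77)
  for (stat in c("theta_st", "jost_d")) {
    m <- divergence_matrix(rt$gt, rt$groups, statistic = stat)
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 3))
  }
})

test_that("the AMOVA distance reproduces the codominant distance table", {
  gt <- genotype_table(c("aa", "bb", "ab", "ac", "cd"), "L1",
                       matrix(c(1L, 2L, 1L, 1L, 3L)),
                       matrix(c(1L, 2L, 2L, 3L, 4L)))
  d <- amova_distance(gt)
  expect_equal(d["aa", "aa"], 0)
  expect_equal(d["aa", "ab"], 1)   # homozygote vs het sharing one allele
  expect_equal(d["aa", "bb"], 4)   # opposite homozygotes
  expect_equal(d["aa", "cd"], 3)   # homozygote vs het sharing none
  expect_equal(d["ab", "ac"], 1)   # hets sharing one allele
  expect_equal(d["ab", "cd"], 2)   # hets sharing none
  expect_equal(d["bb", "ab"], 1)
})

test_that("AMOVA distances are symmetric, zero-diagonal, and rescale for
           missing loci", {
  for (s in 1:3) {
    rt <- random_grouped_table(n_per_group = 8, n_loci = 4, seed = 50 + s,
                               missing_rate = 0.15)
    # heavily missing fixtures may produce flagged (NA) pairs; the warning
    # is the documented behavior
    d <- suppressWarnings(amova_distance(rt$gt))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, nrow(d)))
  }
  # one locus missing for one pair: the summed distance is rescaled L/L_obs
  gt <- genotype_table(c("a", "b"), c("L1", "L2"),
                       cbind(c(1L, 2L), c(1L, NA)),
                       cbind(c(1L, 2L), c(1L, NA)))
  expect_equal(amova_distance(gt)["a", "b"], 4 * 2 / 1)
})

test_that("heterozygote excess is detected by the exact HWP test", {
  gt <- genotype_table(paste0("i", 1:20), "L1", matrix(rep(1L, 20)),
                       matrix(rep(2L, 20)))
  t <- hwp_test(gt, 1, reps = 9999, seed = 1)
  expect_lt(t$p, 0.05)
  mono <- genotype_table(paste0("i", 1:10), "L1", matrix(rep(1L, 10)),
                         matrix(rep(1L, 10)))
  expect_true(hwp_test(mono, 1)$skipped)
})

test_that("the Monte-Carlo HWP p matches exact enumeration at n = 5", {
  # five 1/2 heterozygotes: tables given allele counts (5, 5) have
  # n12 in {1, 3, 5}; p(all-het observed) = sum of prob <= p(n12 = 5)
  probs <- vapply(c(1, 3, 5), function(n12) {
    n11 <- (5 - n12) / 2
    n22 <- 5 - n11 - n12
    exp(lgamma(6) + n12 * log(2) + 2 * lgamma(6) - lgamma(11) -
          (lgamma(n11 + 1) + lgamma(n12 + 1) + lgamma(n22 + 1)))
  }, 0)
  exact <- sum(probs[probs <= probs[3] + 1e-12])
  gt <- genotype_table(paste0("i", 1:5), "L1", matrix(rep(1L, 5)),
                       matrix(rep(2L, 5)))
  mc <- hwp_test(gt, 1, reps = 19999, seed = 2)$p
  expect_equal(mc, exact, tolerance = 0.03)
})

test_that("gametic disequilibrium flags a duplicated locus", {
  set.seed(3)
  l1a <- sample.int(3L, 30, TRUE)
  l1b <- sample.int(3L, 30, TRUE)
  gt <- genotype_table(paste0("i", 1:30), c("L1", "L2"),
                       cbind(l1a, l1a), cbind(l1b, l1b))
  expect_lt(ld_test(gt, c(1, 2), reps = 999, seed = 4)$p, 0.05)
  mono <- genotype_table(paste0("i", 1:10), c("L1", "L2"),
                         cbind(rep(1L, 10), sample.int(3L, 10, TRUE)),
                         cbind(rep(1L, 10), sample.int(3L, 10, TRUE)))
  expect_true(ld_test(mono, c(1, 2))$skipped)
})

test_that("family-wise wrappers apply the Bonferroni factor", {
  rt <- random_grouped_table(n_groups = 2, n_per_group = 10, n_loci = 3,
                             seed = 8)
  hw <- hwp_tests(rt$gt, rt$groups, reps = 199, seed = 5)
  m <- sum(!hw$skipped)
  expect_equal(hw$p_bonf, pmin(1, hw$p_raw * m))
  ld <- ld_tests(rt$gt, NULL, reps = 99, seed = 6)
  expect_equal(nrow(ld), 3)  # three locus pairs, pooled group
})

test_that("a monotone genetic-geographic relation shapes the correlogram", {
  set.seed(11)
  xy <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  geo <- as.matrix(stats::dist(xy))
  gen <- sqrt(geo) + 0.01  # monotone increasing transform
  diag(gen) <- 0
  cg <- mantel_correlog(geo, gen, n_classes = 8, reps = 499, seed = 12,
                        cutoff = FALSE)
  expect_gt(cg$mantel_r[1], 0)
  expect_true(cg$signif[1])
  last <- nrow(cg)
  expect_lt(cg$mantel_r[last], 0)
  expect_true(cg$signif[last])
  # progressive correction is p * k by definition
  expect_equal(cg$p_corr, pmin(1, cg$p_raw * seq_len(nrow(cg))))
})

test_that("per-class Mantel r matches vegan's mantel on the model matrix", {
  set.seed(13)
  xy <- cbind(runif(25, 0, 100), runif(25, 0, 100))
  geo <- as.matrix(stats::dist(xy))
  gen <- as.matrix(stats::dist(matrix(rnorm(75), 25)))
  n_classes <- 8
  ours <- mantel_correlog(geo, gen, n_classes = n_classes, reps = 9,
                          seed = 1, cutoff = FALSE)
  breaks <- seq(0, max(geo), length.out = n_classes + 1)
  for (row in c(1, nrow(ours))) {
    k <- ours$class[row]
    inside <- geo > breaks[k] & geo <= breaks[k + 1]
    model <- 1 - inside  # within-class pairs coded 0, Legendre convention
    diag(model) <- 0
    veg <- vegan::mantel(stats::as.dist(gen), stats::as.dist(model),
                         permutations = 0)
    expect_equal(ours$mantel_r[row], unname(veg$statistic),
                 tolerance = 1e-10)
  }
})

test_that("the all-points cutoff restricts the tested classes", {
  set.seed(14)
  xy <- rbind(cbind(rnorm(10, 0, 1), rnorm(10, 0, 1)),
              cbind(rnorm(10, 500, 1), rnorm(10, 500, 1)))
  geo <- as.matrix(stats::dist(xy))
  gen <- as.matrix(stats::dist(matrix(rnorm(60), 20)))
  full <- mantel_correlog(geo, gen, n_classes = 20, reps = 9, seed = 1,
                          cutoff = FALSE)
  cut <- mantel_correlog(geo, gen, n_classes = 20, reps = 9, seed = 1)
  expect_lt(attr(cut, "n_tested"), attr(full, "n_tested"))
  expect_true(all(cut$class <= attr(cut, "n_tested")))
})
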