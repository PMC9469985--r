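# Synthetic-data generators.

test_that("identical configurations reproduce identical datasets", {
  s1 <- simulate_hierarchical(n_levels = 1, n_per_deme = 10, n_loci = 4,
                              seed = 5)
  s2 <- simulate_hierarchical(n_levels = 1, n_per_deme = 10, n_loci = 4,
                              seed = 5)
  expect_identical(s1, s2)
  t1 <- simulate_stepping_stone(nx = 3, ny = 2, generations = 20,
                                samples_per_deme = 4, seed = 6)
  t2 <- simulate_stepping_stone(nx = 3, ny = 2, generations = 20,
                                samples_per_deme = 4, seed = 6)
  expect_identical(t1, t2)
})

test_that("truth labels follow the bifurcation nomenclature", {
  s <- simulate_hierarchical(n_levels = 2, n_per_deme = 3, n_loci = 2,
                             seed = 7)
  expect_setequal(unique(s$truth$deme), c("1a", "1b", "2a", "2b"))
  expect_setequal(unique(s$truth$level1), c("1", "2"))
  expect_identical(s$truth$level2, s$truth$deme)
  # spatial nesting: level-1 groups separate along x
  x1 <- s$data$coords[s$truth$level1 == "1", 1]
  x2 <- s$data$coords[s$truth$level1 == "2", 1]
  expect_lt(max(x1), min(x2))
})

test_that("vanishing drift leaves demes undifferentiated", {
  s <- simulate_hierarchical(n_levels = 1, f = 0.004, n_per_deme = 100,
                             n_loci = 15, seed = 3)
  expect_lte(theta_st(s$data$geno, s$truth$deme)$overall, 0.01)
})

test_that("strong drift separates demes for the admixture model", {
  s <- simulate_hierarchical(n_levels = 1, f = 0.3, n_per_deme = 50,
                             seed = 4)
  expect_gt(theta_st(s$data$geno, s$truth$deme)$overall, 0.1)
  fit <- fit_admixture(s$data$geno, 2, seed = 9)
  lab <- apply(fit$Q, 1, which.max)
  expect_gte(adjusted_rand_index(lab, s$truth$deme), 0.9)
})

test_that("missing data respects the requested rate", {
  s <- simulate_hierarchical(n_levels = 1, n_per_deme = 50, n_loci = 10,
                             missing_rate = 0.1, seed = 8)
  expect_equal(mean(is.na(s$data$geno$a1)), 0.1, tolerance = 0.03)
})

test_that("stepping-stone divergence grows with lattice separation", {
  ss <- simulate_stepping_stone(seed = 21)
  tr <- ss$truth
  demes <- split(tr$id, tr$deme)
  pos <- cbind(vapply(split(tr$ix, tr$deme), `[`, numeric(1), 1),
               vapply(split(tr$iy, tr$deme), `[`, numeric(1), 1))
  set.seed(1)
  pairs <- t(utils::combn(length(demes), 2))
  pairs <- pairs[sample(nrow(pairs), 50), ]
  sep <- numeric(0)
  th <- numeric(0)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    sep <- c(sep, sqrt(sum((pos[i, ] - pos[j, ])^2)))
    th <- c(th, theta_st(ss$data$geno,
                         stats::setNames(demes[c(i, j)],
                                         c("a", "b")))$overall)
  }
  expect_gte(stats::cor(sep, th, method = "spearman"), 0.8)
})

test_that("dense mixing erases short-range autocorrelation", {
  # weak drift (large demes) plus maximal neighbor exchange approaches
  # panmixia, so the within-deme class carries no detectable excess
  ss <- simulate_stepping_stone(m = 0.5, deme_size = 1000,
                                generations = 400, seed = 21)
  gd <- amova_distance(ss$data$geno)
  geo <- as.matrix(stats::dist(ss$data$coords))
  cg <- mantel_correlog(geo, gd, n_classes = 40, reps = 199, seed = 4,
                        cutoff = FALSE)
  expect_false(cg$signif[1] && cg$mantel_r[1] > 0)
})

test_that("invalid generator configurations are rejected", {
  expect_error(simulate_hierarchical(n_levels = 1, f = 1.2), "drift")
  expect_error(simulate_hierarchical(n_levels = 11), "depth")
  expect_error(simulate_stepping_stone(nx = 1, ny = 1), "lattice")
  expect_error(simulate_stepping_stone(deme_size = 1), "deme_size")
  expect_error(simulate_stepping_stone(m = 0.9), "m")
})
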