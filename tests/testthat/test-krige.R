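# Thin-plate-spline membership surfaces and isocline selection.

test_that("constant fields are reproduced everywhere", {
  set.seed(1)
  xy <- cbind(runif(25, 0, 100), runif(25, 0, 100))
  s <- fit_surface(xy, rep(0.4, 25))
  probe <- cbind(runif(40, -10, 110), runif(40, -10, 110))
  expect_equal(predict(s, probe), rep(0.4, 40), tolerance = 1e-10)
})

test_that("zero smoothing interpolates the data exactly", {
  set.seed(2)
  xy <- cbind(runif(30, 0, 50), runif(30, 0, 50))
  v <- runif(30)
  s <- fit_surface(xy, v, lambda = 0)
  expect_equal(predict(s, xy, clip = FALSE), v, tolerance = 1e-8)
})

test_that("affine fields are recovered exactly under GCV smoothing", {
  set.seed(3)
  xy <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  v <- 0.2 + 0.003 * xy[, 1] + 0.002 * xy[, 2]
  s <- fit_surface(xy, v)
  probe <- cbind(runif(50, 5, 95), runif(50, 5, 95))
  expect_equal(predict(s, probe, clip = FALSE),
               0.2 + 0.003 * probe[, 1] + 0.002 * probe[, 2],
               tolerance = 1e-6)
})

test_that("complementary membership columns give complementary surfaces", {
  set.seed(4)
  xy <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  v <- runif(40)
  s1 <- fit_surface(xy, v)
  s2 <- fit_surface(xy, 1 - v)
  probe <- cbind(runif(60, 0, 100), runif(60, 0, 100))
  tot <- predict(s1, probe, clip = FALSE) + predict(s2, probe, clip = FALSE)
  expect_true(max(abs(tot - 1)) < 2e-2)
})

test_that("the export grid matches pointwise evaluation and covers data", {
  set.seed(5)
  xy <- cbind(runif(15, 0, 10), runif(15, 0, 10))
  s <- fit_surface(xy, runif(15))
  g <- surface_grid(s, n = 21)
  expect_true(min(g$x) <= min(xy[, 1]) && max(g$x) >= max(xy[, 1]))
  pts <- cbind(rep(g$x, times = 21), rep(g$y, each = 21))
  expect_equal(as.vector(g$z), predict(s, pts))
  expect_true(all(g$z >= 0 & g$z <= 1))
})

test_that("degenerate geometry is rejected with advice", {
  xy <- cbind(1:5, 2 * (1:5) + 3)
  expect_error(fit_surface(xy, runif(5)), "collinear")
})

test_that("isocline selection retains boundary values and is disjoint", {
  set.seed(6)
  xy <- cbind(runif(12, 0, 10), runif(12, 0, 10))
  # constant surfaces evaluate exactly, pinning the >= boundary semantics
  s70 <- fit_surface(xy, rep(0.70, 12))
  s30 <- fit_surface(xy, rep(0.30, 12))
  sel <- select_by_isocline(list(s70, s30), xy, threshold = 0.70,
                            ids = paste0("i", 1:12))
  expect_identical(sel$retained[[1]], paste0("i", 1:12))
  expect_identical(sel$retained[[2]], character(0))
  s5a <- fit_surface(xy, rep(0.5, 12))
  sel2 <- select_by_isocline(list(s5a, s5a), xy, threshold = 0.70)
  expect_true(all(lengths(sel2$retained) == 0))
  expect_warning(select_by_isocline(list(s70, s30), xy, threshold = 0.4),
                 "overlap")
})

test_that("a two-blob membership field partitions the blobs", {
  set.seed(7)
  blobA <- cbind(rnorm(25, 0, 5), rnorm(25, 0, 5))
  blobB <- cbind(rnorm(25, 200, 5), rnorm(25, 0, 5))
  xy <- rbind(blobA, blobB)
  v1 <- c(rep(0.9, 25), rep(0.1, 25))
  s1 <- fit_surface(xy, v1)
  s2 <- fit_surface(xy, 1 - v1)
  sel <- select_by_isocline(list(s1, s2), xy, threshold = 0.70,
                            ids = c(paste0("A", 1:25), paste0("B", 1:25)))
  expect_identical(sel$retained[[1]], paste0("A", 1:25))
  expect_identical(sel$retained[[2]], paste0("B", 1:25))
})

test_that("raising the threshold never grows a retained set", {
  set.seed(8)
  xy <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  v <- pmin(1, pmax(0, 0.5 + 0.4 * sin(xy[, 1] / 15)))
  s1 <- fit_surface(xy, v)
  s2 <- fit_surface(xy, 1 - v)
  prev1 <- prev2 <- NULL
  for (th in c(0.55, 0.65, 0.75, 0.85)) {
    sel <- suppressWarnings(select_by_isocline(list(s1, s2), xy, th))
    if (!is.null(prev1)) {
      expect_true(all(sel$retained[[1]] %in% prev1))
      expect_true(all(sel$retained[[2]] %in% prev2))
    }
    prev1 <- sel$retained[[1]]
    prev2 <- sel$retained[[2]]
  }
})
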