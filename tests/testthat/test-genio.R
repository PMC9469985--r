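# Genotype container and format I/O.

make_random_table <- function(seed, n = 12, L = 5, missing_rate = 0.1) {
  set.seed(seed)
  a1 <- matrix(sample.int(9L, n * L, TRUE), n, L)
  a2 <- matrix(sample.int(9L, n * L, TRUE), n, L)
  drop <- matrix(runif(n * L) < missing_rate, n, L)
  for (l in seq_len(L)) if (all(drop[, l])) drop[1, l] <- FALSE
  a1[drop] <- NA_integer_
  a2[drop] <- NA_integer_
  # GENEPOP stores groups as contiguous POP blocks, so fixtures keep group
  # members adjacent
  genotype_table(paste0("ind", seq_len(n)), paste0("loc", seq_len(L)),
                 a1, a2,
                 group = paste0("pop", rep(1:2, c(n %/% 2, n - n %/% 2))))
}

test_that("genotype_table enforces its invariants", {
  expect_error(genotype_table(c("a", "a"), "L1", matrix(1:2), matrix(1:2)),
               "duplicate")
  expect_error(genotype_table(c("a", "b"), "L1", matrix(c(1L, NA)),
                              matrix(c(1L, 2L))), "half-missing")
  expect_error(genotype_table("a", "L1", matrix(0L), matrix(1L)),
               "positive")
  # calls are stored as unordered pairs (canonical order)
  gt <- genotype_table(c("a", "b"), "L1", matrix(c(3L, 1L)),
                       matrix(c(1L, 3L)))
  expect_identical(unname(gt$a1[, 1]), c(1L, 1L))
  expect_identical(unname(gt$a2[, 1]), c(3L, 3L))
})

test_that("GENEPOP parsing decodes alleles and missing codes", {
  f <- withr::local_tempfile()
  writeLines(c("demo title", "locA", "locB", "POP",
               "ind1 , 0101 0202",
               "ind2 , 0000 0102   ",
               "", "POP", "ind3 , 0304 0505"), f)
  gt <- read_genepop(f)
  expect_identical(gt$ids, c("ind1", "ind2", "ind3"))
  expect_identical(unname(gt$a1[1, ]), c(1L, 2L))
  expect_identical(unname(gt$a2[1, ]), c(1L, 2L))
  expect_true(is.na(gt$a1[2, 1]) && is.na(gt$a2[2, 1]))
  expect_identical(unname(c(gt$a1[2, 2], gt$a2[2, 2])), c(1L, 2L))
  expect_identical(gt$group, c("pop1", "pop1", "pop2"))
})

test_that("GENEPOP errors name the offending line", {
  f <- withr::local_tempfile()
  writeLines(c("t", "locA", "locB", "POP", "ind1 , 0101"), f)
  expect_error(read_genepop(f), "line 5.*ragged")
  writeLines(c("t", "locA", "POP", "ind1 , 010"), f)
  expect_error(read_genepop(f), "unknown allele encoding")
})

test_that("write_genepop produces stable block structure", {
  gt <- genotype_table("i1", "L1", matrix(1L), matrix(1L))
  f <- withr::local_tempfile()
  write_genepop(gt, f, title = "t")
  expect_length(readLines(f), 4L)  # title, locus, POP, one individual
  gt2 <- make_random_table(1, n = 5)
  gt2$group <- rep(c("A", "B"), c(2, 3))
  write_genepop(gt2, f)
  lines <- readLines(f)
  expect_identical(sum(lines == "POP"), 2L)
  big <- genotype_table("i1", "L1", matrix(1000L), matrix(1000L))
  expect_error(write_genepop(big, f), "3-digit")
})

test_that("GENEPOP round-trips randomized tables including missing data", {
  for (s in 1:5) {
    gt <- make_random_table(s)
    f <- withr::local_tempfile()
    write_genepop(gt, f)
    gt2 <- read_genepop(f)
    expect_true(isTRUE(all.equal(gt, gt2)))
    # byte-stable output
    f2 <- withr::local_tempfile()
    write_genepop(gt2, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("STRUCTURE two-row layout reads rows as allele copies", {
  f <- withr::local_tempfile()
  writeLines(c("loc1 loc2", "ind1 1 2", "ind1 1 3"), f)
  gt <- read_structure(f)
  expect_identical(unname(cbind(gt$a1, gt$a2)[1, ]), c(1L, 2L, 1L, 3L))
  writeLines(c("loc1", "ind1 -9", "ind1 -9"), f)
  expect_true(is.na(read_structure(f)$a1[1, 1]))
  writeLines(c("loc1", "ind1 1", "ind1 1", "ind2 2"), f)
  expect_error(read_structure(f), "even number of data rows")
})

test_that("STRUCTURE layouts round-trip", {
  for (s in 1:3) {
    gt <- make_random_table(s)
    gt$group <- NULL
    f <- withr::local_tempfile()
    write_structure(gt, f)
    expect_true(isTRUE(all.equal(gt, read_structure(f))))
    write_structure(gt, f, one_row_per_individual = TRUE)
    expect_true(isTRUE(all.equal(
      gt, read_structure(f, one_row_per_individual = TRUE))))
  }
  f <- withr::local_tempfile()
  writeLines(c("loc1", "ind1 1 2 3"), f)
  expect_error(read_structure(f, one_row_per_individual = TRUE),
               "even number of allele columns")
})

test_that("CSV genotype and coordinate tables round-trip", {
  gt <- make_random_table(4)
  f <- withr::local_tempfile()
  write_genotype_csv(gt, f)
  expect_true(isTRUE(all.equal(gt, read_genotype_csv(f))))
})

test_that("attach_coords joins, reports extras, and enforces policy", {
  gt <- make_random_table(2, n = 4)
  geo <- geo_table(c(gt$ids, "stray"), x = c(1, 2, 3, 4, 9),
                   y = c(0, 0, 1, 1, 9))
  expect_message(sp <- attach_coords(gt, geo), "ignoring 1")
  expect_identical(nrow(sp$coords), 4L)
  expect_identical(rownames(sp$coords), gt$ids)
  geo2 <- geo_table(gt$ids[-2], x = c(1, 3, 4), y = c(0, 1, 1))
  expect_error(attach_coords(gt, geo2), "ind2")
  expect_message(sp2 <- attach_coords(gt, geo2, policy = "drop"),
                 "dropping 1")
  expect_identical(n_ind(sp2$geno), 3L)
})

test_that("lon/lat input is projected to a sane planar km frame", {
  gt <- make_random_table(3, n = 3)
  # ~1 degree of latitude apart at mid-latitudes: about 111 km
  geo <- geo_table(gt$ids, x = c(-110, -110, -109), y = c(44, 45, 44),
                   mode = "lonlat")
  sp <- attach_coords(gt, geo)
  d_lat <- sqrt(sum((sp$coords[2, ] - sp$coords[1, ])^2))
  expect_true(abs(d_lat - 111.2) < 1.5)
  d_lon <- sqrt(sum((sp$coords[3, ] - sp$coords[1, ])^2))
  expect_true(abs(d_lon - 111.2 * cos(44 * pi / 180)) < 1.5)
})
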