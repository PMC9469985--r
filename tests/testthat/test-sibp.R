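# The spatial iterative bifurcation process.

test_that("child names alternate the 1|2 and a|b tokens", {
  expect_identical(name_children(""), c("1", "2"))
  expect_identical(name_children("1"), c("1a", "1b"))
  expect_identical(name_children("2"), c("2a", "2b"))
  expect_identical(name_children("1b"), c("1b1", "1b2"))
  expect_identical(name_children("1b2b1"), c("1b2b1a", "1b2b1b"))
  expect_error(name_children("3"), "malformed")
  expect_error(name_children("a1"), "malformed")
  expect_error(name_children("11"), "malformed")
})

test_that("bifurcating two well-separated demes recovers them", {
  sim <- simulate_hierarchical(n_levels = 1, f = 0.25, n_per_deme = 30,
                               n_loci = 10, seed = 31)
  b <- bifurcate_once(sim$data, replicates = 5, seed = 3)
  got <- c(b$groups[[1]], b$groups[[2]])
  lab <- rep(1:2, lengths(b$groups))
  truth <- sim$truth$deme[match(got, sim$truth$id)]
  expect_gte(length(got), 50)
  expect_gte(adjusted_rand_index(lab, truth), 0.9)
  # re-bifurcating one retained group keeps its subsets nested inside it
  g1 <- b$groups[[1]]
  b2 <- bifurcate_once(sim$data[g1], replicates = 5, seed = 3, node = "1")
  expect_true(all(unlist(b2$groups) %in% g1))
})

test_that("the tree nests strictly and partitions the sample", {
  sim <- simulate_hierarchical(n_levels = 2, f = 0.25, n_per_deme = 20,
                               n_loci = 10, seed = 17)
  res <- run_sibp(sim$data, replicates = 5, seed = 7)
  check_nesting <- function(node) {
    for (ch in node$children) {
      expect_true(all(ch$members %in% node$members))
      expect_lte(length(ch$members), length(node$members))
      check_nesting(ch)
    }
    if (length(node$children) == 2) {
      kids <- lapply(node$children, `[[`, "members")
      expect_length(intersect(kids[[1]], kids[[2]]), 0)
    }
  }
  check_nesting(res$tree)
  cen <- sibp_centers(res)
  expect_false(any(duplicated(cen$id)))
  expect_setequal(c(cen$id, res$unassigned), sim$data$geno$ids)
  att <- sibp_attrition(res)
  expect_true(all(att$cut_pct >= 0 & att$cut_pct <= 100))
})

test_that("reruns with the same seed reproduce the identical tree", {
  sim <- simulate_hierarchical(n_levels = 1, f = 0.25, n_per_deme = 20,
                               n_loci = 8, seed = 23)
  r1 <- run_sibp(sim$data, replicates = 4, seed = 5)
  r2 <- run_sibp(sim$data, replicates = 4, seed = 5)
  expect_identical(as.character(sibp_tree_json(r1)),
                   as.character(sibp_tree_json(r2)))
  expect_identical(r1$centers, r2$centers)
})

test_that("serializations reflect the tree topology", {
  sim <- simulate_hierarchical(n_levels = 1, f = 0.3, n_per_deme = 15,
                               n_loci = 8, seed = 29)
  res <- run_sibp(sim$data, replicates = 4, seed = 9)
  nwk <- sibp_tree_newick(res)
  expect_match(nwk, ";$")
  expect_match(nwk, "root_n30")
  js <- jsonlite::fromJSON(sibp_tree_json(res), simplifyVector = FALSE)
  expect_identical(js$name, "root")
  expect_identical(js$n, 30L)
})

test_that("configuration bounds are enforced", {
  sim <- simulate_hierarchical(n_levels = 0, n_per_deme = 12, n_loci = 4,
                               seed = 2)
  expect_error(run_sibp(sim$data, threshold = 0.4), "threshold")
  expect_error(run_sibp(sim$data, min_group = 1), "min_group")
})
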