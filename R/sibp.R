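# Spatial iterative bifurcation process: recursively (1) cluster the sample
# at K = 2, (2) krige the averaged membership of each cluster over space,
# (3) retain the individuals inside each cluster's >= threshold isocline,
# and recurse into the two retained groups.  Terminal retained groups are
# the subpopulation centers; nodes are named with the alternating 1|2 / a|b
# binary nomenclature.

#' Child names under the alternating binary nomenclature
#'
#' The root (`""`) splits into `"1"`/`"2"`; a name ending in a digit token
#' appends `"a"`/`"b"`; a name ending in a letter token appends `"1"`/`"2"`.
#'
#' @param parent_name parent label (`""` for the root); must alternate
#'   digit (`1`/`2`) and letter (`a`/`b`) tokens starting with a digit.
#' @return Character vector of the two child labels.
#' @export
#' @examples
#' name_children("")      # "1"  "2"
#' name_children("1")     # "1a" "1b"
#' name_children("1b2b1") # "1b2b1a" "1b2b1b"
name_children <- function(parent_name) {
  if (!is.character(parent_name) || length(parent_name) != 1 ||
      !grepl("^$|^[12]([ab][12])*[ab]?$", parent_name)) {
    stop("malformed node name: ", deparse(parent_name))
  }
  last <- substr(parent_name, nchar(parent_name), nchar(parent_name))
  if (last %in% c("", "a", "b")) {
    paste0(parent_name, c("1", "2"))
  } else {
    paste0(parent_name, c("a", "b"))
  }
}

#' One bifurcation round: cluster, krige, select
#'
#' Runs seeded replicate admixture fits at K = 2, aligns and averages them,
#' fits one membership surface per cluster, and retains the individuals
#' inside each cluster's `>= threshold` isocline.
#'
#' @param x a [spatial_genotypes()] object.
#' @param threshold isocline level (default 0.70).
#' @param replicates admixture replicates (default 10).
#' @param seed integer seed; all stochastic steps derive from it.
#' @param node node label used in seed derivation (default `""`, the root).
#' @param max_iter,tol EM controls passed to [fit_admixture()].
#' @param align_repeats passed to [align_replicates()].
#' @return A list of class `bifurcation`: `groups` (two id vectors, either
#'   possibly empty), `Q` (aligned mean memberships), `G`, `surfaces`,
#'   `selection`.
#' @export
bifurcate_once <- function(x, threshold = 0.70, replicates = 10, seed = 1,
                           node = "", max_iter = 500, tol = 1e-6,
                           align_repeats = 1000) {
  stopifnot(inherits(x, "spatial_genotypes"))
  reps <- run_admixture_replicates(
    x$geno, K = 2, replicates = replicates,
    seed = derive_seed(seed, paste0("node:", node)),
    align_repeats = align_repeats, cross_fit = TRUE,
    max_iter = max_iter, tol = tol)
  Q <- reps$Q_mean
  surfaces <- lapply(1:2, function(k) {
    fit_surface(x$coords, Q[, k],
                seed = derive_seed(seed, paste0("jitter:", node, ":", k)))
  })
  sel <- select_by_isocline(surfaces, x$coords, threshold = threshold,
                            ids = x$geno$ids)
  groups <- sel$retained
  # Degenerate division: when every sample's interpolated membership leans
  # toward the same cluster (no sample holds majority membership in the
  # other), nothing was actually bifurcated -- the field is a level shift
  # from an unbalanced division, not an isocline partition -- so neither
  # cluster retains anyone.  A genuine one-sided outcome (a real minority
  # region that never reaches the threshold) still has majority samples on
  # both sides and is unaffected.
  degenerate <- any(apply(sel$values, 2, min) > 0.5)
  if (degenerate) groups <- list(character(0), character(0))
  structure(list(groups = groups, Q = Q, G = reps$G,
                 surfaces = surfaces, selection = sel,
                 degenerate = degenerate, node = node),
            class = "bifurcation")
}

#' Run the spatial iterative bifurcation process
#'
#' Depth-first recursion of [bifurcate_once()].  A branch stops when its
#' bifurcation retains no individuals in either cluster, when a retained
#' group is smaller than `min_group`, or at `max_depth`.  A node whose own
#' bifurcation terminates the branch is reported as a subpopulation center;
#' when exactly one child retains individuals, the node is also reported as
#' a center holding its retained members not claimed by deeper centers.
#' Child seeds are derived from `seed` and the node name, so subtree results
#' do not depend on sibling execution order.
#'
#' @inheritParams bifurcate_once
#' @param min_group smallest group eligible for further bifurcation
#'   (default 10).
#' @param max_depth recursion cap (default 8).
#' @return An object of class `sibp_result`: `tree` (nested node list),
#'   `centers` (data frame id/center), `unassigned` (id vector), `rounds`
#'   (per-round attrition report), and the configuration used.
#' @export
run_sibp <- function(x, threshold = 0.70, replicates = 10, min_group = 10,
                     max_depth = 8, seed = 1, max_iter = 500, tol = 1e-6,
                     align_repeats = 1000) {
  stopifnot(inherits(x, "spatial_genotypes"))
  if (n_ind(x$geno) == 0) stop("empty dataset")
  if (threshold <= 0.5 || threshold >= 1) {
    stop("`threshold` must lie in (0.5, 1)")
  }
  if (min_group < 2) stop("`min_group` must be >= 2")
  centers <- list()
  round_rows <- list()

  build <- function(name, members, depth) {
    node <- list(name = if (nzchar(name)) name else "root",
                 label = name, members = members, depth = depth,
                 n = length(members), children = list(), is_center = FALSE)
    if (length(members) < min_group || depth >= max_depth) {
      node$is_center <- TRUE
      node$stopped <- if (length(members) < min_group) "min_group" else "max_depth"
      centers[[length(centers) + 1L]] <<- list(name = node$name,
                                               members = members)
      return(node)
    }
    b <- bifurcate_once(x[members], threshold = threshold,
                        replicates = replicates, seed = seed, node = name,
                        max_iter = max_iter, tol = tol,
                        align_repeats = align_repeats)
    kid_names <- name_children(name)
    retained <- b$groups
    n_ret <- sum(lengths(retained))
    node$G <- b$G
    node$cut_pct <- 100 * (length(members) - n_ret) / length(members)
    round_rows[[length(round_rows) + 1L]] <<- data.frame(
      node = node$name, round = depth + 1L, n_start = length(members),
      n_retained = n_ret, cut_pct = node$cut_pct)
    # a retained group below min_group is not bifurcated further and is too
    # small to stand as a center; its members fall back to the parent
    eligible <- lengths(retained) >= min_group
    if (!any(eligible)) {
      node$is_center <- TRUE
      node$stopped <- if (all(lengths(retained) == 0)) "no_retention"
        else "fragments_below_min_group"
      centers[[length(centers) + 1L]] <<- list(name = node$name,
                                               members = members)
      return(node)
    }
    for (k in 1:2) {
      if (!eligible[k]) next
      node$children[[kid_names[k]]] <-
        build(kid_names[k], retained[[k]], depth + 1L)
    }
    if (sum(eligible) == 1) {
      # one cluster died at the isocline: the node itself is a center for
      # its members not claimed by deeper centers (if enough of them remain)
      claimed <- unlist(lapply(centers, `[[`, "members"), use.names = FALSE)
      rest <- setdiff(members, claimed)
      if (length(rest) >= min_group) {
        node$is_center <- TRUE
        node$stopped <- "one_sided"
        centers[[length(centers) + 1L]] <<- list(name = node$name,
                                                 members = rest)
      }
    }
    node
  }

  tree <- build("", x$geno$ids, 0L)
  cdf <- do.call(rbind, lapply(centers, function(cc) {
    if (length(cc$members) == 0) return(NULL)
    data.frame(id = cc$members, center = cc$name, stringsAsFactors = FALSE)
  }))
  cdf <- cdf[order(match(cdf$id, x$geno$ids)), , drop = FALSE]
  rownames(cdf) <- NULL
  rounds <- if (length(round_rows)) do.call(rbind, round_rows) else
    data.frame(node = character(), round = integer(), n_start = integer(),
               n_retained = integer(), cut_pct = numeric())
  structure(list(tree = tree, centers = cdf,
                 unassigned = setdiff(x$geno$ids, cdf$id),
                 rounds = rounds,
                 config = list(threshold = threshold, replicates = replicates,
                               min_group = min_group, max_depth = max_depth,
                               seed = seed)),
            class = "sibp_result")
}

#' @export
print.sibp_result <- function(x, ...) {
  ncen <- length(unique(x$centers$center))
  cat("<sibp_result> ", ncen, " subpopulation center(s); ",
      nrow(x$centers), " assigned, ", length(x$unassigned),
      " outside all centers\n", sep = "")
  show <- function(node, indent) {
    cat(indent, node$name, " (n=", node$n, ")",
        if (node$is_center) " *center*", "\n", sep = "")
    for (ch in node$children) show(ch, paste0(indent, "  "))
  }
  show(x$tree, "")
  invisible(x)
}

#' Subpopulation-center assignments
#'
#' @param x a [run_sibp()] result.
#' @return Data frame with columns `id` and `center`.
#' @export
sibp_centers <- function(x) {
  stopifnot(inherits(x, "sibp_result"))
  x$centers
}

#' Per-round attrition of the bifurcation process
#'
#' For each round (recursion depth), the percentage of that round's
#' starting samples dropped at the isoclines.
#'
#' @param x a [run_sibp()] result.
#' @return Data frame with one row per round: `round`, `n_start`,
#'   `n_retained`, `cut_pct`.
#' @export
sibp_attrition <- function(x) {
  stopifnot(inherits(x, "sibp_result"))
  r <- x$rounds
  if (nrow(r) == 0) return(data.frame(round = integer(), n_start = integer(),
                                      n_retained = integer(),
                                      cut_pct = numeric()))
  agg <- do.call(rbind, lapply(split(r, r$round), function(d) {
    data.frame(round = d$round[1], n_start = sum(d$n_start),
               n_retained = sum(d$n_retained))
  }))
  agg$cut_pct <- 100 * (agg$n_start - agg$n_retained) / agg$n_start
  rownames(agg) <- NULL
  agg
}

#' Serialize a bifurcation tree
#'
#' `sibp_tree_json()` writes the nested node structure (names, sizes,
#' member lists, centers) as JSON; `sibp_tree_newick()` renders the tree
#' topology as a Newick string with node sizes as comments-free labels.
#'
#' @param x a [run_sibp()] result.
#' @param path optional output path; when `NULL` the string is returned.
#' @return JSON or Newick text (invisibly when written to `path`).
#' @export
sibp_tree_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "sibp_result"))
  strip <- function(node) {
    list(name = node$name, n = node$n, is_center = node$is_center,
         members = node$members,
         children = lapply(unname(node$children), strip))
  }
  js <- jsonlite::toJSON(strip(x$tree), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname sibp_tree_json
#' @export
sibp_tree_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "sibp_result"))
  rec <- function(node) {
    lab <- paste0(node$name, "_n", node$n)
    if (length(node$children) == 0) return(lab)
    paste0("(", paste(vapply(node$children, rec, ""), collapse = ","), ")",
           lab)
  }
  nwk <- paste0(rec(x$tree), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
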