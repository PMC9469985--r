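# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded package internals never disturb the user's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed from (root seed, text tag); keeps subtree results
# independent of sibling execution order.  Stays below 2^31 - 1.
derive_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(paste0("#", as.character(tag)))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

# All permutations of 1..k as a list of integer vectors (k small).
all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- as.integer(append(sub, k, after = pos - 1L))
    }
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same individuals;
#' 1 means identical partitions, 0 is the expectation under independence.
#'
#' @param x,y vectors of group labels of equal length.
#' @return A single numeric value.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (isTRUE(all.equal(max_index, expected))) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Normalise a group specification (factor/vector aligned with individuals, or
# named list of id vectors) into a named list of individual-id character
# vectors, in stable order of first appearance.
as_group_list <- function(x, groups) {
  ids <- x$ids
  if (is.null(groups)) return(list(all = ids))
  if (is.list(groups)) {
    gl <- lapply(groups, as.character)
    if (is.null(names(gl)) || any(!nzchar(names(gl)))) {
      names(gl) <- paste0("group", seq_along(gl))
    }
    bad <- setdiff(unlist(gl), ids)
    if (length(bad) > 0) {
      stop("group members not in genotype table: ", paste(bad, collapse = ", "))
    }
    return(gl)
  }
  groups <- as.character(groups)
  if (length(groups) != length(ids)) {
    stop("`groups` must have one label per individual")
  }
  split(ids, factor(groups, levels = unique(groups)))
}
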