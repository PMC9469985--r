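# Label alignment across replicate membership matrices (the label-switching
# problem): find one column permutation per replicate maximizing the mean
# pairwise similarity statistic G, then average the aligned matrices.

#' Pairwise similarity G between two membership matrices
#'
#' `G = 1 - ||Q1 - Q2||_F / sqrt(2 n)`, which is 1 for identical matrices
#' and 0 at the maximum possible Frobenius distance between row-stochastic
#' matrices.
#'
#' @param Q1,Q2 `n x K` membership matrices.
#' @return A value in `[0, 1]`.
#' @export
g_similarity <- function(Q1, Q2) {
  stopifnot(all(dim(Q1) == dim(Q2)))
  1 - sqrt(sum((Q1 - Q2)^2)) / sqrt(2 * nrow(Q1))
}

#' Align replicate membership matrices
#'
#' Searches for column permutations (one per replicate, the first held at
#' identity since a global relabeling is immaterial) maximizing the mean
#' pairwise G.  When the joint search space `K!^(R-1)` is small
#' (<= `exhaustive_limit`) the optimum is found exactly; otherwise a greedy
#' pass against the running mean is repeated over `repeats` seeded random
#' replicate orders and the best alignment kept.  For `K = 2` the per-step
#' choice is always exhaustive (2 permutations).
#'
#' @param reps list of `n x K` membership matrices or `admixture_fit`
#'   objects, all of the same shape.
#' @param repeats greedy restarts (default 1000).
#' @param seed integer seed for the greedy restart orders.
#' @param exhaustive_limit maximum joint-search size enumerated exactly.
#' @return An object of class `replicate_alignment`: `perms` (list of
#'   permutations applied to each replicate's columns), `G` (mean pairwise
#'   similarity after alignment), `Q_mean` (row-renormalized mean of the
#'   aligned matrices), and `method`.
#' @export
align_replicates <- function(reps, repeats = 1000, seed = NULL,
                             exhaustive_limit = 5000) {
  Qs <- lapply(reps, function(r) if (inherits(r, "admixture_fit")) r$Q else r)
  R <- length(Qs)
  if (R == 0) stop("no replicates to align")
  d <- dim(Qs[[1]])
  if (!all(vapply(Qs, function(q) all(dim(q) == d), TRUE))) {
    stop("replicate membership matrices differ in shape")
  }
  K <- d[2]
  n <- d[1]
  finish <- function(perms, method) {
    aligned <- Map(function(Q, p) Q[, p, drop = FALSE], Qs, perms)
    M <- Reduce(`+`, aligned)
    Q_mean <- M / rowSums(M)
    dimnames(Q_mean) <- dimnames(Qs[[1]])
    G <- if (R == 1) 1 else {
      tot <- 0
      for (i in seq_len(R - 1)) {
        for (j in seq(i + 1, R)) tot <- tot + g_similarity(aligned[[i]], aligned[[j]])
      }
      tot / (R * (R - 1) / 2)
    }
    structure(list(perms = perms, G = G, Q_mean = Q_mean, method = method),
              class = "replicate_alignment")
  }
  if (R == 1 || K == 1) {
    return(finish(rep(list(seq_len(K)), R), "trivial"))
  }
  perms <- all_perms(K)
  perms <- perms[order(vapply(perms, function(p) {
    paste(sprintf("%03d", p), collapse = ",")
  }, ""))]  # identity first, so the reference replicate keeps its labels
  nP <- length(perms)
  if (nP^(R - 1) <= exhaustive_limit) {
    # exact joint optimum via pairwise G lookup tables
    tab <- vector("list", R * R)
    for (i in seq_len(R - 1)) {
      for (j in seq(i + 1, R)) {
        m <- matrix(0, nP, nP)
        for (a in seq_len(nP)) {
          for (b in seq_len(nP)) {
            m[a, b] <- g_similarity(Qs[[i]][, perms[[a]], drop = FALSE],
                                    Qs[[j]][, perms[[b]], drop = FALSE])
          }
        }
        tab[[(i - 1) * R + j]] <- m
      }
    }
    combos <- as.matrix(expand.grid(rep(list(seq_len(nP)), R - 1)))
    best <- -Inf
    best_idx <- rep(1L, R)
    for (ci in seq_len(nrow(combos))) {
      idx <- c(1L, combos[ci, ])
      s <- 0
      for (i in seq_len(R - 1)) {
        for (j in seq(i + 1, R)) s <- s + tab[[(i - 1) * R + j]][idx[i], idx[j]]
      }
      if (s > best + 1e-12) {
        best <- s
        best_idx <- idx
      }
    }
    return(finish(lapply(best_idx, function(a) perms[[a]]), "exhaustive"))
  }
  # greedy against the running mean, restarted over random replicate orders
  run_order <- function(ord) {
    chosen <- vector("list", R)
    chosen[[ord[1]]] <- seq_len(K)
    Msum <- Qs[[ord[1]]]
    t <- 1
    for (r in ord[-1]) {
      ref <- Msum / t
      gbest <- -Inf
      pbest <- seq_len(K)
      for (p in perms) {
        g <- g_similarity(Qs[[r]][, p, drop = FALSE], ref)
        if (g > gbest) {
          gbest <- g
          pbest <- p
        }
      }
      chosen[[r]] <- pbest
      Msum <- Msum + Qs[[r]][, pbest, drop = FALSE]
      t <- t + 1
    }
    chosen
  }
  score <- function(perms_list) {
    aligned <- Map(function(Q, p) Q[, p, drop = FALSE], Qs, perms_list)
    tot <- 0
    for (i in seq_len(R - 1)) {
      for (j in seq(i + 1, R)) tot <- tot + g_similarity(aligned[[i]], aligned[[j]])
    }
    tot
  }
  with_seed(seed, {
    best_perms <- run_order(seq_len(R))
    best_score <- score(best_perms)
    for (rep_i in seq_len(max(0, repeats - 1))) {
      cand <- run_order(sample.int(R))
      sc <- score(cand)
      if (sc > best_score + 1e-12) {
        best_score <- sc
        best_perms <- cand
      }
    }
    finish(best_perms, "greedy")
  })
}

#' @export
print.replicate_alignment <- function(x, ...) {
  cat("<replicate_alignment> ", length(x$perms), " replicate(s), K = ",
      ncol(x$Q_mean), "; G = ", sprintf("%.4f", x$G), " (", x$method, ")\n",
      sep = "")
  invisible(x)
}

#' Evanno-style K-selection diagnostics
#'
#' Per K: mean and standard deviation of the replicate objective (the
#' converged log-likelihood, standing in for ln Pr(X|K)), and the
#' second-difference statistic
#' `delta_K = |mean(L(K+1)) - 2 mean(L(K)) + mean(L(K-1))| / sd(L(K))`,
#' defined only at interior K with consecutive neighbors and positive sd.
#'
#' @param objective_by_K named list mapping K (names coercible to integer)
#'   to numeric vectors of replicate objectives.
#' @return A data frame of class `k_diagnostics` with columns `K`, `n_rep`,
#'   `mean`, `sd`, `delta_K`.
#' @export
k_diagnostics <- function(objective_by_K) {
  Ks <- as.integer(names(objective_by_K))
  if (anyNA(Ks)) stop("names of `objective_by_K` must be the K values")
  ord <- order(Ks)
  Ks <- Ks[ord]
  vals <- objective_by_K[ord]
  m <- vapply(vals, mean, 0)
  s <- vapply(vals, function(v) if (length(v) > 1) stats::sd(v) else NA_real_, 0)
  dk <- rep(NA_real_, length(Ks))
  for (i in seq_along(Ks)) {
    if (i == 1 || i == length(Ks)) next
    if (Ks[i - 1] != Ks[i] - 1L || Ks[i + 1] != Ks[i] + 1L) next
    if (is.na(s[i]) || s[i] <= 0) next
    dk[i] <- abs(m[i + 1] - 2 * m[i] + m[i - 1]) / s[i]
  }
  structure(data.frame(K = Ks, n_rep = lengths(vals), mean = m, sd = s,
                       delta_K = dk, row.names = NULL),
            class = c("k_diagnostics", "data.frame"))
}
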