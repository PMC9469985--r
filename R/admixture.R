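# Maximum-likelihood admixture model: each individual draws each allele copy
# from one of K clusters with probability q_ik; clusters have their own
# allele frequencies per locus (independent across loci and clusters).
# Fitted by block-coordinate EM over Q and the cluster frequencies.  A
# Dirichlet pseudocount on the frequency update (the analogue of a flat
# lambda = 1 frequency prior) keeps frequencies strictly positive; the
# penalized objective is monotone over EM iterations.

# Index the non-missing allele observations once per table.
prep_admixture <- function(gt) {
  al <- locus_alleles(gt)
  nal <- lengths(al)
  if (any(nal == 0)) {
    stop("locus with no non-missing calls: ",
         paste(gt$loci[nal == 0], collapse = ", "))
  }
  L <- length(gt$loci)
  offset <- cumsum(c(0L, nal))[seq_len(L)]
  obs_i <- integer(0)
  obs_col <- integer(0)
  for (l in seq_len(L)) {
    for (mat in list(gt$a1, gt$a2)) {
      v <- mat[, l]
      ok <- which(!is.na(v))
      obs_i <- c(obs_i, ok)
      obs_col <- c(obs_col, offset[l] + match(v[ok], al[[l]]))
    }
  }
  list(obs_i = obs_i, obs_col = obs_col, block = rep(seq_len(L), nal),
       A = sum(nal), alleles = al,
       col_names = unlist(lapply(seq_len(L), function(l) {
         paste0(gt$loci[l], ".", al[[l]])
       })))
}

# Observed per-column allele frequencies (pooled over individuals).
pooled_freqs <- function(prep) {
  cnt <- tabulate(prep$obs_col, nbins = prep$A)
  tot <- as.vector(rowsum(cnt, prep$block))
  cnt / tot[prep$block]
}

#' Fit the admixture model at a fixed number of clusters
#'
#' Estimates an `n x K` membership matrix Q (rows sum to 1) and per-cluster
#' allele frequencies by EM, from a random seeded start.  Missing calls
#' contribute nothing to the likelihood.  The optimized objective is the
#' log-likelihood plus `pseudocount * sum(log p)` over cluster allele
#' frequencies; it is non-decreasing across iterations, and the raw
#' log-likelihood is reported alongside for K-selection diagnostics.
#'
#' @param gt a [genotype_table()] (>= 2 individuals; every locus must have
#'   at least one non-missing call).
#' @param K number of clusters (`1 <= K <= n`).
#' @param max_iter,tol EM controls: iteration cap and convergence threshold
#'   on the change in objective.
#' @param seed integer seed for the random start.
#' @param pseudocount Dirichlet pseudocount added per cluster/allele in the
#'   frequency update (default 1, mirroring a flat frequency prior).
#' @return An object of class `admixture_fit`: `Q`, `P` (allele-frequency
#'   matrix, rows = locus.allele, columns = clusters), `loglik`,
#'   `objective`, `trace`, `n_iter`, `converged`, `K`.
#' @export
fit_admixture <- function(gt, K, max_iter = 500, tol = 1e-6, seed = NULL,
                          pseudocount = 1) {
  stopifnot(inherits(gt, "genotype_table"))
  n <- n_ind(gt)
  if (n < 2) stop("need at least 2 individuals")
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of individuals (", n, ")")
  if (tol <= 0) stop("`tol` must be > 0")
  prep <- prep_admixture(gt)
  if (K == 1) {
    P <- matrix(pooled_freqs(prep), ncol = 1,
                dimnames = list(prep$col_names, "q1"))
    ll <- sum(log(P[prep$obs_col, 1]))
    Q <- matrix(1, n, 1, dimnames = list(gt$ids, "q1"))
    return(structure(list(Q = Q, P = P, loglik = ll, objective = ll,
                          trace = ll, n_iter = 0L, converged = TRUE, K = 1L),
                     class = "admixture_fit"))
  }
  copies <- tabulate(prep$obs_i, nbins = n)
  f0 <- pooled_freqs(prep)
  init <- with_seed(seed, {
    Q0 <- matrix(stats::rgamma(n * K, 1), n, K)
    P0 <- matrix(f0, prep$A, K) * matrix(stats::rgamma(prep$A * K, 20, 20),
                                         prep$A, K)
    list(Q = Q0 / rowSums(Q0),
         P = P0 / as.matrix(rowsum(P0, prep$block))[prep$block, , drop = FALSE])
  })
  Q <- init$Q
  P <- init$P
  obj_prev <- -Inf
  trace <- numeric(0)
  ll <- NA_real_
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    W <- Q[prep$obs_i, , drop = FALSE] * P[prep$obs_col, , drop = FALSE]
    rs <- rowSums(W)
    if (any(!is.finite(rs)) || any(rs <= 0)) {
      stop("non-finite likelihood at EM iteration ", iter)
    }
    ll <- sum(log(rs))
    obj <- ll + pseudocount * sum(log(P))
    trace <- c(trace, obj)
    if (obj < obj_prev - 1e-8) {
      warning("EM objective decreased at iteration ", iter)
    }
    if (is.finite(obj_prev) && abs(obj - obj_prev) < tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
    W <- W / rs
    Qn <- matrix(0, n, K)
    agg <- rowsum(W, prep$obs_i)
    Qn[as.integer(rownames(agg)), ] <- agg
    Q <- Qn / pmax(copies, 1L)
    Q[copies == 0L, ] <- 1 / K
    Pc <- matrix(0, prep$A, K)
    aggp <- rowsum(W, prep$obs_col)
    Pc[as.integer(rownames(aggp)), ] <- aggp
    Pc <- Pc + pseudocount
    S <- as.matrix(rowsum(Pc, prep$block))
    P <- Pc / S[prep$block, , drop = FALSE]
  }
  dimnames(Q) <- list(gt$ids, paste0("q", seq_len(K)))
  dimnames(P) <- list(prep$col_names, paste0("q", seq_len(K)))
  structure(list(Q = Q, P = P, loglik = ll, objective = trace[length(trace)],
                 trace = trace, n_iter = iter, converged = converged,
                 K = as.integer(K)),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("<admixture_fit> K = ", x$K, ", n = ", nrow(x$Q),
      "; loglik = ", sprintf("%.2f", x$loglik),
      " after ", x$n_iter, " EM iteration(s)",
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Log-likelihood of the admixture model at given parameters
#'
#' @param gt a [genotype_table()].
#' @param Q membership matrix (`n x K`, rows sum to 1).
#' @param P allele-frequency matrix as in [fit_admixture()].
#' @return The log-likelihood of the observed allele copies.
#' @export
admixture_loglik <- function(gt, Q, P) {
  prep <- prep_admixture(gt)
  W <- Q[prep$obs_i, , drop = FALSE] * P[prep$obs_col, , drop = FALSE]
  sum(log(rowSums(W)))
}

# Cross-fitted memberships for one replicate: the clustering is learned on
# the training loci, cluster allele frequencies at the held-out loci are
# estimated by weighting individuals with their trained memberships, and
# each individual's membership is then re-estimated from the held-out loci
# alone (q-only EM from a flat start, Dirichlet(1) row smoothing).  A split
# that only fits sampling noise does not generalize: the clusters' held-out
# frequencies are nearly equal, so the cross-fitted memberships stay near
# 1/K.  A genuine split keeps them extreme.
crossfit_Q <- function(gt, K, fit, held, q_iter = 50, q_tol = 1e-8) {
  sub <- gt[, held]
  prep <- prep_admixture(sub)
  n <- n_ind(gt)
  # held-locus cluster frequencies from trained memberships
  Pc <- matrix(1, prep$A, K)  # Dirichlet(1) pseudocount
  for (k in seq_len(K)) {
    agg <- rowsum(fit$Q[prep$obs_i, k], prep$obs_col)
    idx <- as.integer(rownames(agg))
    Pc[idx, k] <- Pc[idx, k] + agg[, 1]
  }
  S <- as.matrix(rowsum(Pc, prep$block))
  P <- Pc / S[prep$block, , drop = FALSE]
  copies <- tabulate(prep$obs_i, nbins = n)
  Q <- matrix(1 / K, n, K)
  for (it in seq_len(q_iter)) {
    W <- Q[prep$obs_i, , drop = FALSE] * P[prep$obs_col, , drop = FALSE]
    W <- W / rowSums(W)
    Qn <- matrix(0, n, K)
    agg <- rowsum(W, prep$obs_i)
    Qn[as.integer(rownames(agg)), ] <- agg
    Qnew <- (Qn + 1) / (copies + K)
    Qnew[copies == 0L, ] <- 1 / K
    delta <- max(abs(Qnew - Q))
    Q <- Qnew
    if (delta < q_tol) break
  }
  dimnames(Q) <- list(gt$ids, paste0("q", seq_len(K)))
  Q
}

#' Fit seeded admixture replicates and align them
#'
#' Runs `replicates` random-restart EM fits (replicate seeds derived from
#' `seed`), aligns their cluster labels with [align_replicates()], and
#' averages the aligned memberships.  With `cross_fit = TRUE` each
#' replicate holds out a random half of the loci: the clustering is
#' learned on the remaining loci and the averaged memberships are
#' re-estimated from the held-out loci alone, which calibrates them --
#' splits that only fit sampling noise collapse toward 1/K because they do
#' not generalize across loci, while genuine structure survives.
#'
#' @inheritParams fit_admixture
#' @param replicates number of random restarts (default 10).
#' @param align_repeats greedy restarts passed to [align_replicates()].
#' @param cross_fit calibrate memberships by locus holdout (default
#'   `FALSE`; the bifurcation process enables it).
#' @param ... passed to [fit_admixture()].
#' @return An object of class `admixture_replicates`: `fits` (list),
#'   `alignment`, `Q_mean`, `G`, `logliks`, `K`.
#' @export
run_admixture_replicates <- function(gt, K, replicates = 10, seed = 1,
                                     align_repeats = 1000, cross_fit = FALSE,
                                     ...) {
  if (replicates < 1) stop("`replicates` must be >= 1")
  L <- n_loci(gt)
  if (cross_fit && L < 3) {
    stop("cross-fitting needs at least 3 loci")
  }
  n_hold <- if (cross_fit) max(1L, min(L - 2L, floor(L / 2))) else 0L
  fits <- vector("list", replicates)
  Qs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rseed <- derive_seed(seed, paste0("rep", r))
    if (cross_fit) {
      held <- with_seed(derive_seed(seed, paste0("hold", r)),
                        sort(sample.int(L, n_hold)))
      fits[[r]] <- fit_admixture(gt[, -held], K, seed = rseed, ...)
      Qs[[r]] <- crossfit_Q(gt, K, fits[[r]], held)
    } else {
      fits[[r]] <- fit_admixture(gt, K, seed = rseed, ...)
      Qs[[r]] <- fits[[r]]$Q
    }
  }
  alg <- align_replicates(Qs, repeats = align_repeats,
                          seed = derive_seed(seed, "align"))
  structure(list(fits = fits, alignment = alg, Q_mean = alg$Q_mean,
                 G = alg$G, logliks = vapply(fits, `[[`, 0, "loglik"),
                 cross_fit = cross_fit, K = as.integer(K)),
            class = "admixture_replicates")
}

#' Replicate admixture fits over a range of K with Evanno diagnostics
#'
#' @inheritParams run_admixture_replicates
#' @param K_values integer vector of cluster counts to scan.
#' @return A list with `results` (one [run_admixture_replicates()] result
#'   per K) and `diagnostics` (see [k_diagnostics()]).
#' @export
admixture_scan <- function(gt, K_values, replicates = 10, seed = 1, ...) {
  K_values <- sort(unique(as.integer(K_values)))
  results <- lapply(K_values, function(K) {
    run_admixture_replicates(gt, K, replicates = replicates,
                             seed = derive_seed(seed, paste0("K", K)), ...)
  })
  names(results) <- as.character(K_values)
  obj <- lapply(results, `[[`, "logliks")
  list(results = results, diagnostics = k_diagnostics(obj))
}
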