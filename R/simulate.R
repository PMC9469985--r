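# Synthetic spatial microsatellite data with known truth, in the two
# regimes the analysis methods assume: (1) nested hierarchical drift (a
# balanced binary tree of Balding-Nichols frequency draws), for parameter-
# recovery tests of the bifurcation process; (2) a stepping-stone lattice
# with stepwise mutation, for genuine isolation by distance.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha)
  g / sum(g)
}

# leaf centers of a balanced binary tree: level 1 splits along x, level 2
# along y, alternating, with halved offsets per level so genetic nesting
# matches spatial nesting
deme_layout <- function(n_levels, spacing) {
  centers <- matrix(0, 1, 2)
  paths <- ""
  for (lev in seq_len(n_levels)) {
    off <- spacing / 2^(lev - 1) / 2
    axis <- 2 - lev %% 2
    tok <- if (lev %% 2 == 1) c("1", "2") else c("a", "b")
    centers <- centers[rep(seq_len(nrow(centers)), each = 2), , drop = FALSE]
    centers[, axis] <- centers[, axis] + rep(c(-off, off),
                                             length.out = nrow(centers))
    paths <- paste0(rep(paths, each = 2), rep(tok, length(paths)))
  }
  list(centers = centers, paths = paths)
}

#' Simulate nested hierarchical population structure
#'
#' Ancestral allele frequencies are drawn per locus from a symmetric
#' Dirichlet; each branch of a balanced binary tree draws its child's
#' frequencies from the Balding-Nichols construction
#' `Dirichlet(p (1 - F) / F)` with that level's drift `F`.  Genotypes are
#' in Hardy-Weinberg proportions within terminal demes.  Coordinates place
#' demes so spatial nesting matches genetic nesting (level-1 split along x,
#' level-2 along y, with halved offsets per level), with individuals
#' scattered around the deme center, optionally clumped into unevenly used
#' leks.  Deme labels follow the same alternating 1|2 / a|b nomenclature as
#' [run_sibp()].
#'
#' @param n_levels tree depth; `2^n_levels` terminal demes (0 = panmixia).
#' @param f per-level drift in (0, 1); scalar or one value per level.
#' @param n_per_deme individuals sampled per terminal deme.
#' @param n_loci,n_alleles loci and ancestral alleles per locus.
#' @param deme_spacing_km distance between the level-1 deme-group centers.
#' @param sigma_km spatial spread of individuals around the deme center.
#' @param leks_per_deme number of lek clumps per deme (0 disables lek
#'   clumping).
#' @param lek_sd_km spread of individuals around their lek.
#' @param missing_rate fraction of calls set to missing.
#' @param seed integer seed; identical configurations reproduce identical
#'   datasets.
#' @return A list with `data` (a [spatial_genotypes()]) and `truth` (data
#'   frame `id`, `deme`, plus one `level<k>` column per split).
#' @export
simulate_hierarchical <- function(n_levels = 2, f = 0.2, n_per_deme = 50,
                                  n_loci = 15, n_alleles = 10,
                                  deme_spacing_km = 400, sigma_km = 25,
                                  leks_per_deme = 5, lek_sd_km = 4,
                                  missing_rate = 0, seed = 1) {
  if (n_levels > 10) stop("tree depth > 10 not supported")
  f <- rep(f, length.out = max(n_levels, 1))
  if (n_levels > 0 && (any(f <= 0) || any(f >= 1))) {
    stop("drift `f` must lie in (0, 1)")
  }
  with_seed(seed, {
    freqs <- lapply(seq_len(n_loci), function(l) {
      list(rdirichlet1(rep(1, n_alleles)))
    })
    for (lev in seq_len(n_levels)) {
      shrink <- (1 - f[lev]) / f[lev]
      freqs <- lapply(freqs, function(fl) {
        unlist(lapply(fl, function(p) {
          list(rdirichlet1(p * shrink), rdirichlet1(p * shrink))
        }), recursive = FALSE)
      })
    }
    lay <- deme_layout(n_levels, deme_spacing_km)
    n_demes <- nrow(lay$centers)
    ids <- character(0)
    deme <- character(0)
    a1 <- NULL
    a2 <- NULL
    coords <- NULL
    for (d in seq_len(n_demes)) {
      nm <- if (nzchar(lay$paths[d])) lay$paths[d] else "deme1"
      ids_d <- sprintf("%s_%03d", nm, seq_len(n_per_deme))
      g1 <- matrix(0L, n_per_deme, n_loci)
      g2 <- matrix(0L, n_per_deme, n_loci)
      for (l in seq_len(n_loci)) {
        p <- freqs[[l]][[d]]
        g1[, l] <- sample.int(n_alleles, n_per_deme, replace = TRUE, prob = p)
        g2[, l] <- sample.int(n_alleles, n_per_deme, replace = TRUE, prob = p)
      }
      if (leks_per_deme > 0) {
        lc <- cbind(stats::rnorm(leks_per_deme, lay$centers[d, 1], sigma_km),
                    stats::rnorm(leks_per_deme, lay$centers[d, 2], sigma_km))
        w <- rdirichlet1(rep(1, leks_per_deme))
        lk <- sample.int(leks_per_deme, n_per_deme, replace = TRUE, prob = w)
        xy <- lc[lk, , drop = FALSE] +
          matrix(stats::rnorm(2 * n_per_deme, 0, lek_sd_km), ncol = 2)
      } else {
        xy <- cbind(stats::rnorm(n_per_deme, lay$centers[d, 1], sigma_km),
                    stats::rnorm(n_per_deme, lay$centers[d, 2], sigma_km))
      }
      ids <- c(ids, ids_d)
      deme <- c(deme, rep(nm, n_per_deme))
      a1 <- rbind(a1, g1)
      a2 <- rbind(a2, g2)
      coords <- rbind(coords, xy)
    }
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(length(a1)) < missing_rate, nrow(a1))
      a1[drop] <- NA_integer_
      a2[drop] <- NA_integer_
    }
    gt <- genotype_table(ids, sprintf("loc%02d", seq_len(n_loci)), a1, a2,
                         group = deme)
    truth <- data.frame(id = ids, deme = deme, stringsAsFactors = FALSE)
    for (lev in seq_len(n_levels)) {
      truth[[paste0("level", lev)]] <- substr(deme, 1, lev)
    }
    list(data = spatial_genotypes(gt, coords), truth = truth)
  })
}

# nearest-neighbor averaging on an nx x ny lattice (rook adjacency)
lattice_neighbors <- function(nx, ny) {
  idx <- function(i, j) (j - 1L) * nx + i
  lapply(seq_len(nx * ny), function(k) {
    i <- (k - 1L) %% nx + 1L
    j <- (k - 1L) %/% nx + 1L
    nb <- c(if (i > 1) idx(i - 1L, j), if (i < nx) idx(i + 1L, j),
            if (j > 1) idx(i, j - 1L), if (j < ny) idx(i, j + 1L))
    as.integer(nb)
  })
}

#' Simulate a stepping-stone lattice under isolation by distance
#'
#' Forward-time Wright-Fisher demes on an `nx x ny` lattice with
#' nearest-neighbor migration `m` and symmetric stepwise mutation `mu` on a
#' bounded allele ladder (reflecting ends), founded from a common pool.
#' Sampled genotypes are in Hardy-Weinberg proportions within demes and
#' carry deme-derived coordinates.
#'
#' @param nx,ny lattice dimensions (>= 2 demes in total).
#' @param deme_size diploid individuals per deme (>= 2).
#' @param generations forward generations (>= 1).
#' @param m migration rate into each deme (split among its neighbors).
#' @param mu stepwise mutation rate per allele copy per generation.
#' @param n_loci loci; `n_alleles` is the ladder length.
#' @param n_alleles allele-ladder length (reflecting boundaries).
#' @param samples_per_deme individuals sampled per deme.
#' @param spacing_km lattice spacing; `sigma_km` in-deme scatter.
#' @param sigma_km spatial scatter of samples around the deme node.
#' @param seed integer seed.
#' @return A list with `data` (a [spatial_genotypes()]) and `truth`
#'   (data frame `id`, `deme`, `ix`, `iy`).
#' @export
simulate_stepping_stone <- function(nx = 10, ny = 2, deme_size = 100,
                                    generations = 1000, m = 0.01, mu = 2e-4,
                                    n_loci = 15, n_alleles = 30,
                                    samples_per_deme = 10, spacing_km = 50,
                                    sigma_km = 5, seed = 1) {
  if (nx * ny < 2) stop("lattice must hold >= 2 demes")
  if (deme_size < 2) stop("`deme_size` must be >= 2")
  if (generations < 1) stop("`generations` must be >= 1")
  if (m < 0 || m > 0.5) stop("`m` must lie in [0, 0.5]")
  nd <- nx * ny
  nb <- lattice_neighbors(nx, ny)
  with_seed(seed, {
    # common founding pool concentrated on the central third of the ladder
    core <- seq(floor(n_alleles / 3) + 1, ceiling(2 * n_alleles / 3))
    P <- array(0, dim = c(nd, n_alleles, n_loci))
    for (l in seq_len(n_loci)) {
      p0 <- numeric(n_alleles)
      p0[core] <- rdirichlet1(rep(1, length(core)))
      P[, , l] <- matrix(p0, nd, n_alleles, byrow = TRUE)
    }
    for (g in seq_len(generations)) {
      for (l in seq_len(n_loci)) {
        pl <- P[, , l]
        mig <- t(vapply(seq_len(nd), function(k) {
          colMeans(pl[nb[[k]], , drop = FALSE])
        }, numeric(n_alleles)))
        pl <- (1 - m) * pl + m * mig
        # stepwise mutation +/-1 on the ladder; steps beyond an end stay put
        up_in <- cbind(0, pl[, -n_alleles, drop = FALSE])
        down_in <- cbind(pl[, -1, drop = FALSE], 0)
        new_pl <- (1 - mu) * pl + (mu / 2) * (up_in + down_in)
        new_pl[, 1] <- new_pl[, 1] + (mu / 2) * pl[, 1]
        new_pl[, n_alleles] <- new_pl[, n_alleles] + (mu / 2) * pl[, n_alleles]
        pl <- new_pl
        for (k in seq_len(nd)) {
          pl[k, ] <- stats::rmultinom(1, 2 * deme_size, pl[k, ]) /
            (2 * deme_size)
        }
        P[, , l] <- pl
      }
    }
    ids <- character(0)
    deme <- integer(0)
    a1 <- NULL
    a2 <- NULL
    coords <- NULL
    for (k in seq_len(nd)) {
      i <- (k - 1L) %% nx + 1L
      j <- (k - 1L) %/% nx + 1L
      ids_k <- sprintf("d%02d_%02d", k, seq_len(samples_per_deme))
      g1 <- matrix(0L, samples_per_deme, n_loci)
      g2 <- matrix(0L, samples_per_deme, n_loci)
      for (l in seq_len(n_loci)) {
        g1[, l] <- sample.int(n_alleles, samples_per_deme, replace = TRUE,
                              prob = P[k, , l])
        g2[, l] <- sample.int(n_alleles, samples_per_deme, replace = TRUE,
                              prob = P[k, , l])
      }
      xy <- cbind(stats::rnorm(samples_per_deme, (i - 1) * spacing_km,
                               sigma_km),
                  stats::rnorm(samples_per_deme, (j - 1) * spacing_km,
                               sigma_km))
      ids <- c(ids, ids_k)
      deme <- c(deme, rep(k, samples_per_deme))
      a1 <- rbind(a1, g1)
      a2 <- rbind(a2, g2)
      coords <- rbind(coords, xy)
    }
    gt <- genotype_table(ids, sprintf("loc%02d", seq_len(n_loci)), a1, a2,
                         group = paste0("deme", deme))
    truth <- data.frame(id = ids, deme = deme,
                        ix = (deme - 1L) %% nx + 1L,
                        iy = (deme - 1L) %/% nx + 1L)
    list(data = spatial_genotypes(gt, coords), truth = truth)
  })
}
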