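# Allele frequencies and the per-group diversity summary (the shared kernel
# for all frequency-based statistics).

#' Per-locus allele frequencies
#'
#' Frequencies are computed from non-missing calls only.  Loci with no data
#' in the selection are returned as `NULL` entries and named in the
#' `excluded` attribute.
#'
#' @param gt a [genotype_table()].
#' @param individuals optional individual subset (ids or indices).
#' @return Named list (one entry per locus) of named frequency vectors
#'   summing to 1, with attribute `excluded`.
#' @export
allele_freqs <- function(gt, individuals = NULL) {
  sub <- if (is.null(individuals)) gt else gt[individuals, ]
  if (n_ind(sub) == 0) stop("empty individual selection")
  out <- vector("list", length(sub$loci))
  names(out) <- sub$loci
  excluded <- character(0)
  for (l in seq_along(sub$loci)) {
    a <- c(sub$a1[, l], sub$a2[, l])
    a <- a[!is.na(a)]
    if (length(a) == 0) {
      excluded <- c(excluded, sub$loci[l])
      next
    }
    tab <- table(a)
    out[[l]] <- stats::setNames(as.numeric(tab) / length(a), names(tab))
  }
  attr(out, "excluded") <- excluded
  out
}

# Per-locus diversity components for one set of individuals.
locus_diversity <- function(gt, individuals) {
  sub <- gt[individuals, ]
  fr <- allele_freqs(sub)
  rows <- lapply(seq_along(sub$loci), function(l) {
    p <- fr[[l]]
    if (is.null(p)) return(NULL)
    het <- !is.na(sub$a1[, l]) & sub$a1[, l] != sub$a2[, l]
    typed <- !is.na(sub$a1[, l])
    data.frame(locus = sub$loci[l],
               A = length(p),
               Ae = 1 / sum(p^2),
               A95 = sum(p >= 0.05),
               Ho = sum(het) / sum(typed),
               He = 1 - sum(p^2))
  })
  do.call(rbind, rows)
}

#' Per-group genetic diversity summary
#'
#' For each group: sample size `n`, mean alleles per locus `A`, mean
#' effective alleles `Ae = 1/sum(p^2)`, mean count of alleles at frequency
#' `>= 0.05` (`A95`), mean observed (`Ho`) and expected (`He = 1 - sum(p^2)`)
#' heterozygosity, and `FIS = 1 - Ho/He` computed from the locus-averaged
#' `Ho`/`He`.  Per-locus values are averaged with equal weights over loci
#' with data; `FIS` is `NA` when `He = 0`.
#'
#' @param gt a [genotype_table()].
#' @param groups group labels per individual, a named list of id vectors,
#'   or `NULL` for a single pooled group.
#' @param unbiased apply the small-sample factor `2n/(2n-1)` to `He`
#'   (default `FALSE`: plain gene diversity, matching `FIS = 1 - Ho/He`).
#' @return Data frame of class `diversity_summary`, one row per group.
#' @export
diversity_summary <- function(gt, groups = NULL, unbiased = FALSE) {
  gl <- as_group_list(gt, groups)
  rows <- lapply(names(gl), function(g) {
    ld <- locus_diversity(gt, gl[[g]])
    if (is.null(ld) || nrow(ld) == 0) {
      stop("group '", g, "' has no typed locus")
    }
    ho <- mean(ld$Ho)
    he <- mean(ld$He)
    if (unbiased) {
      nn <- length(gl[[g]])
      he <- he * 2 * nn / (2 * nn - 1)
    }
    data.frame(group = g, n = length(gl[[g]]), A = mean(ld$A),
               Ae = mean(ld$Ae), A95 = mean(ld$A95), Ho = ho, He = he,
               FIS = if (he > 0) fis_from_het(ho, he) else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("diversity_summary", "data.frame"))
}

#' Heterozygote-deficit statistic from observed and expected heterozygosity
#'
#' `FIS = 1 - Ho/He`: positive values indicate a deficit of heterozygotes
#' relative to Hardy-Weinberg proportions, negative values an excess.
#'
#' @param ho,he observed and expected heterozygosity (`he > 0`).
#' @return Numeric `FIS`.
#' @export
fis_from_het <- function(ho, he) {
  if (any(he <= 0)) stop("`he` must be > 0")
  1 - ho / he
}
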