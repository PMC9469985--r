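# Individual pairwise genetic distance for codominant data (the AMOVA
# squared distance): per locus, half the squared Euclidean distance between
# allele-count vectors, so identical genotypes score 0, heterozygote pairs
# sharing one allele 1, heterozygotes with no shared allele 2, a homozygote
# vs a heterozygote with no shared allele 3, and opposite homozygotes 4.

#' AMOVA squared genetic distance between individuals
#'
#' Distances are summed over loci typed in both individuals and rescaled by
#' `L / L_observed` so pairs with missing loci remain comparable.  Pairs
#' with no shared typed locus are `NA` (with a warning).
#'
#' @param gt a [genotype_table()].
#' @return A symmetric `n x n` matrix with zero diagonal.
#' @export
amova_distance <- function(gt) {
  n <- n_ind(gt)
  L <- n_loci(gt)
  total <- matrix(0, n, n)
  shared <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    alleles <- sort(unique(c(gt$a1[, l], gt$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0) next
    C <- matrix(0, n, length(alleles))
    typed <- !is.na(gt$a1[, l])
    idx <- which(typed)
    C[cbind(idx, match(gt$a1[idx, l], alleles))] <-
      C[cbind(idx, match(gt$a1[idx, l], alleles))] + 1
    C[cbind(idx, match(gt$a2[idx, l], alleles))] <-
      C[cbind(idx, match(gt$a2[idx, l], alleles))] + 1
    G <- tcrossprod(C)
    sq <- rowSums(C^2)
    d2 <- (outer(sq, sq, `+`) - 2 * G) / 2
    mask <- outer(typed, typed, `&`)
    total <- total + d2 * mask
    shared <- shared + mask
  }
  diag(shared) <- pmax(diag(shared), 1L)
  none <- shared == 0
  if (any(none)) {
    warning(sum(none[upper.tri(none)]),
            " pair(s) share no typed locus; distance set to NA")
  }
  out <- total * (L / shared)
  out[none] <- NA_real_
  diag(out) <- 0
  dimnames(out) <- list(gt$ids, gt$ids)
  out
}
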