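#' Per-variant Weir-Cockerham Fst between two groups
#'
#' The two-population variance-components estimator
#' `theta = a / (a + b + c)` with among-population (a),
#' among-individual-within-population (b) and within-individual (c)
#' components computed per site from group sample sizes, allele
#' frequencies and observed heterozygosities. Negative estimates are
#' retained; sites where a + b + c = 0 or where either group has fewer
#' than 2 called samples are returned as `NA` (excluded from quantile
#' calls downstream).
#'
#' @param gm A [geno_matrix()].
#' @param group1_ids,group2_ids Sample id sets.
#' @return `data.frame(chrom, pos, fst)` aligned to `gm$variants`.
#' @export
weir_cockerham_fst <- function(gm, group1_ids, group2_ids) {
  G1 <- gm$calls[match(group1_ids, gm$samples$id), , drop = FALSE]
  G2 <- gm$calls[match(group2_ids, gm$samples$id), , drop = FALSE]
  n1 <- colSums(!is.na(G1)); n2 <- colSums(!is.na(G2))
  p1 <- ifelse(n1 > 0, colSums(G1, na.rm = TRUE) / (2 * n1), NA)
  p2 <- ifelse(n2 > 0, colSums(G2, na.rm = TRUE) / (2 * n2), NA)
  h1 <- ifelse(n1 > 0, colSums(G1 == 1L, na.rm = TRUE) / n1, NA)
  h2 <- ifelse(n2 > 0, colSums(G2 == 1L, na.rm = TRUE) / n2, NA)

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  denom <- a + b + cc
  usable <- n1 >= 2 & n2 >= 2 & is.finite(denom)
  fst <- ifelse(usable & denom != 0, a / denom, NA_real_)
  data.frame(chrom = gm$variants$chrom, pos = gm$variants$pos, fst = fst,
             a = ifelse(usable, a, NA_real_),
             denom = ifelse(usable, denom, NA_real_),
             stringsAsFactors = FALSE)
}

#' Multi-locus Weir-Cockerham Fst
#'
#' The ratio-of-sums (weighted) genome-wide estimator
#' `sum(a) / sum(a + b + c)` over usable sites, the form Weir and
#' Cockerham recommend for combining loci (the mean of per-site ratios
#' is biased downward by site-level noise).
#'
#' @param fst_table Output of [weir_cockerham_fst()].
#' @return Single numeric estimate.
#' @export
global_fst <- function(fst_table) {
  ok <- !is.na(fst_table$a) & !is.na(fst_table$denom)
  sum(fst_table$a[ok]) / sum(fst_table$denom[ok])
}
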