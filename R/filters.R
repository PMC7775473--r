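#' Filter variants on minor allele frequency and missingness
#'
#' Retains variants with MAF >= `maf_min` (computed over non-missing
#' calls) and missing fraction <= `max_missing`. The sample set is never
#' changed. Idempotent.
#'
#' @param gm A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency in \[0, 0.5\].
#' @param max_missing Maximum per-variant missing fraction in \[0, 1\].
#' @return Filtered `geno_matrix`.
#' @export
filter_variants <- function(gm, maf_min = 0.01, max_missing = 0.30) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  maf <- minor_allele_freq(gm)
  miss <- colMeans(is.na(gm$calls))
  keep <- !is.na(maf) & maf >= maf_min & miss <= max_missing
  subset_variants(gm, keep)
}

#' Squared genotype correlation between two dosage vectors
#'
#' Pairwise-complete; `NA` when fewer than 2 joint observations or either
#' vector is constant over them.
#' @keywords internal
geno_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Prune variants for linkage disequilibrium
#'
#' Sliding-window pairwise pruning in the style of PLINK's
#' `--indep-pairwise`: windows of `window` variants advance by `step`
#' variants along each chromosome; while any retained pair within the
#' window has squared genotype correlation greater than `r2_max`, one
#' member of the worst pair is removed. The removed member is the one
#' with the lower MAF (tie: the later position), which makes the result
#' deterministic.
#'
#' @param gm A [geno_matrix()].
#' @param window Window size in variant count (>= 2).
#' @param step Window advance in variant count.
#' @param r2_max Squared-correlation threshold in (0, 1\].
#' @return Pruned `geno_matrix`.
#' @export
prune_ld <- function(gm, window = 10, step = 3, r2_max = 0.5) {
  stopifnot(window >= 2, step >= 1, r2_max > 0, r2_max <= 1)
  maf <- minor_allele_freq(gm)
  keep <- rep(TRUE, ncol(gm$calls))
  for (chrom in unique(gm$variants$chrom)) {
    vi <- which(gm$variants$chrom == chrom)
    if (length(vi) < 2L) next
    starts <- seq(1L, length(vi), by = step)
    for (s in starts) {
      w <- vi[s:min(s + window - 1L, length(vi))]
      repeat {
        act <- w[keep[w]]
        if (length(act) < 2L) break
        cm <- suppressWarnings(
          stats::cor(gm$calls[, act, drop = FALSE],
                     use = "pairwise.complete.obs")^2)
        cm[!is.finite(cm)] <- 0
        diag(cm) <- 0
        if (max(cm) <= r2_max) break
        worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
        a <- act[worst[1L]]; b <- act[worst[2L]]
        drop_v <- if (is.na(maf[a]) || is.na(maf[b])) max(a, b)
        else if (maf[a] < maf[b]) a
        else if (maf[b] < maf[a]) b
        else max(a, b)  # tie: later position goes
        keep[drop_v] <- FALSE
      }
    }
  }
  subset_variants(gm, keep)
}
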