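#' Phased haplotype panel
#'
#' Two haplotypes per diploid sample, positionally aligned to a variant
#' table. Rows of `haps` are haplotypes (sample order preserved, hap 1
#' then hap 2 interleaved per sample), columns are variants, entries are
#' 0/1 alternate-allele indicators.
#'
#' @param haps Integer matrix (2 * n_samples) x n_variants with 0/1 entries.
#' @param sample_ids Character vector of n_samples ids.
#' @param variants Variant `data.frame` as in [geno_matrix()].
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(haps, sample_ids, variants) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  sample_ids <- as.character(sample_ids)
  if (nrow(haps) != 2L * length(sample_ids)) {
    stop("hap_panel requires exactly two haplotype rows per sample")
  }
  if (ncol(haps) != nrow(variants)) stop("haplotype/variant dimension mismatch")
  vals <- haps[!is.na(haps)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 1L)) {
    stop("haplotype alleles must be 0/1")
  }
  rownames(haps) <- paste0(rep(sample_ids, each = 2L), "_", c(1L, 2L))
  structure(list(haps = haps, sample_ids = sample_ids, variants = variants),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("hap_panel:", length(x$sample_ids), "samples (",
      nrow(x$haps), "haplotypes ) x", ncol(x$haps), "variants\n")
  invisible(x)
}

#' Row indices of a sample's two haplotypes
#' @keywords internal
hap_rows <- function(hp, ids) {
  idx <- match(ids, hp$sample_ids)
  if (anyNA(idx)) stop("unknown sample ids: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Collapse a haplotype panel to genotype dosages
#'
#' @param hp A `hap_panel`.
#' @param samples Optional sample `data.frame`; defaults to ids only.
#' @return A `geno_matrix` whose calls are the per-sample haplotype sums.
#' @export
haps_to_genotypes <- function(hp, samples = NULL) {
  n <- length(hp$sample_ids)
  calls <- hp$haps[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    hp$haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  if (is.null(samples)) samples <- data.frame(id = hp$sample_ids)
  geno_matrix(calls, hp$variants, samples)
}

#' Subset a haplotype panel by sample ids
#' @param hp A `hap_panel`.
#' @param ids Sample ids to keep.
#' @return A `hap_panel` restricted to `ids`.
#' @export
subset_haps <- function(hp, ids) {
  hap_panel(hp$haps[hap_rows(hp, ids), , drop = FALSE], ids, hp$variants)
}
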