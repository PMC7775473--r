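#' Genotype matrix container
#'
#' Holds biallelic SNP calls as alternate-allele dosages together with
#' variant and sample metadata. The dosage matrix is samples x variants
#' with entries in \{0, 1, 2\} and `NA` for missing calls.
#'
#' @param calls Integer matrix, samples x variants, values 0/1/2/NA.
#' @param variants `data.frame` with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; one row per variant, positions strictly increasing
#'   within each chromosome.
#' @param samples `data.frame` with at least a column `id`; optional
#'   columns such as `species`, `ploidy_label`, `use_class` and binary
#'   phenotype columns are carried through unchanged.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  if (nrow(samples) != nrow(calls)) {
    stop("samples table (", nrow(samples), ") does not match call rows (",
         nrow(calls), ")")
  }
  if (nrow(variants) != ncol(calls)) {
    stop("variants table (", nrow(variants), ") does not match call columns (",
         ncol(calls), ")")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosage calls must be in {0, 1, 2} or NA")
  }
  for (col in c("chrom", "pos")) {
    if (is.null(variants[[col]])) stop("variants table lacks column '", col, "'")
  }
  if (is.null(variants$ref)) variants$ref <- "A"
  if (is.null(variants$alt)) variants$alt <- "T"
  if (is.null(samples$id)) stop("samples table lacks column 'id'")
  samples$id <- as.character(samples$id)
  if (anyDuplicated(samples$id)) stop("duplicate sample ids")
  pos_ok <- tapply(variants$pos, variants$chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(pos_ok))) {
    stop("variant positions must be strictly increasing within chromosome")
  }
  rownames(calls) <- samples$id
  colnames(calls) <- if (nrow(variants)) {
    paste0(variants$chrom, ":", variants$pos)
  } else character(0)
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by sample ids
#'
#' @param gm A `geno_matrix`.
#' @param ids Character vector of sample ids to keep (order respected).
#' @return A `geno_matrix` restricted to `ids`.
#' @export
subset_samples <- function(gm, ids) {
  miss <- setdiff(ids, gm$samples$id)
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  idx <- match(ids, gm$samples$id)
  geno_matrix(gm$calls[idx, , drop = FALSE],
              gm$variants,
              gm$samples[idx, , drop = FALSE])
}

#' Subset a genotype matrix by variant index
#'
#' @param gm A `geno_matrix`.
#' @param idx Logical or integer index over variants.
#' @return A `geno_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(gm, idx) {
  geno_matrix(gm$calls[, idx, drop = FALSE],
              gm$variants[idx, , drop = FALSE],
              gm$samples)
}

#' Per-variant alternate-allele frequency
#'
#' Computed over non-missing calls only.
#'
#' @param gm A `geno_matrix`.
#' @param ids Optional sample ids over which to compute frequencies
#'   (default: all samples).
#' @return Numeric vector of alternate-allele frequencies; `NA` where a
#'   variant has no non-missing call.
#' @export
allele_freq <- function(gm, ids = NULL) {
  calls <- if (is.null(ids)) gm$calls else gm$calls[match(ids, gm$samples$id), , drop = FALSE]
  n_obs <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
}

#' Per-variant minor allele frequency
#'
#' @inheritParams allele_freq
#' @return Numeric vector in \[0, 0.5\].
#' @export
minor_allele_freq <- function(gm, ids = NULL) {
  p <- allele_freq(gm, ids)
  pmin(p, 1 - p)
}

#' Heterozygosity by sample and by variant
#'
#' Proportion of heterozygous calls among non-missing calls, the screen
#' statistic used to flag putative triploids (which a diploid caller
#' reports with inflated heterozygosity).
#'
#' @param gm A `geno_matrix`.
#' @return List with `sample` (named numeric, per sample) and `variant`
#'   (named numeric, per variant). Samples or variants with zero
#'   non-missing calls get `NA`, never 0.
#' @export
heterozygosity <- function(gm) {
  het <- gm$calls == 1L
  obs_s <- rowSums(!is.na(gm$calls))
  obs_v <- colSums(!is.na(gm$calls))
  by_sample <- ifelse(obs_s > 0, rowSums(het, na.rm = TRUE) / obs_s, NA_real_)
  by_variant <- ifelse(obs_v > 0, colSums(het, na.rm = TRUE) / obs_v, NA_real_)
  names(by_sample) <- gm$samples$id
  list(sample = by_sample, variant = by_variant)
}

#' Record per-sample heterozygosity into the sample table
#'
#' @param gm A `geno_matrix`.
#' @return `gm` with a `heterozygosity` column added to `gm$samples`.
#' @export
annotate_heterozygosity <- function(gm) {
  gm$samples$heterozygosity <- unname(heterozygosity(gm)$sample)
  gm
}
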