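#' Compare heterozygosity across labelled ploidy groups
#'
#' One-way ANOVA followed by Tukey HSD all-pairs comparisons of
#' per-individual heterozygosity between ploidy labels (2x, 3x, 4x, ...).
#' Triploids genotyped through a diploid caller show inflated
#' heterozygosity, so the 3x group is expected to exceed the others.
#'
#' @param het Numeric vector of per-sample heterozygosities.
#' @param labels Ploidy labels, same length as `het`.
#' @return `data.frame` with one row per group pair: `group1`, `group2`,
#'   `diff` (mean difference, group2 - group1), `p_adj` (Tukey-adjusted).
#' @export
compare_het_by_ploidy <- function(het, labels) {
  ok <- !is.na(het) & !is.na(labels)
  het <- het[ok]; labels <- as.character(labels[ok])
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("groups with <2 members excluded: ", paste(small, collapse = ", "))
    keep <- !labels %in% small
    het <- het[keep]; labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) stop("need >=2 groups with >=2 members")
  fit <- stats::aov(het ~ g, data = data.frame(het = het, g = factor(labels)))
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(pairs, `[`, "", 2),
             group2 = vapply(pairs, `[`, "", 1),
             diff = unname(tk[, "diff"]),
             p_adj = unname(tk[, "p adj"]),
             stringsAsFactors = FALSE)
}

#' Classify putative triploids from heterozygosity
#'
#' Samples whose heterozygosity exceeds the threshold are flagged
#' `putative_triploid` regardless of their database ploidy label; the
#' flagged set doubles as the removal set for downstream diploid-only
#' analyses. With `threshold = "midpoint"` the cutoff is set midway
#' between the mean heterozygosity of the 2x- and 3x-labelled groups
#' (a data-driven alternative when the fixed default does not suit the
#' panel).
#'
#' @param samples Sample `data.frame` with columns `id`,
#'   `heterozygosity`, and (for the midpoint mode) `ploidy_label`.
#' @param threshold Numeric heterozygosity cutoff (default 0.21), or the
#'   string "midpoint".
#' @return List with `calls` (`data.frame`: `sample_id`,
#'   `heterozygosity`, `label`, `call`), `removed` (flagged ids),
#'   `threshold` (the cutoff used) and `unclassified` (ids with undefined
#'   heterozygosity, excluded from classification).
#' @export
classify_ploidy <- function(samples, threshold = 0.21) {
  stopifnot(is.data.frame(samples), !is.null(samples$heterozygosity))
  if (identical(threshold, "midpoint")) {
    if (is.null(samples$ploidy_label)) {
      stop("midpoint threshold requires a ploidy_label column")
    }
    m2 <- mean(samples$heterozygosity[samples$ploidy_label == "2x"],
               na.rm = TRUE)
    m3 <- mean(samples$heterozygosity[samples$ploidy_label == "3x"],
               na.rm = TRUE)
    if (!is.finite(m2) || !is.finite(m3)) {
      stop("midpoint threshold needs both 2x and 3x labelled samples")
    }
    threshold <- (m2 + m3) / 2
  }
  und <- samples$id[is.na(samples$heterozygosity)]
  ok <- samples[!is.na(samples$heterozygosity), , drop = FALSE]
  call <- ifelse(ok$heterozygosity > threshold,
                 "putative_triploid", "diploid_like")
  calls <- data.frame(sample_id = ok$id,
                      heterozygosity = ok$heterozygosity,
                      label = if (!is.null(ok$ploidy_label)) ok$ploidy_label
                      else "unknown",
                      call = call, stringsAsFactors = FALSE)
  list(calls = calls,
       removed = calls$sample_id[calls$call == "putative_triploid"],
       threshold = threshold,
       unclassified = und)
}
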