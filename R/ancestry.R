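#' Fit a balanced-reference PCA
#'
#' Principal axes are fitted on equal-sized reference panels from the
#' two progenitor populations only (equal sizes avoid the axis being
#' dominated by the better-sampled population); other samples are later
#' projected onto the axes with [project_onto_pca()]. Genotypes are
#' centred by twice the reference allele frequency and scaled by
#' `sqrt(p(1-p))`, with pseudocount `1/(2n+2)` so no scale is zero;
#' variants monomorphic in the references are dropped. Component signs
#' follow a deterministic convention (the largest-magnitude loading of
#' each component is positive).
#'
#' @param gm A [geno_matrix()].
#' @param ref_a_ids,ref_b_ids Reference sample ids for the two
#'   populations; the larger set is down-sampled deterministically (first
#'   k ids in sorted order) to balance the panels.
#' @param n_components Number of axes to keep.
#' @return Object of class `pca_model`: `variant_idx`, `variant_means`
#'   (2p), `variant_scales`, `loadings` (variants x components),
#'   `reference_scores`, `explained_fraction`, `ref_ids`.
#' @export
fit_reference_pca <- function(gm, ref_a_ids, ref_b_ids, n_components = 10) {
  ref_a_ids <- sort(as.character(ref_a_ids))
  ref_b_ids <- sort(as.character(ref_b_ids))
  k <- min(length(ref_a_ids), length(ref_b_ids))
  if (k < 2) stop("need >=2 reference samples per population")
  ref_a_ids <- ref_a_ids[seq_len(k)]
  ref_b_ids <- ref_b_ids[seq_len(k)]
  refs <- c(ref_a_ids, ref_b_ids)
  G <- gm$calls[match(refs, gm$samples$id), , drop = FALSE]
  n_obs <- colSums(!is.na(G))
  p_raw <- ifelse(n_obs > 0, colSums(G, na.rm = TRUE) / (2 * n_obs), NA)
  keep <- !is.na(p_raw) & p_raw > 0 & p_raw < 1
  if (sum(keep) < 2) stop("model error: fewer than 2 usable variants")
  G <- G[, keep, drop = FALSE]
  n_obs <- n_obs[keep]
  p_hat <- (colSums(G, na.rm = TRUE) + 1) / (2 * n_obs + 2)
  mu <- 2 * p_hat
  sc <- sqrt(p_hat * (1 - p_hat))
  Z <- sweep(sweep(G, 2, mu, "-"), 2, sc, "/")
  Z[is.na(Z)] <- 0
  sv <- svd(Z)
  n_components <- min(n_components, length(sv$d))
  L <- sv$v[, seq_len(n_components), drop = FALSE]
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  # sign convention: largest-|loading| entry of each axis is positive
  for (j in seq_len(n_components)) {
    s <- sign(L[which.max(abs(L[, j])), j])
    if (s < 0) { L[, j] <- -L[, j]; scores[, j] <- -scores[, j] }
  }
  rownames(scores) <- refs
  structure(list(variant_idx = which(keep),
                 variant_means = mu, variant_scales = sc,
                 loadings = L, reference_scores = scores,
                 explained_fraction = sv$d[seq_len(n_components)]^2 /
                   sum(sv$d^2),
                 ref_ids = list(a = ref_a_ids, b = ref_b_ids)),
            class = "pca_model")
}

#' Project samples onto fitted principal axes
#'
#' Each sample's normalised genotype vector is regressed onto the
#' loadings by least squares over its observed entries, so missing calls
#' do not bias the score towards the origin. With no missingness this
#' reduces to the plain loading inner product.
#'
#' @param model A `pca_model` from [fit_reference_pca()].
#' @param gm A [geno_matrix()] aligned to the variants the model was fit
#'   on (same variant table).
#' @param ids Samples to project (default: all in `gm`).
#' @param min_overlap Minimum fraction of model variants a sample must
#'   share to get a confident score (default 0.5).
#' @return List with `scores` (samples x components) and
#'   `low_confidence` (logical per sample). All-missing samples raise an
#'   error if alone, otherwise get `NA` scores.
#' @export
project_onto_pca <- function(model, gm, ids = NULL, min_overlap = 0.5) {
  if (is.null(ids)) ids <- gm$samples$id
  G <- gm$calls[match(ids, gm$samples$id), model$variant_idx, drop = FALSE]
  Z <- sweep(sweep(G, 2, model$variant_means, "-"), 2,
             model$variant_scales, "/")
  L <- model$loadings
  nc <- ncol(L)
  scores <- matrix(NA_real_, nrow(Z), nc,
                   dimnames = list(ids, paste0("PC", seq_len(nc))))
  low_conf <- logical(nrow(Z))
  full_xtx <- crossprod(L)
  for (i in seq_len(nrow(Z))) {
    obs <- !is.na(Z[i, ])
    if (!any(obs)) {
      if (nrow(Z) == 1L) stop("sample ", ids[i], " has no observed calls")
      low_conf[i] <- TRUE
      next
    }
    low_conf[i] <- mean(obs) < min_overlap
    if (all(obs)) {
      scores[i, ] <- solve(full_xtx, crossprod(L, Z[i, ]))
    } else {
      Lo <- L[obs, , drop = FALSE]
      scores[i, ] <- tryCatch(
        solve(crossprod(Lo), crossprod(Lo, Z[i, obs])),
        error = function(e) rep(NA_real_, nc))
    }
  }
  list(scores = scores, low_confidence = stats::setNames(low_conf, ids))
}

#' Mann-Whitney comparison of projected scores between two groups
#'
#' Two-sided Mann-Whitney U test on one principal component's scores,
#' exact for small tie-free samples and normal-approximated (with tie
#' correction) otherwise.
#'
#' @param scores Score matrix (samples x components) with sample-id
#'   rownames, e.g. from [project_onto_pca()].
#' @param group1_ids,group2_ids Disjoint, non-empty id sets.
#' @param component Column index or name (default 1).
#' @return List of class `rank_sum_result`: `w`, `p`, `n1`, `n2`.
#' @export
rank_sum_compare <- function(scores, group1_ids, group2_ids, component = 1) {
  if (!length(group1_ids) || !length(group2_ids)) {
    stop("input error: empty group")
  }
  if (length(intersect(group1_ids, group2_ids))) {
    stop("input error: groups must be disjoint")
  }
  x <- scores[match(group1_ids, rownames(scores)), component]
  y <- scores[match(group2_ids, rownames(scores)), component]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  exact <- length(x) <= 20 && length(y) <= 20 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  structure(list(w = unname(wt$statistic), p = wt$p.value,
                 n1 = length(x), n2 = length(y)),
            class = "rank_sum_result")
}

#' Three-population f3 admixture statistic
#'
#' f3(target; A, B) averages the per-variant term
#' `(c - a)(c - b) - c(1-c)/(n_c - 1)` over variants, where a, b, c are
#' sample alternate-allele frequencies and the subtraction removes the
#' sampling-variance bias of the target frequency (`n_c` = number of
#' called target alleles). A significantly negative value indicates the
#' target is admixed between the two sources. The standard error comes
#' from a leave-one-out block jackknife over contiguous physical blocks.
#'
#' @param gm A [geno_matrix()].
#' @param target_ids,source_a_ids,source_b_ids Sample id sets (>= 2
#'   each).
#' @param block_size_bp Jackknife block length (default 5 Mb).
#' @return Object of class `f3_result`: `f3`, `se`, `z`, `n_blocks`,
#'   `n_variants`.
#' @export
f3_statistic <- function(gm, target_ids, source_a_ids, source_b_ids,
                         block_size_bp = 5e6) {
  for (g in list(target_ids, source_a_ids, source_b_ids)) {
    if (length(g) < 2) stop("each group needs >=2 samples")
  }
  a <- allele_freq(gm, source_a_ids)
  b <- allele_freq(gm, source_b_ids)
  cc <- allele_freq(gm, target_ids)
  Gt <- gm$calls[match(target_ids, gm$samples$id), , drop = FALSE]
  n_c <- 2 * colSums(!is.na(Gt))
  union_p <- allele_freq(gm, c(target_ids, source_a_ids, source_b_ids))
  ok <- !is.na(a) & !is.na(b) & !is.na(cc) & n_c >= 2 &
    !is.na(union_p) & union_p > 0 & union_p < 1
  term <- (cc - a) * (cc - b) - cc * (1 - cc) / (n_c - 1)
  term <- term[ok]
  blocks <- paste0(gm$variants$chrom, "_",
                   floor((gm$variants$pos - 1) / block_size_bp))[ok]
  f3 <- mean(term)
  ub <- unique(blocks)
  if (length(ub) < 2) {
    warning("fewer than 2 jackknife blocks; SE undefined")
    return(structure(list(f3 = f3, se = NA_real_, z = NA_real_,
                          n_blocks = length(ub), n_variants = length(term)),
                     class = "f3_result"))
  }
  loo <- vapply(ub, function(bk) mean(term[blocks != bk]), numeric(1))
  B <- length(ub)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  structure(list(f3 = f3, se = se, z = if (se > 0) f3 / se else NA_real_,
                 n_blocks = B, n_variants = length(term)),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3 = %.6f  se = %.6f  z = %.3f  (%d variants, %d blocks)\n",
              x$f3, x$se, x$z, x$n_variants, x$n_blocks))
  invisible(x)
}
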