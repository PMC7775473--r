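# threshold flagging the top ceiling(q * n) values of x (NA-safe)
top_fraction_flag <- function(x, q, decreasing = TRUE) {
  flag <- rep(FALSE, length(x))
  ok <- which(is.finite(x))
  if (!length(ok)) return(flag)
  k <- ceiling(q * length(ok))
  if (k < 1) return(flag)
  thr <- sort(x[ok], decreasing = decreasing)[k]
  flag[ok] <- if (decreasing) x[ok] >= thr else x[ok] <= thr
  flag
}

#' Flag selection candidates from the Fst and XP-EHH tracks
#'
#' `fst_top` flags variants in the top `q` fraction of defined Fst
#' values. `xpehh_top` flags, in `high_tail` mode, the top `q` fraction
#' of *positive* standardised XP-EHH values (extreme homozygosity in
#' population A), or in `low_tail` mode the bottom `q` fraction of
#' negative values. `overlap_candidate` requires both flags.
#'
#' @param records `data.frame` with columns `chrom`, `pos`, `fst`,
#'   `xpehh_std` on a shared variant set.
#' @param q Tail fraction (default 0.05).
#' @param mode `"high_tail"` or `"low_tail"`.
#' @return `records` with logical columns `fst_top`, `xpehh_top`,
#'   `overlap_candidate` appended.
#' @export
candidate_overlap <- function(records, q = 0.05,
                              mode = c("high_tail", "low_tail")) {
  mode <- match.arg(mode)
  stopifnot(all(c("fst", "xpehh_std") %in% names(records)))
  records$fst_top <- top_fraction_flag(records$fst, q)
  x <- records$xpehh_std
  if (mode == "high_tail") {
    pos_only <- ifelse(!is.na(x) & x > 0, x, NA_real_)
    records$xpehh_top <- top_fraction_flag(pos_only, q, decreasing = TRUE)
  } else {
    neg_only <- ifelse(!is.na(x) & x < 0, x, NA_real_)
    records$xpehh_top <- top_fraction_flag(neg_only, q, decreasing = FALSE)
  }
  records$overlap_candidate <- records$fst_top & records$xpehh_top
  records
}

#' Merge candidate variants into regions
#'
#' Optional convenience: candidate variants closer than `merge_bp` on
#' the same chromosome are merged into one region (the merge distance is
#' an arbitrary reporting choice, not part of the candidate call).
#'
#' @param records Output of [candidate_overlap()].
#' @param merge_bp Merge distance (default 100 kb).
#' @return `data.frame(chrom, start, end, n_snps)`, 1-based inclusive.
#' @export
candidate_regions <- function(records, merge_bp = 1e5) {
  cand <- records[records$overlap_candidate, c("chrom", "pos")]
  if (!nrow(cand)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0)))
  }
  cand <- cand[order(cand$chrom, cand$pos), ]
  out <- list()
  for (chrom in unique(cand$chrom)) {
    p <- cand$pos[cand$chrom == chrom]
    grp <- cumsum(c(1, diff(p) > merge_bp))
    for (gi in unique(grp)) {
      pp <- p[grp == gi]
      out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = min(pp),
                                            end = max(pp),
                                            n_snps = length(pp))
    }
  }
  do.call(rbind, out)
}

#' Genes fully contained in windows around candidate variants
#'
#' A gene qualifies when its *entire* span lies within +/- `flank` of at
#' least one candidate variant; genes straddling a window edge are
#' excluded. Duplicates are collapsed.
#'
#' @param candidates `data.frame` with `chrom`, `pos` (candidate
#'   variants only).
#' @param genes Gene table from [read_gene_annotation()] (`seqid`,
#'   `start`, `end`, `id`).
#' @param flank Window half-width in bp (default 50,000).
#' @return Character vector of unique gene ids, in annotation order.
#' @export
genes_in_windows <- function(candidates, genes, flank = 5e4) {
  if (!nrow(candidates) || !nrow(genes)) return(character(0))
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    p <- candidates$pos[candidates$chrom == genes$seqid[i]]
    # entire-gene rule: gene.start >= pos - flank and gene.end <= pos + flank
    any(p >= genes$end[i] - flank & p <= genes$start[i] + flank)
  }, logical(1))
  unique(genes$id[hit])
}

#' One-sided Fisher (hypergeometric) term enrichment
#'
#' For each annotation term, tests whether candidate genes carry the
#' term more often than expected from the background, by the
#' hypergeometric upper tail; p-values are Benjamini-Hochberg adjusted
#' across terms. This is a flat test: no term-hierarchy weighting.
#'
#' @param candidate_genes Character vector, subset of
#'   `background_genes`.
#' @param background_genes Character vector of all tested genes.
#' @param term_map `data.frame(gene, term)` mapping genes to terms;
#'   terms with no background gene are skipped.
#' @param top_k Rows to mark in the `top` slice (default 10).
#' @return List with `table` (`data.frame(term, n_candidate,
#'   n_background, odds_ratio, p, p_adj)` sorted by p) and `top` (head
#'   of `table`).
#' @export
fisher_enrichment <- function(candidate_genes, background_genes, term_map,
                              top_k = 10) {
  candidate_genes <- unique(candidate_genes)
  background_genes <- unique(background_genes)
  if (!all(candidate_genes %in% background_genes)) {
    stop("candidate genes must be a subset of the background")
  }
  if (!nrow(term_map)) {
    empty <- data.frame(term = character(0), n_candidate = integer(0),
                        n_background = integer(0), odds_ratio = numeric(0),
                        p = numeric(0), p_adj = numeric(0))
    return(list(table = empty, top = empty))
  }
  term_map <- term_map[term_map$gene %in% background_genes, , drop = FALSE]
  N <- length(background_genes)
  n <- length(candidate_genes)
  terms <- unique(term_map$term)
  rows <- lapply(terms, function(tm) {
    tg <- unique(term_map$gene[term_map$term == tm])
    K <- length(tg)
    if (K == 0) return(NULL)
    k <- length(intersect(tg, candidate_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    orr <- (k * (N - n - K + k)) / ((n - k) * (K - k))
    data.frame(term = tm, n_candidate = k, n_background = K,
               odds_ratio = orr, p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, top = utils::head(tab, top_k))
}
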