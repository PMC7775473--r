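# Extended haplotype homozygosity along one direction from a core site.
# H: haplotype matrix restricted to one chromosome, pos: its positions,
# core_j: core column index within the chromosome. Preallocated walk:
# this sits in the inner loop of the genome-wide scan.
ehh_side <- function(H, pos, core_j, direction, cutoff, max_gap) {
  n <- nrow(H)
  step <- if (direction == "left") -1L else 1L
  if (n < 2) {
    return(list(points = data.frame(distance = 0, pos = pos[core_j], ehh = 1),
                truncated = FALSE, gap_terminated = FALSE, undefined = TRUE))
  }
  cap <- if (direction == "left") core_j else length(pos) - core_j + 1L
  dist_v <- numeric(cap); pos_v <- numeric(cap); ehh_v <- numeric(cap)
  dist_v[1] <- 0; pos_v[1] <- pos[core_j]; ehh_v[1] <- 1
  k <- 1L
  denom <- n * (n - 1) / 2
  group <- rep(1L, n)
  j <- core_j
  prev_pos <- pos[core_j]
  truncated <- FALSE; gap_terminated <- FALSE
  repeat {
    j <- j + step
    if (j < 1L || j > length(pos)) { truncated <- TRUE; break }
    if (abs(pos[j] - prev_pos) > max_gap) { gap_terminated <- TRUE; break }
    key <- group * 2L + H[, j]
    group <- match(key, unique(key))
    tab <- tabulate(group)
    ehh <- sum(tab * (tab - 1)) / 2 / denom
    k <- k + 1L
    dist_v[k] <- abs(pos[j] - pos[core_j]); pos_v[k] <- pos[j]
    ehh_v[k] <- ehh
    prev_pos <- pos[j]
    if (ehh < cutoff) break
  }
  list(points = data.frame(distance = dist_v[seq_len(k)],
                           pos = pos_v[seq_len(k)], ehh = ehh_v[seq_len(k)]),
       truncated = truncated, gap_terminated = gap_terminated,
       undefined = FALSE)
}

# integral-only walk used by the scan: no points frame is materialised
ehh_integral <- function(H, pos, core_j, step, cutoff, max_gap) {
  n <- nrow(H)
  if (n < 2) return(NA_real_)
  denom <- n * (n - 1) / 2
  group <- rep(1L, n)
  j <- core_j
  prev_pos <- pos[core_j]
  prev_ehh <- 1
  prev_dist <- 0
  area <- 0
  repeat {
    j <- j + step
    if (j < 1L || j > length(pos)) break
    if (abs(pos[j] - prev_pos) > max_gap) break
    key <- group * 2L + H[, j]
    group <- match(key, unique(key))
    tab <- tabulate(group)
    ehh <- sum(tab * (tab - 1)) / 2 / denom
    d <- abs(pos[j] - pos[core_j])
    area <- area + (d - prev_dist) * (ehh + prev_ehh) / 2
    prev_dist <- d; prev_ehh <- ehh; prev_pos <- pos[j]
    if (ehh < cutoff) break
  }
  area
}

#' EHH decay curves around a core variant
#'
#' Extended haplotype homozygosity: at each successive variant outward
#' from the core, haplotypes (optionally restricted to carriers of one
#' core allele) are partitioned by their extended sequence and
#' `EHH = sum_k C(n_k, 2) / C(n, 2)`. The walk stops when EHH falls
#' below `cutoff`, at the chromosome end (`truncated`), or when the next
#' inter-variant gap exceeds `max_gap` (`gap_terminated`).
#'
#' @param hp A [hap_panel()].
#' @param core_variant Variant index (into `hp$variants`).
#' @param allele_class Optional core allele (0 or 1); `NULL` uses all
#'   haplotypes (the combined curve integrated for XP-EHH).
#' @param ids Optional sample ids restricting the panel.
#' @param cutoff EHH value below which the walk stops (default 0.05).
#' @param max_gap Maximum tolerated inter-variant gap in bp (default
#'   1,500,000).
#' @return List with `left` and `right` curves (each: `points`
#'   data.frame with `distance`, `pos`, `ehh`; flags `truncated`,
#'   `gap_terminated`, `undefined`) plus `core_pos` and `chrom`.
#' @export
ehh_decay <- function(hp, core_variant, allele_class = NULL, ids = NULL,
                      cutoff = 0.05, max_gap = 1.5e6) {
  H <- if (is.null(ids)) hp$haps else hp$haps[hap_rows(hp, ids), , drop = FALSE]
  chrom <- hp$variants$chrom[core_variant]
  vi <- which(hp$variants$chrom == chrom)
  Hc <- H[, vi, drop = FALSE]
  core_j <- match(core_variant, vi)
  if (!is.null(allele_class)) {
    Hc <- Hc[Hc[, core_j] == allele_class, , drop = FALSE]
  }
  pos <- hp$variants$pos[vi]
  list(left = ehh_side(Hc, pos, core_j, "left", cutoff, max_gap),
       right = ehh_side(Hc, pos, core_j, "right", cutoff, max_gap),
       core_pos = pos[core_j], chrom = chrom)
}

# trapezoidal integral of one EHH side over physical distance
ihh_side <- function(side) {
  p <- side$points
  if (nrow(p) < 2) return(0)
  sum(diff(p$distance) * (utils::head(p$ehh, -1) + utils::tail(p$ehh, -1)) / 2)
}

#' Integrated EHH (iHH) for one population at one core
#' @keywords internal
ihh_at_core <- function(hp, core_variant, ids, cutoff, max_gap) {
  d <- ehh_decay(hp, core_variant, allele_class = NULL, ids = ids,
                 cutoff = cutoff, max_gap = max_gap)
  if (d$left$undefined || d$right$undefined) return(NA_real_)
  ihh_side(d$left) + ihh_side(d$right)
}

#' Cross-population EHH (XP-EHH) scan
#'
#' For each core variant, the combined-allele EHH curve of each
#' population is integrated over physical distance (left plus right,
#' truncation at chromosome ends permitted, walks stopped at gaps larger
#' than `max_gap`), and the raw score is `ln(iHH_A / iHH_B)`. Positive
#' scores mean longer haplotype homozygosity in population A. Cores
#' where either integral is zero or undefined are returned `NA` and
#' excluded from standardisation.
#'
#' @param hp A [hap_panel()] (phased; unphased genotype input is
#'   rejected upstream).
#' @param popA_ids,popB_ids Sample id sets (>= 2 diploids each).
#' @param cutoff,max_gap As in [ehh_decay()].
#' @return `data.frame(chrom, pos, xpehh_raw)` aligned to
#'   `hp$variants`.
#' @export
xpehh_scan <- function(hp, popA_ids, popB_ids, cutoff = 0.05,
                       max_gap = 1.5e6) {
  if (length(popA_ids) < 2 || length(popB_ids) < 2) {
    stop("each population needs >=2 diploid samples")
  }
  HA <- hp$haps[hap_rows(hp, popA_ids), , drop = FALSE]
  HB <- hp$haps[hap_rows(hp, popB_ids), , drop = FALSE]
  m <- nrow(hp$variants)
  raw <- rep(NA_real_, m)
  for (chrom in unique(hp$variants$chrom)) {
    vi <- which(hp$variants$chrom == chrom)
    pos <- hp$variants$pos[vi]
    HAc <- HA[, vi, drop = FALSE]
    HBc <- HB[, vi, drop = FALSE]
    for (j in seq_along(vi)) {
      ia <- ehh_integral(HAc, pos, j, -1L, cutoff, max_gap) +
        ehh_integral(HAc, pos, j, 1L, cutoff, max_gap)
      ib <- ehh_integral(HBc, pos, j, -1L, cutoff, max_gap) +
        ehh_integral(HBc, pos, j, 1L, cutoff, max_gap)
      if (is.finite(ia) && is.finite(ib) && ia > 0 && ib > 0) {
        raw[vi[j]] <- log(ia / ib)
      }
    }
  }
  data.frame(chrom = hp$variants$chrom, pos = hp$variants$pos,
             xpehh_raw = raw, stringsAsFactors = FALSE)
}

#' Standardise a scan track to mean 0, SD 1
#'
#' @param values Numeric vector (NA allowed; NA entries stay NA).
#' @return Standardised vector.
#' @export
standardize_scan <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("need >=2 defined values to standardise")
  s <- stats::sd(values[ok])
  if (s == 0) stop("zero standard deviation: cannot standardise")
  (values - mean(values[ok])) / s
}
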