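#' Identity-by-state counts for all sample pairs
#'
#' Counts sites by shared-allele state (IBS0/1/2) over jointly
#' non-missing calls, for every pair of samples. Exposed separately so
#' the moments estimator can be checked against a per-site tally.
#'
#' @param gm A [geno_matrix()].
#' @return List of symmetric integer matrices `ibs0`, `ibs1`, `ibs2`,
#'   `n_joint`.
#' @export
ibs_counts <- function(gm) {
  G <- gm$calls
  W <- !is.na(G)
  A0 <- (G == 0L) & W; A1 <- (G == 1L) & W; A2 <- (G == 2L) & W
  storage.mode(A0) <- storage.mode(A1) <- storage.mode(A2) <-
    storage.mode(W) <- "double"
  ibs2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  ibs0 <- A0 %*% t(A2) + A2 %*% t(A0)
  n_joint <- W %*% t(W)
  ibs1 <- n_joint - ibs0 - ibs2
  list(ibs0 = round(ibs0), ibs1 = round(ibs1), ibs2 = round(ibs2),
       n_joint = round(n_joint))
}

#' Method-of-moments IBD estimation for all sample pairs
#'
#' PLINK-style estimator: per pair, observed IBS0/IBS1/IBS2 site counts
#' are equated with their expectations under the three IBD states. The
#' per-site expected IBS probabilities use allele frequencies from the
#' full analysed sample with unbiased small-sample product corrections
#' (products of allele frequencies estimated by sampling allele counts
#' without replacement). The linear system is solved sequentially,
#' negative estimates are clipped to zero and the state probabilities
#' renormalised to a simplex point; pi-hat = z1/2 + z2.
#'
#' Sites that are monomorphic or have fewer than 4 called alleles carry
#' no information and are excluded. Missing data are handled
#' pairwise-complete.
#'
#' @param gm A [geno_matrix()], ideally LD-pruned and MAF-filtered.
#' @param min_sites Pairs with fewer jointly non-missing informative
#'   sites than this floor are flagged `unreliable` (default 100).
#' @return `data.frame` with one row per unordered pair: `id1`, `id2`,
#'   `z0`, `z1`, `z2`, `pi_hat`, `n_sites`, `unreliable`.
#' @export
estimate_ibd <- function(gm, min_sites = 100) {
  n_obs <- colSums(!is.na(gm$calls))
  x <- colSums(gm$calls, na.rm = TRUE)        # alt allele count
  tot <- 2 * n_obs
  valid <- tot >= 4 & x > 0 & x < tot
  if (!any(valid)) stop("no informative sites for IBD estimation")
  sub <- subset_variants(gm, valid)
  x <- x[valid]; tot <- tot[valid]
  y <- tot - x

  # unbiased estimators of allele-frequency products (sampling without
  # replacement from the 2n observed alleles)
  d2 <- tot * (tot - 1)
  d3 <- d2 * (tot - 2)
  d4 <- d3 * (tot - 3)
  p2q2 <- x * (x - 1) * y * (y - 1) / d4
  p3q <- x * (x - 1) * (x - 2) * y / d4
  pq3 <- x * y * (y - 1) * (y - 2) / d4
  p2q <- x * (x - 1) * y / d3
  pq2 <- x * y * (y - 1) / d3

  e00 <- 2 * p2q2                  # P(IBS0 | IBD0)
  e10 <- 4 * p3q + 4 * pq3         # P(IBS1 | IBD0)
  e20 <- pmax(1 - e00 - e10, 0)    # P(IBS2 | IBD0)
  e11 <- 2 * p2q + 2 * pq2         # P(IBS1 | IBD1)
  e21 <- pmax(1 - e11, 0)          # P(IBS2 | IBD1)

  cnt <- ibs_counts(sub)
  W <- (!is.na(sub$calls)) * 1
  pair_sum <- function(e) (W %*% (t(W) * e))
  E00 <- pair_sum(e00); E10 <- pair_sum(e10); E20 <- pair_sum(e20)
  E11 <- pair_sum(e11); E21 <- pair_sum(e21)

  z0 <- cnt$ibs0 / E00
  z1 <- (cnt$ibs1 - z0 * E10) / E11
  z2 <- (cnt$ibs2 - z0 * E20 - z1 * E21) / cnt$n_joint

  n <- nrow(sub$calls)
  ids <- sub$samples$id
  ut <- which(upper.tri(z0), arr.ind = TRUE)
  zm <- cbind(z0[ut], z1[ut], z2[ut])
  zm[!is.finite(zm)] <- 0
  zm[zm < 0] <- 0
  rs <- rowSums(zm)
  rs[rs == 0] <- 1
  zm <- zm / rs
  pi_hat <- pmin(pmax(zm[, 2] / 2 + zm[, 3], 0), 1)
  ns <- cnt$n_joint[ut]
  data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
             z0 = zm[, 1], z1 = zm[, 2], z2 = zm[, 3],
             pi_hat = pi_hat, n_sites = ns,
             unreliable = ns < min_sites,
             stringsAsFactors = FALSE)
}

#' Look up pi-hat for given pairs in an IBD table
#' @keywords internal
pair_pi_hat <- function(estimates, id1, id2) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  idx <- match(key(id1, id2), key(estimates$id1, estimates$id2))
  estimates$pi_hat[idx]
}
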