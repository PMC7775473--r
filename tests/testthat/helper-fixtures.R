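# Shared fixtures, all built in code. Expensive simulations are memoised
# so several test files can reuse one panel.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default-parameter panel (the "stated world") at a desk-scale marker count
default_sim <- function() {
  memo("default_sim", simulate_panel(sim_config(n_variants = 4000, seed = 101)))
}

# tiny hand-buildable genotype matrix
toy_gm <- function(calls, chrom = NULL, pos = NULL, ids = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  geno_matrix(calls, data.frame(chrom = chrom, pos = pos,
                                ref = rep("A", m), alt = rep("T", m)),
              data.frame(id = ids))
}

# unstructured Hardy-Weinberg panel: one population, known frequencies
hw_panel <- function(n, m, seed, p_range = c(0.1, 0.9)) {
  set.seed(seed)
  p <- runif(m, p_range[1], p_range[2])
  calls <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  toy_gm(calls)
}

# Mendelian families on unlinked sites: founders from HW, children by
# random allele transmission. Returns gm + parent-offspring pairs.
family_panel <- function(n_founders, n_children, m, seed) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  fh1 <- matrix(rbinom(n_founders * m, 1, rep(p, each = n_founders)),
                n_founders, m)
  fh2 <- matrix(rbinom(n_founders * m, 1, rep(p, each = n_founders)),
                n_founders, m)
  ids <- sprintf("F%03d", seq_len(n_founders))
  h1 <- fh1; h2 <- fh2
  pairs <- NULL
  kid_ids <- character(0)
  for (k in seq_len(n_children)) {
    par <- sample(n_founders, 2)
    # unlinked sites: each site independently picks one parental allele
    g1 <- ifelse(runif(m) < 0.5, fh1[par[1], ], fh2[par[1], ])
    g2 <- ifelse(runif(m) < 0.5, fh1[par[2], ], fh2[par[2], ])
    h1 <- rbind(h1, g1); h2 <- rbind(h2, g2)
    kid <- sprintf("K%03d", k)
    kid_ids <- c(kid_ids, kid)
    pairs <- rbind(pairs, data.frame(id1 = kid, id2 = ids[par[1]]),
                   data.frame(id1 = kid, id2 = ids[par[2]]))
  }
  gm <- toy_gm(h1 + h2, ids = c(ids, kid_ids))
  list(gm = gm, pairs = pairs, founder_ids = ids, kid_ids = kid_ids)
}

# independent variance-components Fst oracle: nested allele-count ANOVA
# (mean squares over alleles within individuals within populations),
# a different algebraic route than the direct a/b/c formulas.
fst_anova_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  r <- 2
  alleles <- function(g) cbind(as.integer(g >= 1), as.integer(g == 2))
  a1 <- alleles(g1); a2 <- alleles(g2)
  y <- c(t(a1), t(a2))                       # allele values, 2 per individual
  ind <- rep(seq_len(n1 + n2), each = 2)
  pop <- rep(c(1, 2), times = c(2 * n1, 2 * n2))
  ybar <- mean(y)
  pop_means <- tapply(y, pop, mean)
  ind_means <- tapply(y, ind, mean)
  n_al <- c(2 * n1, 2 * n2)
  ssp <- sum(n_al * (pop_means - ybar)^2)
  ssi <- sum(2 * (ind_means - pop_means[pop[seq(1, length(y), 2)]])^2)
  ssg <- sum((y - ind_means[ind])^2)
  msp <- ssp / (r - 1)
  msi <- ssi / (n1 + n2 - r)
  msg <- ssg / (n1 + n2)
  nc <- (2 * (n1 + n2) - (4 * n1^2 + 4 * n2^2) / (2 * (n1 + n2))) / (2 * (r - 1))
  s2_a <- (msp - msi) / (2 * nc)
  s2_b <- (msi - msg) / 2
  s2_w <- msg
  tot <- s2_a + s2_b + s2_w
  if (tot == 0) return(NA_real_)
  s2_a / tot
}

# pi-hat lookup for unordered pairs
pair_pi <- function(est, id1, id2) maluspop:::pair_pi_hat(est, id1, id2)

# squared genotype correlation, pairwise complete
geno_r2_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(0)
  cor(x[ok], y[ok])^2
}

# brute-force per-site IBS tally for one pair
ibs_tally_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  d <- abs(x[ok] - y[ok])
  c(ibs0 = sum(d == 2), ibs1 = sum(d == 1), ibs2 = sum(d == 0),
    n = sum(ok))
}
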