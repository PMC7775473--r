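#' Standardised-genotype kinship matrix
#'
#' `K = Z Z' / m` where `Z` holds genotypes centred by `2 p-hat` and
#' scaled by `sqrt(2 p-hat (1 - p-hat))` per variant (missing calls
#' imputed to the mean, i.e. zero after centring). Monomorphic variants
#' are dropped. Symmetric and positive semi-definite by construction.
#'
#' @param gm A MAF-filtered [geno_matrix()].
#' @return Symmetric numeric matrix with sample-id dimnames.
#' @export
kinship_matrix <- function(gm) {
  p <- allele_freq(gm)
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop("kinship error: all variants monomorphic")
  G <- gm$calls[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(G, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(gm$samples$id, gm$samples$id)
  K
}

# Fit y = X beta + u + e with u ~ N(0, sg2 K), via eigendecomposition of
# K; delta = se2/sg2 found by REML on the rotated model. Returns the
# pieces per-variant GLS needs plus ML/REML log-likelihoods.
lmm_fit <- function(y, X, eig, reml = TRUE) {
  n <- length(y)
  p <- ncol(X)
  ys <- crossprod(eig$vectors, y)
  Xs <- crossprod(eig$vectors, X)
  lambda <- pmax(eig$values, 0)
  nll <- function(log_delta) {
    v <- lambda + exp(log_delta)
    w <- 1 / v
    A <- crossprod(Xs, Xs * w)
    bvec <- crossprod(Xs, ys * w)
    beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    r <- ys - Xs %*% beta
    rss <- sum(r^2 * w)
    if (reml) {
      s2 <- rss / (n - p)
      0.5 * ((n - p) * log(s2) + sum(log(v)) +
               determinant(A, logarithm = TRUE)$modulus + (n - p))
    } else {
      s2 <- rss / n
      0.5 * (n * log(s2) + sum(log(v)) + n)
    }
  }
  opt <- stats::optimize(nll, c(-12, 12))
  delta <- exp(opt$minimum)
  v <- lambda + delta
  w <- 1 / v
  A <- crossprod(Xs, Xs * w)
  bvec <- crossprod(Xs, ys * w)
  beta <- solve(A, bvec)
  r <- ys - Xs %*% beta
  rss <- sum(r^2 * w)
  s2_ml <- rss / n
  ll_ml <- -0.5 * (n * log(2 * pi * s2_ml) + sum(log(v)) + n)
  list(delta = delta, beta = beta, rss = rss, ll_ml = ll_ml,
       ys = ys, Xs = Xs, w = w, lambda = lambda, eig = eig)
}

check_design <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
}

#' Kinship-corrected mixed-model association scan
#'
#' Single-variance-component linear mixed model
#' `y = covariates b + dosage b_g + u + e`, `u ~ N(0, sg2 K)`. The
#' variance ratio is estimated once on the null model by REML via the
#' eigendecomposition of K, then each variant is tested by generalised
#' least squares with a Wald t test (the population-parameters-
#' previously-determined shortcut). Binary phenotypes are treated as 0/1
#' quantitative responses. With `K = I` the model reduces exactly to
#' ordinary least squares.
#'
#' @param gm A [geno_matrix()].
#' @param phenotype Numeric (or 0/1) response named by sample id, or
#'   aligned to `gm$samples$id`; must be non-constant.
#' @param covariates Optional numeric matrix (e.g. first 3 PC scores),
#'   rows aligned to samples.
#' @param kinship Kinship matrix from [kinship_matrix()].
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return `data.frame(chrom, pos, effect, p, significant)` with
#'   attributes `delta` (variance ratio) and `m` (tested variants).
#' @export
lmm_scan <- function(gm, phenotype, covariates = NULL, kinship,
                     alpha = 0.05) {
  ids <- gm$samples$id
  y <- if (!is.null(names(phenotype))) phenotype[ids] else phenotype
  ok <- !is.na(y)
  if (!all(ok)) {
    gm <- subset_samples(gm, ids[ok])
    y <- y[ok]
    if (!is.null(covariates)) covariates <- covariates[ok, , drop = FALSE]
    kinship <- kinship[ids[ok], ids[ok]]
    ids <- ids[ok]
  }
  if (stats::var(y) == 0) stop("phenotype is constant")
  n <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  check_design(X0)
  eig <- eigen(kinship, symmetric = TRUE)
  null_fit <- lmm_fit(y, X0, eig, reml = TRUE)
  v <- null_fit$lambda + null_fit$delta
  w <- 1 / v
  ys <- null_fit$ys
  X0s <- null_fit$Xs

  G <- gm$calls
  p_freq <- allele_freq(gm)
  m <- ncol(G)
  eff <- rep(NA_real_, m); pv <- rep(NA_real_, m)
  Ut <- t(eig$vectors)
  p0 <- ncol(X0)
  for (j in seq_len(m)) {
    g <- G[, j]
    if (anyNA(g)) g[is.na(g)] <- 2 * p_freq[j]
    if (stats::var(g) == 0) next
    gs <- Ut %*% g
    Xs <- cbind(X0s, gs)
    A <- crossprod(Xs, Xs * w)
    bvec <- crossprod(Xs, ys * w)
    beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
    if (is.null(beta)) next
    r <- ys - Xs %*% beta
    rss <- sum(r^2 * w)
    df <- n - p0 - 1
    if (df <= 0) next
    s2 <- rss / df
    Ainv_gg <- tryCatch(solve(A)[p0 + 1, p0 + 1], error = function(e) NA)
    if (!is.finite(Ainv_gg) || Ainv_gg <= 0) next
    se <- sqrt(s2 * Ainv_gg)
    tval <- beta[p0 + 1] / se
    eff[j] <- beta[p0 + 1]
    pv[j] <- 2 * stats::pt(-abs(tval), df)
  }
  m_tested <- sum(!is.na(pv))
  out <- data.frame(chrom = gm$variants$chrom, pos = gm$variants$pos,
                    effect = eff, p = pv,
                    significant = !is.na(pv) & pv < alpha / max(m_tested, 1),
                    stringsAsFactors = FALSE)
  attr(out, "delta") <- null_fit$delta
  attr(out, "m") <- m_tested
  out
}

#' Stepwise multi-locus mixed-model scan with EBIC selection
#'
#' Iteratively adds the current smallest-p variant as a fixed cofactor,
#' refits the mixed model, and records the extended Bayesian information
#' criterion `EBIC = -2 logLik_ML + k log n + 2 gamma log C(m, k)` for
#' each step (gamma = 1). The scan of the EBIC-optimal model is
#' returned; cofactor variants are excluded from their own test.
#'
#' @inheritParams lmm_scan
#' @param max_steps Maximum cofactors to add (>= 1).
#' @param gamma EBIC genome-size penalty weight (default 1).
#' @return List of class `mlmm_trace`: `steps` (cofactor variant ids in
#'   order), `ebic_per_step` (step 0 = no cofactor), `optimal_step`,
#'   `cofactors` (ids in the optimal model), `scan` (AssocRecord
#'   data.frame of the optimal model).
#' @export
mlmm_stepwise <- function(gm, phenotype, covariates = NULL, kinship,
                          max_steps = 5, alpha = 0.05, gamma = 1) {
  if (max_steps < 1) stop("input error: max_steps must be >= 1")
  ids <- gm$samples$id
  y <- if (!is.null(names(phenotype))) phenotype[ids] else phenotype
  n <- length(y)
  m <- ncol(gm$calls)
  eig <- eigen(kinship, symmetric = TRUE)
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  check_design(X0)
  p_freq <- allele_freq(gm)
  dosage <- function(j) {
    g <- gm$calls[, j]
    if (anyNA(g)) g[is.na(g)] <- 2 * p_freq[j]
    g
  }
  ebic <- function(X, k) {
    fit <- lmm_fit(y, X, eig, reml = FALSE)
    -2 * fit$ll_ml + k * log(n) + 2 * gamma * lchoose(m, k)
  }
  vid <- paste0(gm$variants$chrom, ":", gm$variants$pos)
  cof_idx <- integer(0)
  ebics <- ebic(X0, 0)
  scans <- list()
  scan_with <- function(cof) {
    Xc <- X0
    if (length(cof)) {
      Xc <- cbind(X0, vapply(cof, dosage, numeric(n)))
      colnames(Xc) <- c(colnames(X0), vid[cof])
    }
    sc <- lmm_scan_with_base(gm, y, Xc, eig, alpha, exclude = cof)
    sc
  }
  scans[[1]] <- scan_with(integer(0))
  for (s in seq_len(max_steps)) {
    sc <- scans[[s]]
    cand <- which(!is.na(sc$p))
    cand <- setdiff(cand, cof_idx)
    if (!length(cand)) break
    best <- cand[which.min(sc$p[cand])]
    cof_idx <- c(cof_idx, best)
    Xc <- cbind(X0, vapply(cof_idx, dosage, numeric(n)))
    colnames(Xc) <- c(colnames(X0), vid[cof_idx])
    ebics <- c(ebics, ebic(Xc, length(cof_idx)))
    scans[[s + 1]] <- scan_with(cof_idx)
  }
  optimal_step <- which.min(ebics) - 1L
  structure(list(steps = vid[cof_idx],
                 ebic_per_step = ebics,
                 optimal_step = optimal_step,
                 cofactors = vid[cof_idx[seq_len(optimal_step)]],
                 scan = scans[[optimal_step + 1L]]),
            class = "mlmm_trace")
}

# per-variant GLS scan given a fixed base design (used by mlmm);
# cofactor variants in `exclude` get NA p.
lmm_scan_with_base <- function(gm, y, X0, eig, alpha, exclude = integer(0)) {
  n <- length(y)
  null_fit <- lmm_fit(y, X0, eig, reml = TRUE)
  w <- 1 / (null_fit$lambda + null_fit$delta)
  ys <- null_fit$ys
  X0s <- null_fit$Xs
  Ut <- t(eig$vectors)
  p0 <- ncol(X0)
  p_freq <- allele_freq(gm)
  m <- ncol(gm$calls)
  eff <- rep(NA_real_, m); pv <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    if (j %in% exclude) next
    g <- gm$calls[, j]
    if (anyNA(g)) g[is.na(g)] <- 2 * p_freq[j]
    if (stats::var(g) == 0) next
    Xs <- cbind(X0s, Ut %*% g)
    A <- crossprod(Xs, Xs * w)
    beta <- tryCatch(solve(A, crossprod(Xs, ys * w)),
                     error = function(e) NULL)
    if (is.null(beta)) next
    rss <- sum((ys - Xs %*% beta)^2 * w)
    df <- n - p0 - 1
    if (df <= 0) next
    Ainv_gg <- tryCatch(solve(A)[p0 + 1, p0 + 1], error = function(e) NA)
    if (!is.finite(Ainv_gg) || Ainv_gg <= 0) next
    se <- sqrt(rss / df * Ainv_gg)
    eff[j] <- beta[p0 + 1]
    pv[j] <- 2 * stats::pt(-abs(beta[p0 + 1] / se), df)
  }
  m_tested <- sum(!is.na(pv))
  data.frame(chrom = gm$variants$chrom, pos = gm$variants$pos,
             effect = eff, p = pv,
             significant = !is.na(pv) & pv < alpha / max(m_tested, 1),
             stringsAsFactors = FALSE)
}

#' Overlap of GWAS hits with the XP-EHH top tail
#'
#' Intersects Bonferroni-significant association records with variants
#' flagged in the selection-scan tail, on the shared variant universe.
#'
#' @param assoc_records Output of [lmm_scan()] (needs `chrom`, `pos`,
#'   `significant`).
#' @param scan_records Output of [candidate_overlap()] or any table with
#'   `chrom`, `pos`, `xpehh_top`.
#' @return `data.frame` of variants present in both sets, with the
#'   association p and the scan flag.
#' @export
scan_overlap <- function(assoc_records, scan_records) {
  key_a <- paste0(assoc_records$chrom, ":", assoc_records$pos)
  key_s <- paste0(scan_records$chrom, ":", scan_records$pos)
  sig <- assoc_records$significant
  top <- scan_records$xpehh_top[match(key_a, key_s)]
  sel <- which(sig & !is.na(top) & top)
  data.frame(chrom = assoc_records$chrom[sel],
             pos = assoc_records$pos[sel],
             p = assoc_records$p[sel],
             xpehh_top = rep(TRUE, length(sel)),
             stringsAsFactors = FALSE)
}

#' Probability that k random accessions are all homozygous
#'
#' Monte Carlo draws of `k` samples without replacement, counting the
#' fraction of draws in which every sampled accession is homozygous,
#' together with the exact hypergeometric probability
#' `prod_{i=0}^{k-1} (K - i) / (N - i)`.
#'
#' @param ids Panel sample ids (length N).
#' @param homozygous_flags Logical vector aligned to `ids` (K = number
#'   TRUE).
#' @param k Draw size (default 8).
#' @param n_draws Monte Carlo draws (default 10,000).
#' @param seed Optional integer seed.
#' @return List of class `resample_result`: `n_draws`, `k`,
#'   `observed_probability`, `exact_probability`.
#' @export
homozygote_resample <- function(ids, homozygous_flags, k = 8,
                                n_draws = 10000, seed = NULL) {
  N <- length(ids)
  stopifnot(length(homozygous_flags) == N)
  if (k > N) stop("input error: k exceeds panel size")
  if (!is.null(seed)) set.seed(seed)
  K <- sum(homozygous_flags)
  hits <- 0L
  for (d in seq_len(n_draws)) {
    if (all(homozygous_flags[sample.int(N, k)])) hits <- hits + 1L
  }
  exact <- if (K < k) 0 else prod((K - seq_len(k) + 1) / (N - seq_len(k) + 1))
  structure(list(n_draws = n_draws, k = k,
                 observed_probability = hits / n_draws,
                 exact_probability = exact),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("P(all %d homozygous): Monte Carlo %.4f (%d draws), exact %.6f\n",
              x$k, x$observed_probability, x$n_draws, x$exact_probability))
  invisible(x)
}
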