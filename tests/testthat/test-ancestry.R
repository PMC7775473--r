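two_pop_gm <- function(n_per = 25, m = 600, f = 0.2, seed = 41) {
  cfg <- sim_config(n_progenitor_a = n_per, n_progenitor_b = n_per,
                    n_derived = 2, n_variants = m, drift_f = f,
                    n_pedigree = 0, n_clones = 0, n_triploids = 0,
                    missing_rate = 0, sweep_spec = NULL, trait_spec = NULL,
                    seed = seed)
  st <- simulate_founders(simulate_frequencies(cfg), cfg)
  list(gm = haps_to_genotypes(hap_panel(st$haps, st$ids, st$variants)),
       ids_a = st$ids[st$pop == "A"], ids_b = st$ids[st$pop == "B"])
}

test_that("PC1 separates diverged reference populations without overlap", {
  tp <- two_pop_gm(n_per = 20, m = 800)
  model <- fit_reference_pca(tp$gm, tp$ids_a, tp$ids_b, n_components = 4)
  sc <- model$reference_scores[, 1]
  a <- sc[tp$ids_a]; b <- sc[tp$ids_b]
  expect_true(max(a) < min(b) || max(b) < min(a))
  expect_true(all(diff(model$explained_fraction) <= 1e-12))
  expect_lte(sum(model$explained_fraction), 1)
  # loadings orthonormal
  expect_equal(crossprod(model$loadings), diag(4), tolerance = 1e-8)
})

test_that("projection round-trips reference samples and scale invariance", {
  tp <- two_pop_gm(n_per = 12, m = 400, seed = 42)
  model <- fit_reference_pca(tp$gm, tp$ids_a, tp$ids_b, n_components = 3)
  proj <- project_onto_pca(model, tp$gm, ids = rownames(model$reference_scores))
  expect_equal(proj$scores, model$reference_scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_false(any(proj$low_confidence))
  # duplicated variant columns get identical loadings
  gm2 <- tp$gm
  j <- 5L
  gm2$calls <- cbind(gm2$calls, gm2$calls[, j])
  gm2$variants <- rbind(gm2$variants,
                        transform(gm2$variants[j, ], pos = max(gm2$variants$pos) + 1000))
  gm2 <- geno_matrix(gm2$calls, gm2$variants, gm2$samples)
  m2 <- fit_reference_pca(gm2, tp$ids_a, tp$ids_b, n_components = 3)
  dup_rows <- which(m2$variant_idx %in% c(j, ncol(gm2$calls)))
  expect_equal(m2$loadings[dup_rows[1], ], m2$loadings[dup_rows[2], ],
               tolerance = 1e-10)
})

test_that("projection handles missingness and degenerate samples", {
  tp <- two_pop_gm(n_per = 12, m = 400, seed = 43)
  model <- fit_reference_pca(tp$gm, tp$ids_a, tp$ids_b, n_components = 2)
  gm <- tp$gm
  victim <- gm$samples$id[1]
  gm$calls[1, seq(1, 400, 2)] <- NA          # 50% missing
  proj <- project_onto_pca(model, gm, ids = victim, min_overlap = 0.6)
  expect_true(proj$low_confidence[victim])
  expect_true(all(is.finite(proj$scores)))
  # all-missing single sample errors
  gm$calls[1, ] <- NA
  expect_error(project_onto_pca(model, gm, ids = victim), "no observed")
})

test_that("admixed samples project between the reference centroids", {
  sim <- simulate_panel(sim_config(n_variants = 1000, admixture_alpha = 0.5,
                                   n_pedigree = 0, n_clones = 0,
                                   n_triploids = 0, missing_rate = 0,
                                   sweep_spec = NULL, trait_spec = NULL,
                                   seed = 44))
  gm <- sim$genotypes
  a_ids <- gm$samples$id[gm$samples$species == "wild_a"]
  b_ids <- gm$samples$id[gm$samples$species == "wild_b"]
  d_ids <- gm$samples$id[gm$samples$species == "domesticated"]
  model <- fit_reference_pca(gm, a_ids, b_ids, n_components = 2)
  proj <- project_onto_pca(model, gm)
  ca <- mean(model$reference_scores[a_ids, 1])
  cb <- mean(model$reference_scores[b_ids, 1])
  dmean <- mean(proj$scores[d_ids, 1])
  expect_gt(dmean, min(ca, cb))
  expect_lt(dmean, max(ca, cb))
  # PC1 tracks realised ancestry dosage (parameter-recovery property)
  dose <- sim$truth$ancestry_dosage[d_ids]
  expect_gte(abs(cor(proj$scores[d_ids, 1], dose, method = "spearman")), 0.9)
})

test_that("projections order monotonically with admixture proportion", {
  mean_pc1 <- vapply(c(0.2, 0.5, 0.8), function(alpha) {
    sim <- simulate_panel(sim_config(n_derived = 30, n_variants = 800,
                                     admixture_alpha = alpha,
                                     n_pedigree = 0, n_clones = 0,
                                     n_triploids = 0, missing_rate = 0,
                                     sweep_spec = NULL, trait_spec = NULL,
                                     seed = 45))
    gm <- sim$genotypes
    model <- fit_reference_pca(gm,
                               gm$samples$id[gm$samples$species == "wild_a"],
                               gm$samples$id[gm$samples$species == "wild_b"],
                               n_components = 2)
    proj <- project_onto_pca(model, gm)
    mean(proj$scores[gm$samples$species == "domesticated", 1])
  }, numeric(1))
  expect_true(all(diff(mean_pc1) > 0) || all(diff(mean_pc1) < 0))
})

test_that("rank-sum test matches its boundary cases", {
  sc <- matrix(c(1:5, 11:15), ncol = 1,
               dimnames = list(paste0("s", 1:10), "PC1"))
  res <- rank_sum_compare(sc, paste0("s", 1:5), paste0("s", 6:10))
  expect_true(res$w %in% c(0, 25))
  expect_equal(res$p, 2 * (1 / choose(10, 5)))  # minimal two-sided exact p
  # identical multisets: p = 1
  sc2 <- matrix(rep(c(1, 2, 3), 2), ncol = 1,
                dimnames = list(paste0("t", 1:6), "PC1"))
  res2 <- rank_sum_compare(sc2, paste0("t", 1:3), paste0("t", 4:6))
  expect_equal(res2$p, 1)
  expect_error(rank_sum_compare(sc, character(0), "s1"), "empty")
  expect_error(rank_sum_compare(sc, c("s1", "s2"), c("s2", "s3")), "disjoint")
})

test_that("rank-sum type-I error is calibrated", {
  set.seed(46)
  rej <- vapply(1:1000, function(r) {
    sc <- matrix(rnorm(100), ncol = 1,
                 dimnames = list(paste0("s", 1:100), "PC1"))
    rank_sum_compare(sc, paste0("s", 1:50), paste0("s", 51:100))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("f3 is negative for an exact midpoint target", {
  # sources fixed for opposite alleles, target all heterozygous
  calls <- rbind(matrix(0L, 4, 50), matrix(2L, 4, 50), matrix(1L, 4, 50))
  gm <- toy_gm(calls, ids = sprintf("x%02d", 1:12))
  f3 <- f3_statistic(gm, sprintf("x%02d", 9:12), sprintf("x%02d", 1:4),
                     sprintf("x%02d", 5:8), block_size_bp = 10000)
  expect_lt(f3$f3, 0)
})

test_that("f3 shows no admixture signal for an unadmixed target", {
  # target drawn from the same population as source A
  cfg <- sim_config(n_progenitor_a = 60, n_progenitor_b = 30, n_derived = 2,
                    n_variants = 2000, drift_f = 0.2, n_pedigree = 0,
                    n_clones = 0, n_triploids = 0, missing_rate = 0,
                    sweep_spec = NULL, trait_spec = NULL, seed = 47)
  st <- simulate_founders(simulate_frequencies(cfg), cfg)
  gm <- haps_to_genotypes(hap_panel(st$haps, st$ids, st$variants))
  ids_a <- st$ids[st$pop == "A"]
  target <- ids_a[1:30]; src_a <- ids_a[31:60]
  src_b <- st$ids[st$pop == "B"]
  f3 <- f3_statistic(gm, target, src_a, src_b)
  expect_gt(f3$z, -3)    # not significantly negative
  expect_gt(f3$se, 0)
  expect_gte(f3$n_blocks, 2)
  # symmetry in the two sources
  f3_swap <- f3_statistic(gm, target, src_b, src_a)
  expect_equal(f3$f3, f3_swap$f3, tolerance = 1e-12)
})

test_that("f3 is clearly negative for a strongly admixed target", {
  sim <- simulate_panel(sim_config(n_variants = 2000, admixture_alpha = 0.5,
                                   drift_f = 0.3, n_pedigree = 0,
                                   n_clones = 0, n_triploids = 0,
                                   missing_rate = 0, sweep_spec = NULL,
                                   trait_spec = NULL, seed = 48))
  gm <- sim$genotypes
  f3 <- f3_statistic(gm, gm$samples$id[gm$samples$species == "domesticated"],
                     gm$samples$id[gm$samples$species == "wild_a"],
                     gm$samples$id[gm$samples$species == "wild_b"])
  expect_lt(f3$f3, 0)
  expect_lt(f3$z, -3)
})
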