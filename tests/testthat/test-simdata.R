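test_that("configuration invariants are enforced", {
  expect_error(sim_config(drift_f = 0), "drift_f")
  expect_error(sim_config(drift_f = 1.2), "drift_f")
  expect_error(sim_config(admixture_alpha = 1.5), "admixture_alpha")
  expect_error(sim_config(sweep_spec = list(population = "derived",
                                            chrom = "chr1", start_bp = 5e6,
                                            end_bp = 20e6,
                                            carrier_fraction = 0.9)),
               "sweep interval")
  expect_error(sim_config(sweep_spec = list(population = "derived",
                                            chrom = "chr1", start_bp = 1e6,
                                            end_bp = 2e6,
                                            carrier_fraction = 2)),
               "carrier_fraction")
})

test_that("Balding-Nichols frequencies behave at the drift limits", {
  cfg <- sim_config(n_variants = 2000, drift_f = 1e-4, seed = 1)
  fr <- simulate_frequencies(cfg)
  expect_lt(max(abs(fr$pa - fr$anc)), 0.05)    # no-drift limit
  expect_lt(max(abs(fr$pb - fr$anc)), 0.05)
  # determinism
  fr2 <- simulate_frequencies(cfg)
  expect_identical(fr, fr2)
})

test_that("realised Fst between progenitor samples tracks drift_f", {
  cfg <- sim_config(n_progenitor_a = 30, n_progenitor_b = 30, n_derived = 2,
                    n_variants = 10000, drift_f = 0.2, n_pedigree = 0,
                    n_clones = 0, n_triploids = 0, missing_rate = 0,
                    sweep_spec = NULL, trait_spec = NULL, seed = 2)
  fr <- simulate_frequencies(cfg)
  st <- simulate_founders(fr, cfg)
  gm <- haps_to_genotypes(hap_panel(st$haps, st$ids, st$variants))
  ids_a <- st$ids[st$pop == "A"]; ids_b <- st$ids[st$pop == "B"]
  fst <- weir_cockerham_fst(gm, ids_a, ids_b)
  # multi-locus (ratio-of-sums) Weir-Cockerham estimate tracks drift_f;
  # the mean of per-site ratios is biased low by site-level noise
  expect_lt(abs(global_fst(fst) - 0.2), 0.03)
})

test_that("admixture proportion is respected", {
  # alpha = 1: derived frequencies indistinguishable from popA
  cfg1 <- sim_config(n_derived = 50, n_variants = 800, admixture_alpha = 1,
                     n_pedigree = 0, n_clones = 0, n_triploids = 0,
                     missing_rate = 0, sweep_spec = NULL, trait_spec = NULL,
                     seed = 3)
  fr <- simulate_frequencies(cfg1)
  st <- simulate_founders(fr, cfg1)
  expect_true(all(st$ancestry_dosage[st$pop == "derived"] == 1))
  gm <- haps_to_genotypes(hap_panel(st$haps, st$ids, st$variants))
  ga <- gm$calls[st$pop == "A", ]; gd <- gm$calls[st$pop == "derived", ]
  ps <- vapply(seq_len(ncol(ga)), function(j) {
    suppressWarnings(prop.test(c(sum(ga[, j]), sum(gd[, j])),
                               c(2 * nrow(ga), 2 * nrow(gd)))$p.value)
  }, numeric(1))
  expect_lt(mean(ps < 0.05, na.rm = TRUE), 0.10)  # no excess rejections
  # alpha = 0.5: mean realised dosage near 0.5
  cfg2 <- sim_config(n_derived = 60, n_variants = 800,
                     admixture_alpha = 0.5, n_pedigree = 0, n_clones = 0,
                     n_triploids = 0, missing_rate = 0, sweep_spec = NULL,
                     trait_spec = NULL, seed = 4)
  st2 <- simulate_founders(simulate_frequencies(cfg2), cfg2)
  expect_gt(mean(st2$ancestry_dosage[st2$pop == "derived"]), 0.45)
  expect_lt(mean(st2$ancestry_dosage[st2$pop == "derived"]), 0.55)
})

test_that("genotypes equal haplotype sums and Mendelian transmission holds", {
  sim <- simulate_panel(sim_config(n_variants = 600, missing_rate = 0,
                                   n_clones = 0, n_triploids = 0, seed = 5))
  hp <- sim$haplotypes
  gm_h <- haps_to_genotypes(hp)
  shared <- intersect(sim$genotypes$samples$id, hp$sample_ids)
  expect_equal(sim$genotypes$calls[shared, ], gm_h$calls[shared, ])
  # no opposing homozygotes between child and parent
  ped <- sim$truth$pedigree_edges
  for (i in sample(nrow(ped), 10)) {
    gk <- gm_h$calls[ped$child[i], ]
    gp <- gm_h$calls[ped$parent[i], ]
    expect_equal(sum(gk == 0 & gp == 2) + sum(gk == 2 & gp == 0), 0)
  }
})

test_that("full sibs share about half their genome", {
  cfg <- sim_config(n_variants = 1200, n_derived = 20, n_pedigree = 0,
                    n_clones = 0, n_triploids = 0, missing_rate = 0,
                    sweep_spec = NULL, trait_spec = NULL, seed = 6)
  fr <- simulate_frequencies(cfg)
  st <- simulate_founders(fr, cfg)
  # 60 sib pairs: two children per founder couple
  ped <- data.frame(child = sprintf("S%03d", 1:120),
                    parent1 = rep(sprintf("D%03d", seq(1, 19, 2)), 12),
                    parent2 = rep(sprintf("D%03d", seq(2, 20, 2)), 12))
  st <- breed_pedigree(st, ped)
  gm <- haps_to_genotypes(hap_panel(st$haps, st$ids, st$variants))
  ibd <- estimate_ibd(gm)
  sib_pairs <- t(combn(sprintf("S%03d", 1:10), 2))  # same couple: 1..10? no
  # children i and i+60 share the same parent pair
  sib <- pair_pi(ibd, sprintf("S%03d", 1:60), sprintf("S%03d", 61:120))
  expect_gt(mean(sib, na.rm = TRUE), 0.40)
  expect_lt(mean(sib, na.rm = TRUE), 0.60)
})

test_that("children of two popA founders have ancestry dosage 1", {
  cfg <- sim_config(n_variants = 300, n_pedigree = 0, n_clones = 0,
                    n_triploids = 0, missing_rate = 0, sweep_spec = NULL,
                    trait_spec = NULL, seed = 7)
  st <- simulate_founders(simulate_frequencies(cfg), cfg)
  st <- breed_pedigree(st, data.frame(child = "X1", parent1 = "PA001",
                                      parent2 = "PA002"))
  expect_equal(unname(st$ancestry_dosage["X1"]), 1)
  expect_error(breed_pedigree(st, data.frame(child = "X2", parent1 = "NOPE",
                                             parent2 = "PA001")),
               "unknown parent")
})

test_that("artifacts: clones, triploids and missingness", {
  # error_rate 0, missing_rate 0 -> clone identical to source
  cfg <- sim_config(n_variants = 500, n_pedigree = 0,
                    clone_spec = data.frame(source = "D001", clone = "C001",
                                            error_rate = 0),
                    n_triploids = 0, missing_rate = 0, seed = 8)
  sim <- simulate_panel(cfg)
  expect_equal(sim$genotypes$calls["C001", ], sim$genotypes$calls["D001", ],
               ignore_attr = TRUE)
  expect_error(
    simulate_panel(sim_config(n_variants = 50, n_pedigree = 0,
                              clone_spec = data.frame(source = "ZZZ",
                                                      clone = "C001",
                                                      error_rate = 0),
                              n_triploids = 0, seed = 8)),
    "unknown source")
  # triploid heterozygosity exceeds diploid (one-sided test, >=20 each)
  cfg3 <- sim_config(n_variants = 1000, n_derived = 60, n_pedigree = 0,
                     n_clones = 0, n_triploids = 25, missing_rate = 0,
                     seed = 9)
  sim3 <- simulate_panel(cfg3)
  het <- heterozygosity(sim3$genotypes)$sample
  tri <- names(sim3$truth$ploidy_map)[sim3$truth$ploidy_map == "3x"]
  dip <- sim3$genotypes$samples$id[
    sim3$genotypes$samples$species == "domesticated" &
      !(sim3$genotypes$samples$id %in% tri)]
  tt <- t.test(het[tri], het[dip], alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
  # missing_rate 0.1 -> overall missing fraction within 0.01
  cfg4 <- sim_config(n_variants = 2000, missing_rate = 0.1, seed = 10)
  sim4 <- simulate_panel(cfg4)
  expect_lt(abs(mean(is.na(sim4$genotypes$calls)) - 0.1), 0.01)
})

test_that("sweep and trait injection honour their degenerate settings", {
  cfg <- sim_config(n_variants = 1000, n_chromosomes = 2,
                    chrom_length_bp = 5e6, n_pedigree = 0, n_clones = 0,
                    n_triploids = 0, missing_rate = 0,
                    sweep_spec = list(population = "derived", chrom = "chr1",
                                      start_bp = 2e6, end_bp = 3e6,
                                      carrier_fraction = 1),
                    trait_spec = list(causal_variant_index = NA,
                                      penetrance = 1, background_rate = 0),
                    seed = 11)
  sim <- simulate_panel(cfg)
  hp <- sim$haplotypes
  der <- sim$genotypes$samples$id[
    sim$genotypes$samples$species == "domesticated"]
  vi <- which(hp$variants$chrom == "chr1" & hp$variants$pos >= 2e6 &
                hp$variants$pos <= 3e6)
  H <- hp$haps[maluspop:::hap_rows(hp, der), vi]
  expect_equal(nrow(unique(H)), 1L)   # carrier_fraction 1: one haplotype
  # penetrance 1 / background 0: phenotype = indicator(dosage >= 1)
  ci <- sim$truth$causal_variant
  g <- haps_to_genotypes(hp)$calls[, ci]
  expect_equal(unname(sim$truth$phenotype[hp$sample_ids]),
               unname(as.integer(g >= 1)))
})

test_that("identical configs give byte-identical emitted panels", {
  cfg <- sim_config(n_variants = 400, seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim(simulate_panel(cfg), d1)
  write_sim(simulate_panel(cfg), d2)
  for (f in c("genotypes.vcf", "haplotypes.vcf", "samples.tsv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # dosage bounds
  sim <- simulate_panel(cfg)
  vals <- sim$genotypes$calls[!is.na(sim$genotypes$calls)]
  expect_true(all(vals %in% 0:2))
})
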