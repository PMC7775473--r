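test_that("Fst hits its analytic boundary cases", {
  # populations fixed for alternate alleles -> theta = 1
  gm <- toy_gm(rbind(matrix(0L, 5, 10), matrix(2L, 5, 10)))
  fst <- weir_cockerham_fst(gm, sprintf("S%02d", 1:5), sprintf("S%02d", 6:10))
  expect_equal(fst$fst, rep(1, 10))
  # identical-composition halves of one panel -> mean near 0
  gm2 <- hw_panel(60, 6000, seed = 51)
  fst2 <- weir_cockerham_fst(gm2, sprintf("S%02d", 1:30),
                             sprintf("S%02d", 31:60))
  expect_lt(abs(mean(fst2$fst, na.rm = TRUE)), 0.01)
})

test_that("Fst matches the worked single-site oracle to 1e-10", {
  # n1 = n2 = 10, p1 = 0.8, p2 = 0.2, observed het 0.4 each
  # (het 0.32 is not realisable with 10 individuals; 4/10 het is)
  g1 <- c(rep(2L, 6), rep(1L, 4))               # p = 0.8, het 0.4
  g2 <- c(rep(0L, 6), rep(1L, 4))               # p = 0.2, het 0.4
  gm <- toy_gm(cbind(c(g1, g2)), ids = sprintf("S%02d", 1:20))
  fst <- weir_cockerham_fst(gm, sprintf("S%02d", 1:10), sprintf("S%02d", 11:20))
  oracle <- fst_anova_oracle(g1, g2)
  expect_equal(fst$fst, oracle, tolerance = 1e-10)
})

test_that("Fst equals the ANOVA oracle on exhaustive tiny configurations", {
  # every genotype configuration for 2 samples per population
  confs <- expand.grid(a1 = 0:2, a2 = 0:2, b1 = 0:2, b2 = 0:2)
  ids <- c("p1", "p2", "q1", "q2")
  for (i in seq_len(nrow(confs))) {
    g <- as.integer(confs[i, ])
    gm <- toy_gm(cbind(g), ids = ids)
    fst <- weir_cockerham_fst(gm, c("p1", "p2"), c("q1", "q2"))$fst
    oracle <- fst_anova_oracle(g[1:2], g[3:4])
    expect_equal(fst, oracle, tolerance = 1e-10,
                 label = paste("config", paste(g, collapse = "")))
  }
})

mini_hp <- function(haps, pos, chrom = "chr1") {
  n <- nrow(haps) / 2
  hap_panel(haps, sprintf("H%02d", seq_len(n)),
            data.frame(chrom = chrom, pos = pos,
                       ref = rep("A", length(pos)), alt = rep("T", length(pos))))
}

test_that("EHH decay obeys its defining identities", {
  # identical carrier haplotypes: EHH stays 1, integral = spanned length
  haps <- matrix(rep(c(1L, 0L, 1L, 0L), 6), nrow = 6, byrow = TRUE)
  hp <- mini_hp(haps, pos = c(100, 200, 300, 400))
  d <- ehh_decay(hp, core_variant = 2)
  expect_equal(d$left$points$ehh[1], 1)          # EHH(0) = 1 by definition
  expect_true(all(d$right$points$ehh == 1))
  expect_true(d$right$truncated)
  # carriers pairwise distinct at the first flank: EHH = 0 there
  # (two carriers of the core allele, opposite alleles at the flank)
  haps2 <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 0L, 1L), c(0L, 1L, 1L))
  hp2 <- mini_hp(haps2, pos = c(100, 200, 300))
  d2 <- ehh_decay(hp2, core_variant = 1, allele_class = 1)
  expect_equal(d2$right$points$ehh[2], 0)
  # monotone non-increasing
  set.seed(52)
  haps3 <- matrix(rbinom(20 * 30, 1, 0.5), 20, 30)
  hp3 <- mini_hp(haps3, pos = sort(sample(1e5, 30)))
  d3 <- ehh_decay(hp3, core_variant = 15)
  expect_true(all(diff(d3$right$points$ehh) <= 1e-12))
  expect_true(all(diff(d3$left$points$ehh) <= 1e-12))
  # gap termination
  hp4 <- mini_hp(haps, pos = c(100, 200, 2e6 + 300, 2e6 + 400))
  d4 <- ehh_decay(hp4, core_variant = 2, max_gap = 1.5e6)
  expect_true(d4$right$gap_terminated)
  # single carrier haplotype: undefined
  hp5 <- mini_hp(rbind(c(1L, 0L), c(0L, 1L), c(0L, 0L), c(0L, 1L)),
                 pos = c(100, 200))
  d5 <- ehh_decay(hp5, core_variant = 1, allele_class = 1)
  expect_true(d5$left$undefined)
})

test_that("XP-EHH is zero on identical panels and antisymmetric", {
  set.seed(53)
  haps <- matrix(rbinom(16 * 40, 1, 0.5), 16, 40)
  pos <- sort(sample(2e6, 40))
  hpA <- mini_hp(rbind(haps, haps), pos)   # 16 samples, two identical halves
  idsA <- sprintf("H%02d", 1:8); idsB <- sprintf("H%02d", 9:16)
  xp <- xpehh_scan(hpA, idsA, idsB)
  expect_equal(xp$xpehh_raw[!is.na(xp$xpehh_raw)],
               rep(0, sum(!is.na(xp$xpehh_raw))))
  # antisymmetry under population swap
  sim <- simulate_panel(sim_config(n_variants = 300, n_chromosomes = 1,
                                   n_pedigree = 0, n_clones = 0,
                                   n_triploids = 0, missing_rate = 0,
                                   seed = 54))
  hp <- sim$haplotypes
  a <- sim$genotypes$samples$id[sim$genotypes$samples$species == "wild_a"]
  b <- sim$genotypes$samples$id[sim$genotypes$samples$species == "wild_b"]
  x1 <- xpehh_scan(hp, a, b)$xpehh_raw
  x2 <- xpehh_scan(hp, b, a)$xpehh_raw
  expect_equal(x1, -x2, tolerance = 1e-12)
})

test_that("a simulated sweep yields the genome-wide XP-EHH maximum", {
  sim <- simulate_panel(sim_config(n_variants = 1200, n_chromosomes = 3,
                                   n_pedigree = 0, n_clones = 0,
                                   n_triploids = 0, missing_rate = 0,
                                   seed = 55))
  hp <- sim$haplotypes
  sm <- sim$genotypes$samples
  A <- sm$id[sm$species == "domesticated"]
  B <- sm$id[sm$species == "wild_a"]
  xp <- xpehh_scan(hp, A, B)
  std <- standardize_scan(xp$xpehh_raw)
  sw <- sim$truth$sweep_interval
  imax <- which.max(std)
  expect_equal(xp$chrom[imax], sw$chrom)
  expect_gte(xp$pos[imax], sw$start_bp)
  expect_lte(xp$pos[imax], sw$end_bp)
  expect_gt(std[imax], 0)
})

test_that("standardisation behaves and fails as specified", {
  x <- c(1, 2, 3, NA, 5)
  s <- standardize_scan(x)
  expect_equal(mean(s, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sd(s, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_true(is.na(s[4]))
  expect_error(standardize_scan(rep(2, 10)), "zero standard deviation")
  expect_equal(standardize_scan(10 + 3 * x), s)   # affine invariance
})

test_that("candidate overlap flags follow the tail rules", {
  set.seed(56)
  n <- 200
  rec <- data.frame(chrom = "chr1", pos = seq_len(n) * 1000,
                    fst = runif(n), xpehh_std = rnorm(n))
  out <- candidate_overlap(rec, q = 0.05, mode = "high_tail")
  # brute-force check of both flags
  expect_equal(which(out$fst_top),
               which(rank(-rec$fst) <= ceiling(0.05 * n)))
  pos_vals <- rec$xpehh_std[rec$xpehh_std > 0]
  k <- ceiling(0.05 * length(pos_vals))
  thr <- sort(pos_vals, decreasing = TRUE)[k]
  expect_equal(which(out$xpehh_top), which(rec$xpehh_std >= thr))
  expect_equal(out$overlap_candidate, out$fst_top & out$xpehh_top)
  # identical rank order: candidate count = top-xpehh count (subset of fst top)
  rec2 <- data.frame(chrom = "chr1", pos = seq_len(n) * 1000,
                     fst = seq_len(n) / n, xpehh_std = seq_len(n) - n / 2)
  out2 <- candidate_overlap(rec2, q = 0.05, mode = "high_tail")
  n_pos <- sum(rec2$xpehh_std > 0)
  expect_equal(sum(out2$overlap_candidate),
               min(ceiling(0.05 * n_pos), sum(out2$fst_top)))
  # disjoint top sets give zero candidates
  rec3 <- data.frame(chrom = "chr1", pos = seq_len(n) * 1000,
                     fst = seq_len(n), xpehh_std = rev(seq_len(n)) - n / 2)
  expect_equal(sum(candidate_overlap(rec3, 0.05)$overlap_candidate), 0)
  # low tail mirrors on negative values
  out_low <- candidate_overlap(rec, q = 0.05, mode = "low_tail")
  expect_true(all(rec$xpehh_std[out_low$xpehh_top] < 0))
})

test_that("gene windows apply the entire-gene rule", {
  cand <- data.frame(chrom = "chr1", pos = 100000)
  genes <- data.frame(seqid = "chr1",
                      start = c(90000, 140000, 95000),
                      end = c(110000, 160000, 105000),
                      id = c("inside", "straddle", "inside2"))
  got <- genes_in_windows(cand, genes, flank = 5e4)
  expect_setequal(got, c("inside", "inside2"))   # straddler excluded
  # two candidates sharing a gene report it once
  cand2 <- rbind(cand, data.frame(chrom = "chr1", pos = 101000))
  expect_equal(sum(genes_in_windows(cand2, genes, 5e4) == "inside"), 1L)
  # wrong chromosome never matches
  genes_chr2 <- transform(genes, seqid = "chr2")
  expect_length(genes_in_windows(cand, genes_chr2, 5e4), 0)
})

test_that("gene annotation reading via rtracklayer round-trips a GFF3", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "gene", "1000", "2000", ".", "+", ".",
                     "ID=g1", sep = "\t"),
               paste("chr1", "src", "mRNA", "1000", "2000", ".", "+", ".",
                     "ID=t1;Parent=g1", sep = "\t"),
               paste("chr2", "src", "gene", "5000", "7000", ".", "-", ".",
                     "ID=g2", sep = "\t")), path)
  genes <- read_gene_annotation(path)
  expect_equal(genes$id, c("g1", "g2"))
  expect_equal(genes$start, c(1000, 5000))
  expect_equal(genes$end, c(2000, 7000))
})

test_that("Fisher enrichment matches the exact hypergeometric tail", {
  bg <- sprintf("g%04d", 1:1000)
  cand <- bg[1:10]
  tm <- data.frame(gene = c(bg[1:10], bg[501:520]),
                   term = c(rep("T_hit", 10), rep("T_null", 20)))
  res <- fisher_enrichment(cand, bg, tm)
  hit <- res$table[res$table$term == "T_hit", ]
  # all 10 candidates carry a term present in 10/1000 background genes
  expect_equal(hit$p, phyper(9, 10, 990, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(hit$p, 1 / choose(1000, 10), tolerance = 1e-9)
  expect_equal(res$table$p_adj, p.adjust(res$table$p, "BH"))
  # candidates = background -> all p = 1
  res2 <- fisher_enrichment(bg, bg, tm)
  expect_true(all(res2$table$p == 1))
  # empty term map -> empty report
  res3 <- fisher_enrichment(cand, bg, tm[0, ])
  expect_equal(nrow(res3$table), 0)
  expect_error(fisher_enrichment(c("zzz"), bg, tm), "subset")
})
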