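#' Simulation configuration
#'
#' Describes a synthetic germplasm panel: two wild progenitor populations
#' diverged under a Balding-Nichols model, a domesticated population
#' admixed from both in contiguous ancestry blocks, bred offspring,
#' clonal duplicates with genotyping error, triploids reported through a
#' diploid caller, one local selective sweep and one major-locus binary
#' trait.
#'
#' `pedigree_spec`, `clone_spec` and `triploid_ids` may be given either
#' explicitly or as counts (`n_pedigree`, `n_clones`, `n_triploids`), in
#' which case concrete ids are drawn under the simulation seed.
#'
#' @param n_progenitor_a,n_progenitor_b,n_derived Sample counts for wild
#'   population A, wild population B and the derived (domesticated)
#'   population.
#' @param n_variants,n_chromosomes,chrom_length_bp Marker layout.
#' @param drift_f Balding-Nichols differentiation parameter in (0, 1);
#'   approximately the expected Fst between the progenitors.
#' @param admixture_alpha Probability that a derived ancestry block comes
#'   from progenitor A.
#' @param block_mean_bp Mean ancestry-block length (exponential), bp.
#' @param crossover_rate Expected crossovers per chromosome per gamete.
#' @param pedigree_spec `data.frame(child, parent1, parent2)` in
#'   topological order, or `NULL` to derive from `n_pedigree`.
#' @param n_pedigree Number of offspring to breed from random derived
#'   parents when `pedigree_spec` is `NULL`.
#' @param clone_spec `data.frame(source, clone, error_rate)` or `NULL`.
#' @param n_clones,clone_error_rate Used when `clone_spec` is `NULL`.
#' @param triploid_ids Character ids of derived samples to render as
#'   triploids, or `NULL` to draw `n_triploids` of them.
#' @param n_triploids Count used when `triploid_ids` is `NULL`.
#' @param sweep_spec List `(population, chrom, start_bp, end_bp,
#'   carrier_fraction)`; `population` one of "derived", "A", "B".
#' @param trait_spec List `(causal_variant_index, penetrance,
#'   background_rate)`; `causal_variant_index = NA` picks a common variant
#'   mid-way along chromosome 2 at simulation time.
#' @param missing_rate Per-call missing probability after artifacts.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_progenitor_a = 30, n_progenitor_b = 30,
                       n_derived = 60,
                       n_variants = 5000, n_chromosomes = 5,
                       chrom_length_bp = 10e6,
                       drift_f = 0.2, admixture_alpha = 0.5,
                       block_mean_bp = 2e6, crossover_rate = 1.5,
                       pedigree_spec = NULL, n_pedigree = 55,
                       clone_spec = NULL, n_clones = 12,
                       clone_error_rate = 0.01,
                       triploid_ids = NULL, n_triploids = 8,
                       sweep_spec = list(population = "derived",
                                         chrom = "chr1", start_bp = 4e6,
                                         end_bp = 5e6,
                                         carrier_fraction = 0.9),
                       trait_spec = list(causal_variant_index = NA,
                                         penetrance = 0.9,
                                         background_rate = 0.05),
                       missing_rate = 0.02, seed = 42) {
  cfg <- list(n_progenitor_a = n_progenitor_a,
              n_progenitor_b = n_progenitor_b, n_derived = n_derived,
              n_variants = n_variants, n_chromosomes = n_chromosomes,
              chrom_length_bp = chrom_length_bp, drift_f = drift_f,
              admixture_alpha = admixture_alpha,
              block_mean_bp = block_mean_bp,
              crossover_rate = crossover_rate,
              pedigree_spec = pedigree_spec, n_pedigree = n_pedigree,
              clone_spec = clone_spec, n_clones = n_clones,
              clone_error_rate = clone_error_rate,
              triploid_ids = triploid_ids, n_triploids = n_triploids,
              sweep_spec = sweep_spec, trait_spec = trait_spec,
              missing_rate = missing_rate, seed = as.integer(seed))
  counts <- c("n_progenitor_a", "n_progenitor_b", "n_derived", "n_variants",
              "n_chromosomes", "chrom_length_bp")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("configuration error: '", nm, "' must be a positive count")
    }
  }
  if (!is.numeric(drift_f) || drift_f <= 0 || drift_f >= 1) {
    stop("configuration error: drift_f must lie in (0, 1)")
  }
  for (nm in c("admixture_alpha", "missing_rate")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("configuration error: '", nm, "' must lie in [0, 1]")
    }
  }
  if (!is.null(sweep_spec)) {
    with(sweep_spec, {
      if (carrier_fraction < 0 || carrier_fraction > 1) {
        stop("configuration error: carrier_fraction must lie in [0, 1]")
      }
      if (start_bp < 1 || end_bp > chrom_length_bp || start_bp >= end_bp) {
        stop("configuration error: sweep interval outside chromosome bounds")
      }
    })
  }
  if (!is.null(trait_spec)) {
    for (nm in c("penetrance", "background_rate")) {
      if (trait_spec[[nm]] < 0 || trait_spec[[nm]] > 1) {
        stop("configuration error: trait ", nm, " must lie in [0, 1]")
      }
    }
  }
  if (!is.null(pedigree_spec)) {
    known <- character(0)
    founders <- TRUE  # parents validated against panel at build time
    for (i in seq_len(nrow(pedigree_spec))) {
      known <- c(known, pedigree_spec$child[i])
    }
    if (anyDuplicated(pedigree_spec$child)) {
      stop("configuration error: duplicate child ids in pedigree_spec")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Balding-Nichols per-variant allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each progenitor
#' population's frequency is an independent
#' Beta(p(1-F)/F, (1-p)(1-F)/F) draw, so E\[Fst\] between the populations
#' is approximately `drift_f`.
#'
#' @param config A [sim_config()]. Uses `config$seed`.
#' @return `data.frame(chrom, pos, anc, pa, pb)` with positions strictly
#'   increasing within chromosome.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_variants
  per_chr <- diff(round(seq(0, m, length.out = config$n_chromosomes + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(k) {
    sort(sample.int(config$chrom_length_bp, k))
  }))
  p <- stats::runif(m, 0.05, 0.95)
  f <- config$drift_f
  shape_scale <- (1 - f) / f
  pa <- stats::rbeta(m, p * shape_scale, (1 - p) * shape_scale)
  pb <- stats::rbeta(m, p * shape_scale, (1 - p) * shape_scale)
  data.frame(chrom = chrom, pos = pos, anc = p, pa = pa, pb = pb,
             stringsAsFactors = FALSE)
}

# Draw one derived haplotype's per-variant ancestry (1 = progenitor A)
# as contiguous blocks with exponential lengths.
block_ancestry <- function(freqs, config) {
  anc <- integer(nrow(freqs))
  for (chrom in unique(freqs$chrom)) {
    vi <- which(freqs$chrom == chrom)
    pos <- freqs$pos[vi]
    bp <- 0
    breaks <- numeric(0)
    while (bp < config$chrom_length_bp) {
      bp <- bp + stats::rexp(1, 1 / config$block_mean_bp)
      breaks <- c(breaks, bp)
    }
    src <- stats::rbinom(length(breaks), 1, config$admixture_alpha)
    anc[vi] <- src[findInterval(pos, c(0, breaks), left.open = TRUE)]
  }
  anc
}

#' Simulate founder haplotypes
#'
#' Progenitor haplotypes are drawn per site from their population
#' frequency; derived haplotypes are mosaics of contiguous ancestry
#' blocks whose source is progenitor A with probability
#' `admixture_alpha`, with alleles drawn from the source population's
#' frequency. Assumes the RNG state set by [simulate_frequencies()] (the
#' [simulate_panel()] driver runs the stages in order under one seed).
#'
#' @param freqs Output of [simulate_frequencies()].
#' @param config A [sim_config()].
#' @return A simulation state list with elements `haps`, `ancestry`
#'   (haplotype x variant matrices), `ids`, `pop` (per-sample population
#'   label), `variants` and `ancestry_dosage`.
#' @export
simulate_founders <- function(freqs, config) {
  m <- nrow(freqs)
  na <- config$n_progenitor_a; nb <- config$n_progenitor_b
  nd <- config$n_derived
  ids <- c(sprintf("PA%03d", seq_len(na)), sprintf("PB%03d", seq_len(nb)),
           sprintf("D%03d", seq_len(nd)))
  pop <- c(rep("A", na), rep("B", nb), rep("derived", nd))
  n_hap <- 2L * (na + nb + nd)
  haps <- matrix(0L, n_hap, m)
  anc_mat <- matrix(0L, n_hap, m)
  ha <- 2L * na
  haps[seq_len(ha), ] <- matrix(
    stats::rbinom(ha * m, 1L, rep(freqs$pa, each = ha)), ha, m)
  anc_mat[seq_len(ha), ] <- 1L
  hb <- 2L * nb
  haps[ha + seq_len(hb), ] <- matrix(
    stats::rbinom(hb * m, 1L, rep(freqs$pb, each = hb)), hb, m)
  for (h in seq_len(2L * nd)) {
    row <- ha + hb + h
    a <- block_ancestry(freqs, config)
    p_site <- ifelse(a == 1L, freqs$pa, freqs$pb)
    haps[row, ] <- stats::rbinom(m, 1L, p_site)
    anc_mat[row, ] <- a
  }
  dosage <- (anc_mat[seq(1, n_hap, 2), , drop = FALSE] +
               anc_mat[seq(2, n_hap, 2), , drop = FALSE]) / 2
  state <- list(haps = haps,
                ancestry = anc_mat,
                ids = ids, pop = pop,
                variants = data.frame(chrom = freqs$chrom, pos = freqs$pos,
                                      ref = "A", alt = "T",
                                      stringsAsFactors = FALSE),
                freqs = freqs,
                config = config,
                ancestry_dosage = stats::setNames(rowMeans(dosage), ids))
  state
}

# One recombinant gamete (hap allele vector + ancestry vector) from a
# parent's two haplotype rows.
make_gamete <- function(state, parent_id) {
  i <- match(parent_id, state$ids)
  if (is.na(i)) stop("unknown parent id: ", parent_id)
  r1 <- 2L * i - 1L; r2 <- 2L * i
  m <- ncol(state$haps)
  hap <- integer(m); anc <- integer(m)
  for (chrom in unique(state$variants$chrom)) {
    vi <- which(state$variants$chrom == chrom)
    pos <- state$variants$pos[vi]
    k <- stats::rpois(1, state$config$crossover_rate)
    xo <- sort(stats::runif(k, 0, state$config$chrom_length_bp))
    seg <- findInterval(pos, xo)  # 0..k
    cur <- sample(c(r1, r2), 1L)
    use_r1 <- ((seg %% 2L) == 0L) == (cur == r1)
    src <- ifelse(use_r1, r1, r2)
    hap[vi] <- state$haps[cbind(src, vi)]
    anc[vi] <- state$ancestry[cbind(src, vi)]
  }
  list(hap = hap, anc = anc)
}

#' Breed pedigree offspring into a simulated panel
#'
#' Each child receives one recombinant gamete per parent; crossover
#' counts per chromosome are Poisson(`crossover_rate`). Children are
#' appended to the panel and recorded as known parent-offspring edges.
#'
#' @param state Simulation state from [simulate_founders()].
#' @param pedigree_spec `data.frame(child, parent1, parent2)`; parents
#'   must already exist (topological order).
#' @return Updated state with a `pedigree_edges` data.frame.
#' @export
breed_pedigree <- function(state, pedigree_spec) {
  edges <- data.frame(child = character(0), parent = character(0))
  if (is.null(pedigree_spec) || !nrow(pedigree_spec)) {
    state$pedigree_edges <- edges
    return(state)
  }
  for (i in seq_len(nrow(pedigree_spec))) {
    child <- as.character(pedigree_spec$child[i])
    p1 <- as.character(pedigree_spec$parent1[i])
    p2 <- as.character(pedigree_spec$parent2[i])
    g1 <- make_gamete(state, p1)
    g2 <- make_gamete(state, p2)
    state$haps <- rbind(state$haps, g1$hap, g2$hap)
    state$ancestry <- rbind(state$ancestry, g1$anc, g2$anc)
    state$ids <- c(state$ids, child)
    state$pop <- c(state$pop, "derived")
    state$ancestry_dosage[child] <- mean((g1$anc + g2$anc) / 2)
    edges <- rbind(edges, data.frame(child = child, parent = c(p1, p2)))
  }
  state$pedigree_edges <- edges
  state
}

#' Inject a selective sweep and a major-locus binary trait
#'
#' Within the sweep interval, `carrier_fraction` of the target
#' population's haplotypes are replaced by one fixed haplotype (the
#' pattern of the first selected carrier), creating extended haplotype
#' homozygosity. The binary trait is then assigned from the causal
#' variant's dosage: 1 with probability `penetrance` when dosage >= 1,
#' else with probability `background_rate`.
#'
#' @param state Simulation state (after [breed_pedigree()]).
#' @param config A [sim_config()].
#' @return Updated state with `sweep_interval`, `causal_variant` and
#'   `phenotype` recorded.
#' @export
inject_sweep_and_trait <- function(state, config) {
  sw <- config$sweep_spec
  if (!is.null(sw)) {
    if (sw$carrier_fraction < 0 || sw$carrier_fraction > 1) {
      stop("configuration error: carrier_fraction must lie in [0, 1]")
    }
    vi <- which(state$variants$chrom == sw$chrom &
                  state$variants$pos >= sw$start_bp &
                  state$variants$pos <= sw$end_bp)
    target <- which(state$pop == switch(sw$population,
                                        derived = "derived", A = "A", B = "B"))
    hap_rows_t <- as.vector(rbind(2L * target - 1L, 2L * target))
    n_carrier <- round(sw$carrier_fraction * length(hap_rows_t))
    if (length(vi) && n_carrier > 0) {
      carriers <- sort(sample(hap_rows_t, n_carrier))
      fixed <- state$haps[carriers[1L], vi]
      state$haps[carriers, vi] <- rep(fixed, each = length(carriers))
      state$sweep_carriers <- carriers
    }
    state$sweep_interval <- list(chrom = sw$chrom, start_bp = sw$start_bp,
                                 end_bp = sw$end_bp)
  }
  tr <- config$trait_spec
  if (!is.null(tr)) {
    ci <- tr$causal_variant_index
    if (is.na(ci)) {
      # common variant nearest the middle of chromosome 2
      chr <- if (config$n_chromosomes >= 2) "chr2" else "chr1"
      vi2 <- which(state$variants$chrom == chr)
      g <- hap_pair_sums(state$haps)
      p_der <- colMeans(g[state$pop == "derived", vi2, drop = FALSE]) / 2
      common <- vi2[p_der > 0.2 & p_der < 0.8]
      if (!length(common)) common <- vi2
      mid <- config$chrom_length_bp / 2
      ci <- common[which.min(abs(state$variants$pos[common] - mid))]
    }
    g_causal <- hap_pair_sums(state$haps)[, ci]
    prob <- ifelse(g_causal >= 1, tr$penetrance, tr$background_rate)
    state$phenotype <- stats::setNames(stats::rbinom(length(prob), 1, prob),
                                       state$ids)
    state$causal_variant <- ci
  }
  state
}

# sum interleaved haplotype rows into per-sample dosages
hap_pair_sums <- function(haps) {
  n <- nrow(haps) / 2L
  haps[seq(1L, 2L * n, 2L), , drop = FALSE] +
    haps[seq(2L, 2L * n, 2L), , drop = FALSE]
}

#' Apply post-hoc artifacts: clones, triploids, missing calls
#'
#' Clones copy a source genotype with independent per-site call error
#' (an erroneous call is redrawn from Hardy-Weinberg proportions at the
#' panel allele frequency). Triploids receive a third allele drawn from
#' the derived-population frequency and their 0..3 dosage is collapsed to
#' a diploid report (0 -> 0; 1,2 -> 1; 3 -> 2), which inflates apparent
#' heterozygosity. Missing calls are inserted uniformly.
#'
#' @param state Simulation state after [inject_sweep_and_trait()].
#' @param config A [sim_config()] (resolved specs: `clone_spec` a
#'   data.frame, `triploid_ids` character).
#' @return Updated state with `calls` (the final dosage matrix including
#'   clone samples), `clone_map` and `ploidy_map`.
#' @export
apply_artifacts <- function(state, config) {
  calls <- hap_pair_sums(state$haps)
  ids <- state$ids
  p_all <- colMeans(calls) / 2
  der <- state$pop == "derived"
  p_der <- if (any(der)) colMeans(calls[der, , drop = FALSE]) / 2 else p_all
  clone_map <- data.frame(clone = character(0), source = character(0))
  cs <- config$clone_spec
  if (!is.null(cs) && nrow(cs)) {
    for (i in seq_len(nrow(cs))) {
      src <- as.character(cs$source[i])
      j <- match(src, ids)
      if (is.na(j)) stop("clone of unknown source: ", src)
      g <- calls[j, ]
      err <- which(stats::runif(length(g)) < cs$error_rate[i])
      if (length(err)) {
        pe <- p_all[err]
        g[err] <- stats::rbinom(length(err), 2, pe)
      }
      calls <- rbind(calls, g)
      ids <- c(ids, as.character(cs$clone[i]))
      state$pop <- c(state$pop, "derived")
      clone_map <- rbind(clone_map,
                         data.frame(clone = as.character(cs$clone[i]),
                                    source = src))
    }
  }
  ploidy <- stats::setNames(rep("2x", length(ids)), ids)
  tri <- config$triploid_ids
  if (!is.null(tri) && length(tri)) {
    j <- match(tri, ids)
    if (anyNA(j)) stop("unknown triploid ids: ",
                       paste(tri[is.na(j)], collapse = ", "))
    for (i in j) {
      third <- stats::rbinom(ncol(calls), 1, p_der)
      s3 <- calls[i, ] + third
      calls[i, ] <- ifelse(s3 == 0, 0L, ifelse(s3 == 3, 2L, 1L))
    }
    ploidy[tri] <- "3x"
  }
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(length(calls)) < config$missing_rate,
                   nrow(calls))
    calls[mask] <- NA_integer_
  }
  rownames(calls) <- ids
  state$calls <- calls
  state$final_ids <- ids
  state$clone_map <- clone_map
  state$ploidy_map <- ploidy
  state
}

#' Simulate a complete synthetic germplasm panel
#'
#' Runs the full generator under one seed: Balding-Nichols frequencies,
#' founder haplotypes with block admixture, pedigree breeding, sweep and
#' trait injection, then clone/triploid/missingness artifacts.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_panel`: list with `genotypes` (a
#'   [geno_matrix()] carrying sample metadata), `haplotypes` (a
#'   [hap_panel()] of truth-phased non-clone samples), `truth` (a
#'   `truth_set` list) and `config`.
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- simulate_frequencies(config)  # seeds the RNG
  state <- simulate_founders(freqs, config)

  ped <- config$pedigree_spec
  if (is.null(ped) && config$n_pedigree > 0) {
    nk <- config$n_pedigree
    founder_pool <- state$ids[state$pop == "derived"]
    parents <- t(vapply(seq_len(nk),
                        function(i) sample(founder_pool, 2L), character(2)))
    ped <- data.frame(child = sprintf("K%03d", seq_len(nk)),
                      parent1 = parents[, 1], parent2 = parents[, 2],
                      stringsAsFactors = FALSE)
  }
  state <- breed_pedigree(state, ped)
  state <- inject_sweep_and_trait(state, config)

  cs <- config$clone_spec
  if (is.null(cs) && config$n_clones > 0) {
    pool <- state$ids[state$pop == "derived"]
    src <- sample(pool, config$n_clones)
    cs <- data.frame(source = src,
                     clone = sprintf("C%03d", seq_len(config$n_clones)),
                     error_rate = config$clone_error_rate,
                     stringsAsFactors = FALSE)
  }
  tri <- config$triploid_ids
  if (is.null(tri) && config$n_triploids > 0) {
    pool <- setdiff(state$ids[state$pop == "derived"],
                    if (!is.null(cs)) cs$source else character(0))
    tri <- sort(sample(pool, config$n_triploids))
  }
  cfg2 <- config
  cfg2$clone_spec <- cs
  cfg2$triploid_ids <- tri
  state <- apply_artifacts(state, cfg2)

  ids <- state$final_ids
  species <- c(A = "wild_a", B = "wild_b", derived = "domesticated")[state$pop]
  pheno <- state$phenotype
  firmness <- if (is.null(pheno)) rep(NA_integer_, length(ids)) else {
    c(pheno, stats::setNames(rep(NA_integer_,
                                 length(setdiff(ids, names(pheno)))),
                             setdiff(ids, names(pheno))))[ids]
  }
  use_class <- ifelse(species == "domesticated",
                      ifelse(stats::runif(length(ids)) < 0.5, "dessert",
                             "cider"),
                      "unknown")
  samples <- data.frame(id = ids, species = unname(species),
                        ploidy_label = unname(state$ploidy_map[ids]),
                        use_class = use_class,
                        color = stats::rbinom(length(ids), 1, 0.3),
                        firmness = unname(firmness),
                        size = stats::rbinom(length(ids), 1, 0.3),
                        stringsAsFactors = FALSE)
  gm <- geno_matrix(state$calls, state$variants, samples)

  hp <- hap_panel(state$haps, state$ids, state$variants)

  truth <- structure(list(
    ancestry_dosage = state$ancestry_dosage,
    pedigree_edges = state$pedigree_edges,
    clone_map = state$clone_map,
    ploidy_map = state$ploidy_map,
    sweep_interval = state$sweep_interval,
    sweep_population = if (!is.null(config$sweep_spec))
      config$sweep_spec$population else NULL,
    causal_variant = state$causal_variant,
    causal_variant_id = if (!is.null(state$causal_variant))
      paste0(state$variants$chrom[state$causal_variant], ":",
             state$variants$pos[state$causal_variant]) else NULL,
    phenotype = state$phenotype), class = "truth_set")

  structure(list(genotypes = gm, haplotypes = hp, truth = truth,
                 config = config),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("sim_panel:", nrow(x$genotypes$calls), "samples,",
      ncol(x$genotypes$calls), "variants\n")
  cat("  pedigree edges:", nrow(x$truth$pedigree_edges),
      "| clones:", nrow(x$truth$clone_map),
      "| triploids:", sum(x$truth$ploidy_map == "3x"), "\n")
  invisible(x)
}

#' Write a simulated panel to disk
#'
#' Emits `genotypes.vcf` (unphased, post-artifact), `haplotypes.vcf`
#' (phased truth haplotypes, pre-artifact), `samples.tsv` and
#' `truth.json`.
#'
#' @param sim A `sim_panel`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  gm_hap <- haps_to_genotypes(sim$haplotypes)
  write_vcf(gm_hap, file.path(dir, "haplotypes.vcf"),
            haplotypes = sim$haplotypes)
  write_sample_metadata(sim$genotypes$samples, file.path(dir, "samples.tsv"))
  truth <- sim$truth
  truth$ancestry_dosage <- as.list(truth$ancestry_dosage)
  truth$ploidy_map <- as.list(truth$ploidy_map)
  truth$phenotype <- as.list(truth$phenotype)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
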