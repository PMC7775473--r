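pipeline_defaults <- function() {
  list(
    out_dir = "maluspop_run",
    simulate = NULL,     # sim_config() arguments, or NULL when reading files
    input = list(vcf = NULL, phased_vcf = NULL, metadata = NULL,
                 known_pairs = NULL, gff = NULL, terms = NULL),
    stages = list(filter = TRUE, ploidy = TRUE, clone_collapse = TRUE,
                  relate = TRUE, ancestry = TRUE, scan = TRUE, gwas = TRUE,
                  resample = TRUE),
    params = list(maf_min = 0.01, max_missing = 0.30,
                  ld_window = 10, ld_step = 3, ld_r2 = 0.5,
                  het_threshold = "midpoint",
                  clone_threshold = 0.90,
                  first_degree_range = "calibrate",
                  drop_rule = "iqr",
                  q = 0.05, scan_mode = "high_tail",
                  ehh_cutoff = 0.05, max_gap = 1.5e6, flank = 5e4,
                  block_size_bp = 5e6,
                  trait = "firmness", n_pcs = 3, mlmm_max_steps = 3,
                  resample_k = 8, resample_draws = 10000,
                  seed = 1))
}

merge_defaults <- function(user, defaults, path, errors) {
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      errors$msgs <- c(errors$msgs,
                       paste0("unknown key '", paste(c(path, key),
                                                     collapse = "."), "'"))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "simulate") {
      if (!is.list(user[[key]])) {
        errors$msgs <- c(errors$msgs,
                         paste0("'", paste(c(path, key), collapse = "."),
                                "' must be a mapping"))
        next
      }
      defaults[[key]] <- merge_defaults(user[[key]], defaults[[key]],
                                        c(path, key), errors)
    } else {
      defaults[key] <- user[key]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), checks it against the known
#' schema, fills defaults, and reports *every* violation found rather
#' than the first. Unknown keys are errors (they are usually typos).
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  errors <- new.env()
  errors$msgs <- character(0)
  cfg <- merge_defaults(config, pipeline_defaults(), character(0), errors)
  p <- cfg$params
  chk <- function(cond, msg) if (!isTRUE(cond)) {
    errors$msgs <- c(errors$msgs, msg)
  }
  chk(is.numeric(p$maf_min) && p$maf_min >= 0 && p$maf_min <= 0.5,
      "params.maf_min must lie in [0, 0.5]")
  chk(is.numeric(p$max_missing) && p$max_missing >= 0 && p$max_missing <= 1,
      "params.max_missing must lie in [0, 1]")
  chk(is.numeric(p$q) && p$q > 0 && p$q < 1, "params.q must lie in (0, 1)")
  chk(identical(p$het_threshold, "midpoint") ||
        (is.numeric(p$het_threshold) && p$het_threshold > 0),
      "params.het_threshold must be positive or \"midpoint\"")
  chk(is.numeric(p$clone_threshold) && p$clone_threshold > 0 &&
        p$clone_threshold <= 1,
      "params.clone_threshold must lie in (0, 1]")
  chk(p$scan_mode %in% c("high_tail", "low_tail"),
      "params.scan_mode must be high_tail or low_tail")
  chk(is.numeric(p$seed) && p$seed == round(p$seed),
      "params.seed must be an integer")
  if (is.null(cfg$simulate)) {
    for (f in c("vcf", "metadata")) {
      chk(!is.null(cfg$input[[f]]) && file.exists(cfg$input[[f]]),
          paste0("input.", f, " must name an existing file (or set simulate:)"))
    }
  }
  if (length(errors$msgs)) {
    stop("invalid configuration:\n  - ",
         paste(errors$msgs, collapse = "\n  - "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

stage_report <- function(name, n_in, v_in, n_out, v_out, params, t0,
                         warnings = character(0)) {
  list(stage = name,
       samples_in = n_in, variants_in = v_in,
       samples_out = n_out, variants_out = v_out,
       parameters = params,
       wall_time_s = round(as.numeric(Sys.time()) - t0, 3),
       warnings = warnings)
}

#' Run the full germplasm analysis pipeline
#'
#' Executes the enabled stages in fixed order: simulate/ingest ->
#' variant filter -> ploidy screen -> clone collapse -> relatedness
#' network -> ancestry (projection PCA, rank-sum, f3) -> selection scans
#' (Fst, XP-EHH, overlap) -> GWAS (LMM + MLMM + scan overlap) ->
#' homozygosity resample. Every stage writes its artifact under
#' `out_dir` and contributes a stage report; a run manifest records the
#' config hash and seeds so a rerun is byte-reproducible.
#'
#' @param config A `pipeline_config` from [validate_config()] (or a list
#'   / YAML path, validated on the fly).
#' @return List of class `pipeline_result` with `reports` (stage
#'   reports), `artifacts` (in-memory results per stage) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  p <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- list()
  art <- list()
  set.seed(p$seed)

  ## -- ingest ---------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  truth <- NULL; hp <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- p$seed
    sim <- simulate_panel(do.call(sim_config, sim_args))
    gm <- sim$genotypes
    hp <- sim$haplotypes
    truth <- sim$truth
    art$sim <- sim
  } else {
    vr <- read_vcf(config$input$vcf)
    gm <- vr$genotypes
    hp <- vr$haplotypes
    meta <- read_sample_metadata(config$input$metadata)
    gm$samples <- merge(gm$samples, meta, by = "id", sort = FALSE)
    if (!is.null(config$input$phased_vcf)) {
      hp <- read_vcf(config$input$phased_vcf)$haplotypes
      if (is.null(hp)) stop("phased_vcf is not fully phased")
    }
  }
  reports$ingest <- stage_report("ingest", NA, NA, nrow(gm$calls),
                                 ncol(gm$calls), list(), t0)

  ## -- filter ---------------------------------------------------------
  if (isTRUE(config$stages$filter)) {
    t0 <- as.numeric(Sys.time())
    n_in <- nrow(gm$calls); v_in <- ncol(gm$calls)
    gm <- filter_variants(gm, p$maf_min, p$max_missing)
    reports$filter <- stage_report("filter", n_in, v_in, nrow(gm$calls),
                                   ncol(gm$calls),
                                   list(maf_min = p$maf_min,
                                        max_missing = p$max_missing), t0)
  }

  ## -- ploidy screen --------------------------------------------------
  removed_triploid <- character(0)
  if (isTRUE(config$stages$ploidy)) {
    t0 <- as.numeric(Sys.time())
    n_in <- nrow(gm$calls)
    gm <- annotate_heterozygosity(gm)
    pl <- classify_ploidy(gm$samples, threshold = p$het_threshold)
    removed_triploid <- pl$removed
    art$ploidy <- pl
    utils::write.table(pl$calls, file.path(config$out_dir,
                                           "ploidy_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gm <- subset_samples(gm, setdiff(gm$samples$id, removed_triploid))
    reports$ploidy <- stage_report("ploidy", n_in, ncol(gm$calls),
                                   nrow(gm$calls), ncol(gm$calls),
                                   list(threshold = pl$threshold), t0)
  }

  ## -- LD prune + IBD (shared by clone collapse and relate) -----------
  warn_clones <- character(0)
  ibd <- NULL
  if (isTRUE(config$stages$clone_collapse) || isTRUE(config$stages$relate)) {
    gm_pruned <- prune_ld(gm, p$ld_window, p$ld_step, p$ld_r2)
    ibd <- estimate_ibd(gm_pruned)
    art$ibd <- ibd
  }

  ## -- clone collapse -------------------------------------------------
  if (isTRUE(config$stages$clone_collapse)) {
    t0 <- as.numeric(Sys.time())
    n_in <- nrow(gm$calls)
    cg <- clonal_groups(ibd, p$clone_threshold, ids = gm$samples$id)
    art$clones <- cg
    gm <- subset_samples(gm, setdiff(gm$samples$id, cg$removed))
    ibd <- ibd[ibd$id1 %in% gm$samples$id & ibd$id2 %in% gm$samples$id, ]
    reports$clone_collapse <- stage_report(
      "clone_collapse", n_in, ncol(gm$calls), nrow(gm$calls),
      ncol(gm$calls), list(threshold = p$clone_threshold), t0)
  } else if (isTRUE(config$stages$relate)) {
    warn_clones <- "clone collapse disabled: clonal pairs may inflate first-degree counts"
    warning(warn_clones)
  }

  ## -- relatedness network -------------------------------------------
  if (isTRUE(config$stages$relate)) {
    t0 <- as.numeric(Sys.time())
    rng <- p$first_degree_range
    if (identical(rng, "calibrate")) {
      kp <- NULL
      if (!is.null(truth) && nrow(truth$pedigree_edges)) {
        kp <- data.frame(id1 = truth$pedigree_edges$child,
                         id2 = truth$pedigree_edges$parent)
        kp <- kp[kp$id1 %in% gm$samples$id & kp$id2 %in% gm$samples$id, ]
      } else if (!is.null(config$input$known_pairs)) {
        kp <- utils::read.table(config$input$known_pairs, header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
        names(kp)[1:2] <- c("id1", "id2")
      }
      if (is.null(kp) || nrow(kp) < 3) {
        stop("relate stage: no known pairs available for calibration; ",
             "set params.first_degree_range to c(lower, upper)")
      }
      rng <- calibrate_first_degree(kp, ibd, drop_rule = p$drop_rule)
      art$first_degree_range <- rng
    }
    net <- relationship_network(ibd, rng, ids = gm$samples$id)
    art$network <- net
    write_edge_list(net, file.path(config$out_dir, "first_degree_edges.tsv"))
    reports$relate <- stage_report(
      "relate", nrow(gm$calls), ncol(gm$calls), nrow(gm$calls),
      ncol(gm$calls),
      list(lower = if (inherits(rng, "first_degree_range")) rng$lower
           else rng[1],
           upper = if (inherits(rng, "first_degree_range")) rng$upper
           else rng[2]),
      t0, warnings = warn_clones)
  }

  ## -- ancestry -------------------------------------------------------
  if (isTRUE(config$stages$ancestry)) {
    t0 <- as.numeric(Sys.time())
    sm <- gm$samples
    ref_a <- sm$id[sm$species == "wild_a"]
    ref_b <- sm$id[sm$species == "wild_b"]
    target <- sm$id[sm$species == "domesticated"]
    if (length(ref_a) >= 2 && length(ref_b) >= 2 && length(target) >= 2) {
      model <- fit_reference_pca(gm, ref_a, ref_b,
                                 n_components = max(p$n_pcs, 2))
      proj <- project_onto_pca(model, gm)
      art$pca <- list(model = model, projection = proj)
      dessert <- sm$id[sm$use_class == "dessert"]
      cider <- sm$id[sm$use_class == "cider"]
      if (length(dessert) && length(cider)) {
        art$rank_sum <- rank_sum_compare(proj$scores, cider, dessert, 1)
      }
      art$f3 <- f3_statistic(gm, target, ref_a, ref_b,
                             block_size_bp = p$block_size_bp)
      utils::write.table(
        data.frame(id = rownames(proj$scores), proj$scores),
        file.path(config$out_dir, "pca_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    reports$ancestry <- stage_report("ancestry", nrow(gm$calls),
                                     ncol(gm$calls), nrow(gm$calls),
                                     ncol(gm$calls),
                                     list(n_pcs = p$n_pcs), t0)
  }

  ## -- selection scan -------------------------------------------------
  scan_records <- NULL
  if (isTRUE(config$stages$scan) && !is.null(hp)) {
    t0 <- as.numeric(Sys.time())
    sm <- gm$samples
    keep_dip <- sm$id[sm$ploidy_label != "3x"]
    popA <- intersect(sm$id[sm$species == "domesticated"],
                      intersect(keep_dip, hp$sample_ids))
    popB <- intersect(sm$id[sm$species == "wild_a"],
                      intersect(keep_dip, hp$sample_ids))
    if (length(popA) >= 2 && length(popB) >= 2) {
      hp_sub <- subset_haps(hp, c(popA, popB))
      keyv <- paste0(hp$variants$chrom, ":", hp$variants$pos)
      keyg <- paste0(gm$variants$chrom, ":", gm$variants$pos)
      common <- intersect(keyg, keyv)
      hp_sub <- hap_panel(hp_sub$haps[, match(common, keyv), drop = FALSE],
                          hp_sub$sample_ids,
                          hp$variants[match(common, keyv), , drop = FALSE])
      gm_scan <- subset_variants(gm, match(common, keyg))
      fst <- weir_cockerham_fst(gm_scan, popA, popB)
      xp <- xpehh_scan(hp_sub, popA, popB, cutoff = p$ehh_cutoff,
                       max_gap = p$max_gap)
      rec <- data.frame(chrom = fst$chrom, pos = fst$pos, fst = fst$fst,
                        xpehh_raw = xp$xpehh_raw)
      rec$xpehh_std <- standardize_scan(rec$xpehh_raw)
      scan_records <- candidate_overlap(rec, q = p$q, mode = p$scan_mode)
      art$scan <- scan_records
      utils::write.table(scan_records,
                         file.path(config$out_dir, "scan_track.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(config$input$gff)) {
        genes <- read_gene_annotation(config$input$gff)
        cand <- scan_records[scan_records$overlap_candidate, ]
        art$candidate_genes <- genes_in_windows(cand, genes, p$flank)
        if (!is.null(config$input$terms)) {
          tm <- utils::read.table(config$input$terms, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
          names(tm)[1:2] <- c("gene", "term")
          art$enrichment <- fisher_enrichment(art$candidate_genes,
                                              genes$id, tm)
        }
      }
    }
    reports$scan <- stage_report("scan", nrow(gm$calls), ncol(gm$calls),
                                 nrow(gm$calls),
                                 if (is.null(scan_records)) ncol(gm$calls)
                                 else nrow(scan_records),
                                 list(q = p$q, mode = p$scan_mode), t0)
  }

  ## -- GWAS -----------------------------------------------------------
  if (isTRUE(config$stages$gwas)) {
    t0 <- as.numeric(Sys.time())
    sm <- gm$samples
    trait <- sm[[p$trait]]
    keep <- sm$id[sm$species == "domesticated" & !is.na(trait)]
    if (length(keep) >= 10) {
      gm_g <- subset_samples(gm, keep)
      y <- stats::setNames(sm[[p$trait]][match(keep, sm$id)], keep)
      if (stats::var(y) > 0) {
        K <- kinship_matrix(gm_g)
        eigK <- eigen(K, symmetric = TRUE)
        pcs <- eigK$vectors[, seq_len(min(p$n_pcs, ncol(K))), drop = FALSE]
        colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
        assoc <- lmm_scan(gm_g, y, covariates = pcs, kinship = K)
        art$gwas <- assoc
        art$mlmm <- mlmm_stepwise(gm_g, y, covariates = pcs, kinship = K,
                                  max_steps = p$mlmm_max_steps)
        if (!is.null(scan_records)) {
          art$gwas_scan_overlap <- scan_overlap(assoc, scan_records)
        }
        utils::write.table(assoc, file.path(config$out_dir, "gwas.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    reports$gwas <- stage_report("gwas", nrow(gm$calls), ncol(gm$calls),
                                 nrow(gm$calls), ncol(gm$calls),
                                 list(trait = p$trait, n_pcs = p$n_pcs), t0)
  }

  ## -- homozygosity resample ------------------------------------------
  if (isTRUE(config$stages$resample)) {
    t0 <- as.numeric(Sys.time())
    sm <- gm$samples
    dom <- sm$id[sm$species == "domesticated"]
    cv <- if (!is.null(truth)) truth$causal_variant_id else NULL
    if (length(dom) >= p$resample_k && !is.null(cv)) {
      j <- match(cv, paste0(gm$variants$chrom, ":", gm$variants$pos))
      if (!is.na(j)) {
        g <- gm$calls[match(dom, sm$id), j]
        flags <- !is.na(g) & g != 1L
        art$resample <- homozygote_resample(dom, flags, k = p$resample_k,
                                            n_draws = p$resample_draws,
                                            seed = p$seed)
      }
    }
    reports$resample <- stage_report("resample", nrow(gm$calls),
                                     ncol(gm$calls), nrow(gm$calls),
                                     ncol(gm$calls),
                                     list(k = p$resample_k,
                                          draws = p$resample_draws), t0)
  }

  ## -- manifest -------------------------------------------------------
  cfg_file <- file.path(config$out_dir, "config_resolved.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   seed = p$seed,
                   stages_run = names(reports))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  art$final_genotypes <- gm
  structure(list(reports = reports, artifacts = art, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$reports), "stages\n")
  for (r in x$reports) {
    cat(sprintf("  %-14s %s samples x %s variants -> %s x %s (%.2fs)\n",
                r$stage, r$samples_in, r$variants_in, r$samples_out,
                r$variants_out, r$wall_time_s))
  }
  invisible(x)
}
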