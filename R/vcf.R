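#' Read genotypes from a VCF file
#'
#' Minimal VCF v4.2 reader for the GT field. Only biallelic SNP records
#' are loaded; indels, multi-allelic records and records whose GT carries
#' more than two alleles are skipped and counted. `./.` (and `.`) become
#' missing. When every retained record is phased (`|` separator
#' throughout) a [hap_panel()] is returned alongside the matrix.
#'
#' @param path Path to a plain or gzipped VCF.
#' @return List with elements `genotypes` (a [geno_matrix()]),
#'   `haplotypes` (a [hap_panel()] or `NULL` when any call is unphased),
#'   and `skipped` (named integer: counts of skipped records by reason).
#' @export
read_vcf <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line found in ", path)
  hdr <- hdr[1L]
  head_fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(head_fields) < 10L) stop("VCF has no sample columns")
  sample_ids <- head_fields[-(1:9)]
  n <- length(sample_ids)

  body <- lines[seq_along(lines) > hdr]
  body_lineno <- which(seq_along(lines) > hdr)
  keep_chrom <- character(0); keep_pos <- integer(0)
  keep_ref <- character(0); keep_alt <- character(0)
  calls_list <- list(); hap_list <- list()
  skipped <- c(multiallelic = 0L, indel = 0L, nonsnp = 0L, bad_gt = 0L)
  phased_all <- TRUE

  for (k in seq_along(body)) {
    ln <- body[k]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + n) {
      stop("malformed VCF record at line ", body_lineno[k], ": expected ",
           9L + n, " fields, found ", length(f))
    }
    ref <- f[4]; alt <- f[5]
    if (grepl(",", alt, fixed = TRUE)) { skipped["multiallelic"] <- skipped["multiallelic"] + 1L; next }
    if (nchar(ref) != 1L || nchar(alt) != 1L) { skipped["indel"] <- skipped["indel"] + 1L; next }
    if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
      skipped["nonsnp"] <- skipped["nonsnp"] + 1L; next
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop("record at line ", body_lineno[k], " lacks GT")
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gt_i)
    alleles <- strsplit(gts, "[/|]")
    n_al <- lengths(alleles)
    if (any(n_al > 2L)) {
      warning("line ", body_lineno[k], ": GT with >2 alleles; site skipped")
      skipped["bad_gt"] <- skipped["bad_gt"] + 1L
      next
    }
    am <- suppressWarnings(
      matrix(as.integer(unlist(lapply(alleles, function(a) {
        a[a == "."] <- NA
        if (length(a) == 1L) a <- c(a, NA)
        a
      }))), nrow = 2L)
    )
    if (any(!is.na(am) & am > 1L)) {
      stop("allele index out of range at line ", body_lineno[k])
    }
    dos <- am[1L, ] + am[2L, ]
    if (!all(grepl("|", gts, fixed = TRUE) | is.na(dos))) phased_all <- FALSE
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("malformed POS at line ", body_lineno[k])
    keep_chrom <- c(keep_chrom, f[1]); keep_pos <- c(keep_pos, pos)
    keep_ref <- c(keep_ref, ref); keep_alt <- c(keep_alt, alt)
    calls_list[[length(calls_list) + 1L]] <- dos
    hap_list[[length(hap_list) + 1L]] <- as.vector(am)
  }

  variants <- data.frame(chrom = keep_chrom, pos = keep_pos,
                         ref = keep_ref, alt = keep_alt,
                         stringsAsFactors = FALSE)
  calls <- if (length(calls_list)) do.call(cbind, calls_list) else
    matrix(integer(0), nrow = n, ncol = 0)
  gm <- geno_matrix(calls, variants, data.frame(id = sample_ids))
  hp <- NULL
  if (phased_all && length(hap_list) && !anyNA(do.call(cbind, hap_list))) {
    hmat <- do.call(cbind, hap_list)
    hp <- hap_panel(hmat, sample_ids, variants)
  }
  list(genotypes = gm, haplotypes = hp, skipped = skipped)
}

#' Write genotypes to a VCF file
#'
#' Emits VCF v4.2 with a GT-only FORMAT. Diploid calls are written
#' unphased (`0/1`); when a matching [hap_panel()] is supplied the phased
#' alleles are written with `|` separators instead. Missing calls become
#' `./.`.
#'
#' @param gm A [geno_matrix()]. Variants must be sorted by (chrom, pos).
#' @param path Output path.
#' @param haplotypes Optional [hap_panel()] aligned to `gm` for phased
#'   output.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, haplotypes = NULL) {
  v <- gm$variants
  ord_ok <- !is.unsorted(order(v$chrom, v$pos)) &&
    all(unlist(tapply(v$pos, v$chrom, function(p) length(p) < 2 || all(diff(p) > 0))))
  if (!ord_ok) stop("internal error: variants not sorted by (chrom, pos)")
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=maluspop",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples$id), collapse = "\t")),
             con)
  if (!nrow(v)) return(invisible(path))
  if (!is.null(haplotypes)) {
    if (!identical(haplotypes$sample_ids, gm$samples$id) ||
        ncol(haplotypes$haps) != nrow(v)) {
      stop("haplotype panel does not align with the genotype matrix")
    }
    n <- length(haplotypes$sample_ids)
    h1 <- haplotypes$haps[seq(1L, 2L * n, 2L), , drop = FALSE]
    h2 <- haplotypes$haps[seq(2L, 2L * n, 2L), , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), nrow = n)
    gt[is.na(h1) | is.na(h2)] <- ".|."
  } else {
    lut <- c("0/0", "0/1", "1/1")
    gt <- matrix(lut[gm$calls + 1L], nrow = nrow(gm$calls))
    gt[is.na(gm$calls)] <- "./."
  }
  recs <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], paste0(v$chrom[j], "_", v$pos[j]),
            v$ref[j], v$alt[j], ".", "PASS", ".", "GT", gt[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(recs, con)
  invisible(path)
}

#' Read a gene annotation (GFF3/BED) as a gene table
#'
#' Wraps `rtracklayer::import`. Gene features are reduced to the fields
#' the scan stage needs: `seqid`, `start`, `end` (1-based inclusive) and
#' a gene `id` (GFF3 `ID` attribute, or name/auto index as fallback).
#'
#' @param path GFF3 or BED file.
#' @param feature_type For GFF3, feature types to keep (default "gene");
#'   ignored for BED.
#' @return `data.frame` with columns `seqid`, `start`, `end`, `id`.
#' @export
read_gene_annotation <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type) && any(as.character(md$type) %in% feature_type)) {
    gr <- gr[as.character(md$type) %in% feature_type]
    md <- S4Vectors::mcols(gr)
  }
  ids <- if (!is.null(md$ID)) as.character(md$ID)
  else if (!is.null(md$name)) as.character(md$name)
  else paste0("gene", seq_along(gr))
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             id = ids, stringsAsFactors = FALSE)
}

#' Write the sample metadata table
#'
#' Tab-separated, one row per sample, as emitted next to simulated VCFs.
#'
#' @param samples Sample `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#' @param path Tab-separated metadata written by [write_sample_metadata()].
#' @return `data.frame` with an `id` column of character ids.
#' @export
read_sample_metadata <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  x$id <- as.character(x$id)
  x
}
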