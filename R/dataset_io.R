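#' Write a simulated dataset to disk
#'
#' Exports a simulated line as standard files: a VCF 4.2 with per-sample
#' GT, DS (dosage, 4 decimals), GP (genotype-probability triplet,
#' 3 decimals with rounding repair so triplets sum to 1) and DP fields,
#' site QUAL and an `TR2` INFO key carrying the per-SNP target accuracy;
#' a phenotype TSV (`id<TAB>phenotype`); and a ground-truth TSV
#' (`chrom pos effect target_r2 realized_r2`). An optional chip VCF
#' (hard calls only) is written for a chip subset of the sequence SNPs.
#'
#' @param dir Output directory (created if needed).
#' @param gp A `genotype_panel` of true genotypes.
#' @param dp Optional `dosage_panel` aligned with `gp`.
#' @param trait Optional `trait_model`.
#' @param ann Optional `seq_annotations` (provides QUAL and DP; its
#'   missingness mask is applied to the written GT field).
#' @param chip_index Optional column indices forming the chip panel.
#' @param contig_length Declared contig length in the VCF header.
#'
#' @return Invisibly, a named list of the paths written.
#' @export
write_dataset <- function(dir, gp, dp = NULL, trait = NULL, ann = NULL,
                          chip_index = NULL, contig_length = NULL) {
  stopifnot(inherits(gp, "genotype_panel"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir, call. = FALSE)
  }
  paths <- list()
  paths$sequence_vcf <- file.path(dir, "sequence.vcf")
  write_vcf(paths$sequence_vcf, gp, dp = dp, ann = ann,
            contig_length = contig_length)

  if (!is.null(chip_index)) {
    paths$chip_vcf <- file.path(dir, "chip.vcf")
    write_vcf(paths$chip_vcf, subset_panel(gp, chip_index),
              contig_length = contig_length)
  }

  if (!is.null(trait)) {
    paths$phenotype <- file.path(dir, "phenotype.tsv")
    utils::write.table(
      data.frame(id = sprintf("ind_%d", seq_along(trait$phenotype)),
                 phenotype = sprintf("%.6f", trait$phenotype)),
      paths$phenotype, sep = "\t", quote = FALSE, row.names = FALSE)

    paths$truth <- file.path(dir, "truth.tsv")
    truth <- data.frame(
      chrom = gp$map$chrom[trait$causal_idx],
      pos = gp$map$pos[trait$causal_idx],
      effect = trait$effects,
      target_r2 = if (is.null(dp)) NA_real_ else dp$target_r2[trait$causal_idx],
      realized_r2 = if (is.null(dp)) NA_real_ else dp$realized_r2[trait$causal_idx])
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

# Keep a column subset of a genotype panel.
subset_panel <- function(gp, idx) {
  out <- list(calls = gp$calls[, idx, drop = FALSE],
              map = gp$map[idx, , drop = FALSE], line = gp$line)
  class(out) <- "genotype_panel"
  out
}

write_vcf <- function(path, gp, dp = NULL, ann = NULL, contig_length = NULL) {
  n <- nrow(gp$calls); m <- ncol(gp$calls)
  map <- gp$map
  con <- file(path, "w")
  on.exit(close(con))

  writeLines("##fileformat=VCFv4.2", con)
  len <- contig_length %||% (max(map$pos) + 1)
  for (ch in sort(unique(map$chrom))) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, as.integer(len)), con)
  }
  writeLines(c(
    '##INFO=<ID=TR2,Number=1,Type=Float,Description="Target imputation accuracy R2">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  if (!is.null(dp)) {
    writeLines(c(
      '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated alternate allele dosage">',
      '##FORMAT=<ID=GP,Number=3,Type=Float,Description="Genotype posterior probabilities">'), con)
  }
  if (!is.null(ann)) {
    writeLines('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">', con)
  }
  samples <- sprintf("ind_%d", seq_len(n))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)

  fmt <- paste(c("GT", if (!is.null(dp)) c("DS", "GP"),
                 if (!is.null(ann)) "DP"), collapse = ":")
  gt_code <- c("0/0", "0/1", "1/1")

  for (s in seq_len(m)) {
    calls <- gp$calls[, s]
    if (!is.null(ann)) calls[ann$missing[, s]] <- NA
    gt <- ifelse(is.na(calls), "./.", gt_code[calls + 1L])
    cells <- gt
    if (!is.null(dp)) {
      gpt <- round(gp_triplets(dp, s), 3)
      # rounding repair: largest component absorbs the residual
      imax <- max.col(gpt, ties.method = "first")
      gpt[cbind(seq_len(n), imax)] <- 1 - (rowSums(gpt) - gpt[cbind(seq_len(n), imax)])
      cells <- paste(cells, sprintf("%.4f", dp$dosage[, s]),
                     paste(sprintf("%.3f", gpt[, 1]), sprintf("%.3f", gpt[, 2]),
                           sprintf("%.3f", gpt[, 3]), sep = ","), sep = ":")
    }
    if (!is.null(ann)) {
      dpv <- ifelse(is.na(calls), ".", as.character(ann$depth[, s]))
      cells <- paste(cells, dpv, sep = ":")
    }
    qual <- if (is.null(ann)) "." else sprintf("%.2f", ann$qual[s])
    info <- if (is.null(dp)) "." else sprintf("TR2=%.4f", dp$target_r2[s])
    writeLines(paste(c(map$chrom[s], map$pos[s], map$snp_id[s], map$ref[s],
                       map$alt[s], qual, "PASS", info, fmt, cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' Parses the VCF through `vcfR` and returns the matrices in the
#' individuals-by-SNPs orientation used throughout the package.
#'
#' @param dir Directory holding `sequence.vcf` and optionally
#'   `phenotype.tsv` / `truth.tsv`.
#' @return A list with `gt` (hard calls, NA for missing), `ds` (dosage,
#'   NULL if absent), `gp` (list of per-SNP n x 3 triplet matrices, NULL
#'   if absent), `depth`, `qual`, `map`, `phenotype`, `truth`.
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "sequence.vcf")
  if (!file.exists(path)) stop("no sequence.vcf under ", dir, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  map <- data.frame(chrom = as.integer(fix[, "CHROM"]),
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    snp_id = fix[, "ID"], stringsAsFactors = FALSE)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt <- t(matrix(match(gt_raw, c("0/0", "0/1", "1/1")) - 1L,
                 nrow = nrow(gt_raw)))

  ds <- gp <- depth <- NULL
  fmt_fields <- strsplit(unlist(v@gt[1, "FORMAT"]), ":")[[1]]
  if ("DS" %in% fmt_fields) {
    ds <- t(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
  }
  if ("GP" %in% fmt_fields) {
    gp_raw <- vcfR::extract.gt(v, element = "GP")
    gp <- lapply(seq_len(nrow(gp_raw)), function(s) {
      do.call(rbind, lapply(strsplit(gp_raw[s, ], ","), as.numeric))
    })
  }
  if ("DP" %in% fmt_fields) {
    depth <- t(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  }

  pheno <- truth <- NULL
  if (file.exists(file.path(dir, "phenotype.tsv"))) {
    pheno <- utils::read.table(file.path(dir, "phenotype.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  }
  if (file.exists(file.path(dir, "truth.tsv"))) {
    truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  }
  list(gt = gt, ds = ds, gp = gp, depth = depth, qual = qual, map = map,
       phenotype = pheno, truth = truth)
}
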