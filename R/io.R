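# Readers and writers for the plain-text formats the pipeline touches.
#
# Coordinate convention: user-facing files are 1-based (inclusive intervals,
# VCF-style positions). Internally every point position is 0-based (`pos0`)
# and every interval is 0-based half-open [start, end); converters live only
# in this file so window arithmetic elsewhere is off-by-one free.

SNP_COLUMNS <- c("chrom", "pos", "ref", "alt",
                 "normal_ref", "normal_alt", "tumor_ref", "tumor_alt")
MUT_COLUMNS <- c("chrom", "pos", "ref", "alt", "sample_id",
                 "alt_reads", "depth")

.check_columns <- function(dt, required, what) {
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.sort_genomic <- function(dt, what) {
  ord <- order(dt$chrom, dt$pos0)
  if (is.unsorted(ord)) {
    warning(sprintf("%s was not position-sorted; sorting", what), call. = FALSE)
    dt <- dt[ord]
  }
  dt
}

#' Read a per-sample table of germline heterozygous-SNP allele counts
#'
#' Expects a tab-separated table with columns `chrom`, `pos` (1-based), `ref`,
#' `alt`, `normal_ref`, `normal_alt`, `tumor_ref`, `tumor_alt`. Rows are
#' filtered to credible heterozygous sites in the matched normal (normal VAF
#' inside `config$het_vaf_range` and normal depth `>= config$min_normal_depth`);
#' zero-depth rows are dropped and counted in a message. Chromosomes left with
#' no heterozygous SNPs are skipped with a warning.
#'
#' @param path File path (TSV, `#` comment lines ignored).
#' @param config A [pipeline_config()].
#' @return data.table with internal 0-based `pos0` plus per-SNP depths.
#' @export
read_snp_counts <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop("SNP count file not found: ", path)
  dt <- tryCatch(data.table::fread(path, sep = "\t", skip = "chrom"),
                 error = function(e) {
                   stop(basename(path), " is missing required column(s): chrom",
                        call. = FALSE)
                 })
  .check_columns(dt, SNP_COLUMNS, basename(path))
  dt[, `:=`(normal_depth = normal_ref + normal_alt,
            tumor_depth = tumor_ref + tumor_alt)]
  n0 <- nrow(dt)
  dt <- dt[normal_depth > 0 & tumor_depth > 0]
  if (nrow(dt) < n0) {
    message(sprintf("dropped %d zero-depth SNP row(s)", n0 - nrow(dt)))
  }
  nvaf <- dt$normal_alt / dt$normal_depth
  keep <- dt$normal_depth >= config$min_normal_depth &
    nvaf >= config$het_vaf_range[1] & nvaf <= config$het_vaf_range[2]
  all_chroms <- unique(dt$chrom)
  dt <- dt[keep]
  empty <- setdiff(all_chroms, unique(dt$chrom))
  if (length(empty)) {
    warning("no heterozygous SNPs on chromosome(s) ",
            paste(empty, collapse = ", "), "; skipped", call. = FALSE)
  }
  dt[, pos0 := pos - 1L]
  dt[, pos := NULL]
  .sort_genomic(dt, basename(path))[]
}

#' Read somatic mutation calls
#'
#' Accepts either a long-format TSV (columns `chrom`, `pos`, `ref`, `alt`,
#' `sample_id`, `alt_reads`, `depth`, optional `called` and `context`) or a
#' minimal VCF with per-sample `AD` fields (requires the VariantAnnotation
#' package). VAFs are computed as `alt_reads / depth`.
#'
#' @param path File path (`.vcf` dispatches to the VCF reader).
#' @return data.table, one row per mutation x sample, 0-based `pos0`.
#' @export
read_mutation_calls <- function(path) {
  if (!file.exists(path)) stop("mutation file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) return(.read_mutations_vcf(path))
  dt <- tryCatch(data.table::fread(path, sep = "\t", skip = "chrom"),
                 error = function(e) {
                   stop(basename(path), " is missing required column(s): chrom",
                        call. = FALSE)
                 })
  .check_columns(dt, MUT_COLUMNS, basename(path))
  if (!"called" %in% names(dt)) dt[, called := TRUE]
  dt[, pos0 := pos - 1L]
  dt[, pos := NULL]
  dt[, vaf_obs := ifelse(depth > 0, alt_reads / depth, NA_real_)]
  .sort_genomic(dt, basename(path))[]
}

.read_mutations_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF input requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop(basename(path), " is missing required column(s): AD")
  rr <- SummarizedExperiment::rowRanges(vcf)
  samples <- colnames(vcf)
  rows <- lapply(seq_along(samples), function(j) {
    counts <- ad[, j]
    refd <- vapply(counts, function(x) as.numeric(x[1]), 0)
    altd <- vapply(counts, function(x) as.numeric(x[2]), 0)
    data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos0 = BiocGenerics::start(rr) - 1L,
      ref = as.character(rr$REF),
      alt = vapply(rr$ALT, function(a) as.character(a[1]), ""),
      sample_id = samples[j],
      alt_reads = altd,
      depth = refd + altd)
  })
  dt <- data.table::rbindlist(rows)
  dt[, called := TRUE]
  dt[, vaf_obs := ifelse(depth > 0, alt_reads / depth, NA_real_)]
  .sort_genomic(dt, basename(path))[]
}

#' Read a per-patient sample manifest
#'
#' TSV with columns `patient_id`, `sample_id`, `site_label`,
#' `collection_order`, `snp_path`, `mutation_path`. Sample ids must be unique
#' within a patient and every referenced path must exist; relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @return data.table, one row per sample.
#' @export
read_manifest <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  .check_columns(dt, c("patient_id", "sample_id", "site_label",
                       "collection_order", "snp_path", "mutation_path"),
                 basename(path))
  if (anyDuplicated(dt[, c("patient_id", "sample_id")])) {
    stop("sample_id values must be unique within each patient")
  }
  if (any(dt$collection_order < 0)) stop("collection_order must be >= 0")
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  dt[, snp_path := fix(snp_path)]
  dt[, mutation_path := fix(mutation_path)]
  for (p in c(dt$snp_path, dt$mutation_path)) {
    if (!file.exists(p)) stop("manifest references missing file: ", p)
  }
  dt[]
}

#' Load all inputs referenced by a manifest
#'
#' @param manifest A data.table from [read_manifest()].
#' @param config A [pipeline_config()].
#' @return List with `snps` (per-sample list of SNP tables) and `mutations`
#'   (single long data.table).
#' @export
read_inputs <- function(manifest, config = pipeline_config()) {
  snps <- lapply(seq_len(nrow(manifest)), function(i) {
    read_snp_counts(manifest$snp_path[i], config)
  })
  names(snps) <- manifest$sample_id
  muts <- data.table::rbindlist(
    lapply(unique(manifest$mutation_path), read_mutation_calls),
    fill = TRUE)
  list(snps = snps, mutations = muts)
}

# ---- writers -----------------------------------------------------------

.write_with_header <- function(dt, path, config) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable output directory: ", dir)
  writeLines(output_header(config), path)
  suppressWarnings(data.table::fwrite(dt, path, sep = "\t", append = TRUE,
                                      col.names = TRUE))
  invisible(path)
}

#' Write segments as a SEG table
#'
#' Columns: `sample_id`, `chrom`, `start`, `end` (1-based inclusive), `nsnp`,
#' `cnh`, `cnl`, `cn_total`. A header line records tool version, configuration
#' hash, seed and the interval convention.
#'
#' @param segments Internal segment table (0-based half-open).
#' @param path Output path.
#' @param config A [pipeline_config()].
#' @export
write_seg <- function(segments, path, config = pipeline_config()) {
  cols <- intersect(c("sample_id", "chrom", "start", "end", "nsnp",
                      "m_seg", "ratio", "cnah", "cnal", "cnh", "cnl",
                      "cn_total"), names(segments))
  out <- data.table::as.data.table(segments)[, cols, with = FALSE]
  out[, start := start + 1]
  .write_with_header(out, path, config)
}

#' Read a SEG table written by [write_seg()]
#' @param path File path.
#' @return Internal segment table (0-based half-open intervals).
#' @export
read_seg <- function(path) {
  dt <- data.table::fread(path, sep = "\t", skip = "sample_id")
  dt[, start := start - 1]
  dt[]
}

#' Write / read the annotated mutation table
#'
#' All per-sample evidence and the heterogeneity / clonality labels in one
#' TSV; positions written 1-based.
#' @param mutations Internal mutation table.
#' @param path Output path.
#' @param config A [pipeline_config()].
#' @export
write_mutation_table <- function(mutations, path, config = pipeline_config()) {
  out <- data.table::copy(data.table::as.data.table(mutations))
  out[, pos := pos0 + 1L]
  out[, pos0 := NULL]
  data.table::setcolorder(out, intersect(c("chrom", "pos"), names(out)))
  .write_with_header(out, path, config)
}

#' @rdname write_mutation_table
#' @export
read_mutation_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", skip = "chrom")
  dt[, pos0 := pos - 1L]
  dt[, pos := NULL]
  dt[]
}

#' Write / read sample profiles and calibration results as JSON
#'
#' @param x List-like object (sample profiles, calibration summaries, ...).
#' @param path Output path.
#' @param config A [pipeline_config()].
#' @export
write_profiles_json <- function(x, path, config = pipeline_config()) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable output directory: ", dir)
  payload <- list(header = output_header(config), data = x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_profiles_json
#' @export
read_profiles_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)$data
}

#' Write a SNP count table (round-trip partner of [read_snp_counts()])
#' @param snps Internal SNP table.
#' @param path Output path.
#' @param config A [pipeline_config()].
#' @export
write_snp_counts <- function(snps, path, config = pipeline_config()) {
  out <- data.table::copy(data.table::as.data.table(snps))
  out[, pos := pos0 + 1L]
  drop <- intersect(c("pos0", "normal_depth", "tumor_depth"), names(out))
  out[, (drop) := NULL]
  data.table::setcolorder(out, SNP_COLUMNS)
  .write_with_header(out, path, config)
}
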