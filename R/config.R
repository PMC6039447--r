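#' Pipeline configuration
#'
#' Bundles every tunable constant of the pipeline with its default. Defaults
#' are the calibrated values used throughout: 4 Mb bins sliding by 1 Mb with
#' at least 40 heterozygous SNPs per bin; a candidate breakpoint when adjacent
#' bin BAFs differ by more than 0.015 (empirical p = 0.05 under the equal-BAF
#' simulation) and confirmation at 0.018 in the refinement scan; samples below
#' 20% tumor purity excluded; mutation detection powered at 95% for one
#' mutated allele out of four; rescue of uncalled mutations against a 1/200
#' error rate; signature fitting refused below 10 mutations, contributions
#' under 5% suppressed.
#'
#' @param bin_size_bp Sliding-bin width in bp.
#' @param step_size_bp Bin step in bp; must not exceed `bin_size_bp`.
#' @param min_snps_per_bin Bins with fewer het SNPs are merged into a neighbor.
#' @param candidate_cutoff BAF difference between adjacent bins that opens a
#'   candidate breakpoint region.
#' @param refine_cutoff Major-allele-frequency contrast confirming a
#'   breakpoint in the windowed refinement scan.
#' @param min_purity Samples with estimated purity below this are flagged
#'   excluded.
#' @param detection_probability Required power of the per-sample depth
#'   threshold for calling a mutation absent.
#' @param rescue_error_rate Sequencing error rate for the rescue binomial test.
#' @param signature_min_mutations Minimum mutation count for signature fitting.
#' @param signature_report_threshold Signature weights below this fraction are
#'   zeroed and the rest renormalized.
#' @param min_normal_depth,het_vaf_range Heterozygous-SNP selection in the
#'   matched normal: depth at least `min_normal_depth` and normal VAF inside
#'   `het_vaf_range`.
#' @param sd_test_alpha Significance level of the variance-ratio test deciding
#'   whether a bin's tumor allele frequencies differ from the normal's.
#' @param refine_flank_bp,refine_window_snps Refinement scan geometry.
#' @param wgd_ploidy_hi,wgd_ploidy_lo,wgd_minor2_frac Deterministic
#'   whole-genome-duplication call: ploidy >= `wgd_ploidy_hi`, or ploidy >=
#'   `wgd_ploidy_lo` with at least `wgd_minor2_frac` of the genome at minor
#'   allele copy number >= 2.
#' @param exclude_sex_chroms Drop X/Y from purity, ploidy and WGD estimation
#'   (the formulas assume a diploid normal baseline).
#' @param random_seed Seed recorded in every output header.
#' @return A list of class `cne_config`.
#' @export
pipeline_config <- function(bin_size_bp = 4e6,
                            step_size_bp = 1e6,
                            min_snps_per_bin = 40L,
                            candidate_cutoff = 0.015,
                            refine_cutoff = 0.018,
                            min_purity = 0.20,
                            detection_probability = 0.95,
                            rescue_error_rate = 1 / 200,
                            signature_min_mutations = 10L,
                            signature_report_threshold = 0.05,
                            min_normal_depth = 8L,
                            het_vaf_range = c(0.2, 0.8),
                            sd_test_alpha = 0.05,
                            refine_flank_bp = 4e6,
                            refine_window_snps = 3L,
                            wgd_ploidy_hi = 3.0,
                            wgd_ploidy_lo = 2.6,
                            wgd_minor2_frac = 0.25,
                            exclude_sex_chroms = TRUE,
                            random_seed = 1L) {
  cutoffs <- c(candidate_cutoff, refine_cutoff, min_purity,
               detection_probability, rescue_error_rate,
               signature_report_threshold)
  if (any(cutoffs <= 0 | cutoffs >= 1)) {
    stop("all cutoffs and probabilities must lie strictly inside (0, 1)")
  }
  if (bin_size_bp < step_size_bp) stop("bin_size_bp must be >= step_size_bp")
  stopifnot(min_snps_per_bin >= 1, refine_window_snps >= 1,
            length(het_vaf_range) == 2L, het_vaf_range[1] < het_vaf_range[2])
  cfg <- list(bin_size_bp = bin_size_bp, step_size_bp = step_size_bp,
              min_snps_per_bin = as.integer(min_snps_per_bin),
              candidate_cutoff = candidate_cutoff,
              refine_cutoff = refine_cutoff,
              min_purity = min_purity,
              detection_probability = detection_probability,
              rescue_error_rate = rescue_error_rate,
              signature_min_mutations = as.integer(signature_min_mutations),
              signature_report_threshold = signature_report_threshold,
              min_normal_depth = as.integer(min_normal_depth),
              het_vaf_range = het_vaf_range,
              sd_test_alpha = sd_test_alpha,
              refine_flank_bp = refine_flank_bp,
              refine_window_snps = as.integer(refine_window_snps),
              wgd_ploidy_hi = wgd_ploidy_hi,
              wgd_ploidy_lo = wgd_ploidy_lo,
              wgd_minor2_frac = wgd_minor2_frac,
              exclude_sex_chroms = exclude_sex_chroms,
              random_seed = as.integer(random_seed))
  class(cfg) <- "cne_config"
  cfg
}

# Fingerprint used in output file headers.
config_hash <- function(config) {
  fnv1a_hash(paste(names(config), unlist(config), collapse = ";"))
}

output_header <- function(config) {
  sprintf("#cnevolve %s; config=%s; seed=%d; intervals=1-based inclusive",
          as.character(utils::packageVersion("cnevolve")),
          config_hash(config), config$random_seed)
}
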