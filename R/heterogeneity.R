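# Trunk / branch / private classification with detectability rules,
# relative VAF and clonality, polyclonal-seeding evidence, and mutational
# diversity.

#' Sample-specific detection depth threshold
#'
#' Smallest depth at which a mutation on one of four alleles would be
#' detected (at least two supporting reads) with probability at least
#' `detection_probability`, given the sample's tumor cell fraction `rho`:
#' expected VAF `p = rho / (2 (1 - rho) + 4 rho)`, exact binomial tail.
#' Yields 56 at `rho = 0.20` and 18 at `rho = 1`.
#'
#' @param rho Tumor cell fraction in (0, 1].
#' @param detection_probability Required detection power (default 0.95).
#' @return Integer depth threshold.
#' @export
detection_depth_threshold <- function(rho, detection_probability = 0.95) {
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  p <- rho / (2 * (1 - rho) + 4 * rho)
  d <- 2L
  while (stats::pbinom(1L, d, p) > 1 - detection_probability) {
    d <- d + 1L
    if (d > 1e6) stop("no attainable depth threshold")
  }
  d
}

#' Rescue an uncalled mutation from raw read support
#'
#' A mutation missed by the caller is deemed present when more than one read
#' supports it and that support exceeds sequencing error: one-sided binomial
#' tail `P(X >= alt_reads | depth, error_rate) < 0.05`.
#'
#' @param alt_reads,depth Observed support.
#' @param error_rate Sequencing error rate (default 1/200).
#' @param p_cutoff Binomial test level (default 0.05).
#' @return Logical: present?
#' @export
rescue_uncalled <- function(alt_reads, depth, error_rate = 1 / 200,
                            p_cutoff = 0.05) {
  stopifnot(depth >= alt_reads, alt_reads >= 0)
  if (alt_reads <= 1L) return(FALSE)
  tail_p <- stats::pbinom(alt_reads - 1L, depth, error_rate,
                          lower.tail = FALSE)
  tail_p < p_cutoff
}

#' Classify mutations as trunk, branch or private within a patient
#'
#' Presence per sample is called-or-rescued. An absence is excused when the
#' locus sits at a copy-number loss relative to the carrier samples (total
#' copy number below the carriers' minimum) or when the sample's depth at
#' the position is below its detection threshold. Trunk: present everywhere,
#' or every absence excused. Private: present in exactly one sample with no
#' absence excused. Branch: everything else.
#'
#' @param mutations Long mutation table (one row per mutation x sample) with
#'   `chrom`, `pos0`, `sample_id`, `alt_reads`, `depth`, `called`.
#' @param seg_list Named list of per-sample segment tables with integer
#'   calls.
#' @param profiles Named list of sample profiles (needs `purity`).
#' @param config A [pipeline_config()].
#' @return The table with `present`, `absence_excused`, and a patient-level
#'   `label` column (same value on every row of a mutation).
#' @export
classify_heterogeneity <- function(mutations, seg_list, profiles,
                                   config = pipeline_config()) {
  mutations <- data.table::copy(data.table::as.data.table(mutations))
  samples <- names(seg_list)
  if (length(samples) < 2L) {
    mutations[, label := NA_character_]
    return(mutations[])
  }
  thresholds <- vapply(samples, function(s) {
    detection_depth_threshold(profiles[[s]]$purity,
                              config$detection_probability)
  }, 0L)
  mutations[, rescued := !called &
              mapply(rescue_uncalled, alt_reads, depth,
                     MoreArgs = list(error_rate = config$rescue_error_rate))]
  mutations[, present := called | rescued]
  cn_at <- function(s, chrom, pos0) {
    segs <- data.table::as.data.table(seg_list[[s]])
    idx <- .overlap_rows(data.table::data.table(chrom = chrom, pos0 = pos0),
                         segs)
    segs$cn_total[idx]
  }
  mutations[, cn_locus := cn_at(.BY$sample_id, chrom, pos0),
            by = sample_id]
  mutations[, mut_key := paste(chrom, pos0, ref, alt, sep = ":")]
  lab <- mutations[, {
    pres <- present
    carrier_cn <- cn_locus[pres]
    min_carrier <- if (any(pres)) min(carrier_cn, na.rm = TRUE) else NA
    excused <- !pres & (depth < thresholds[sample_id] |
                          (!is.na(cn_locus) & !is.na(min_carrier) &
                             cn_locus < min_carrier))
    n_present <- sum(pres)
    label <- if (n_present == 0L) {
      NA_character_
    } else if (all(pres | excused)) {
      "trunk"
    } else if (n_present == 1L && !any(excused)) {
      "private"
    } else {
      "branch"
    }
    .(label = label, absence_excused = excused, row = .I)
  }, by = mut_key]
  mutations[lab$row, `:=`(label = lab$label,
                          absence_excused = lab$absence_excused)]
  mutations[, mut_key := NULL]
  mutations[]
}

#' Relative VAF of a mutation
#'
#' Ratio of observed to expected VAF given mutated-allele count, local total
#' copy number and tumor cell content:
#' `rVAF = VAF_obs / (n_mut rho / (2 (1 - rho) + n_tot rho))`.
#'
#' @param vaf_obs Observed variant allele frequency.
#' @param n_mut Mutated-allele count (>= 1).
#' @param n_tot Total copy number at the locus (>= 1).
#' @param rho Tumor cell content in (0, 1].
#' @return Relative VAF (vectorized).
#' @export
compute_rvaf <- function(vaf_obs, n_mut, n_tot, rho) {
  if (any(rho <= 0) || any(n_mut <= 0) || any(n_tot <= 0)) {
    stop("rho, n_mut and n_tot must be positive")
  }
  vaf_exp <- (n_mut * rho) / (2 * (1 - rho) + n_tot * rho)
  vaf_obs / vaf_exp
}

#' Clonality from the trunk rVAF distribution
#'
#' Per sample, the interquartile range of trunk-mutation rVAFs defines the
#' clonal band: a mutation is subclonal below `Q1 - 1.5 IQR`, otherwise
#' clonal when its rVAF reaches half the trunk median, otherwise of unknown
#' clonality. Quantiles are linear-interpolation (type 7). With fewer than
#' `min_trunk` trunk mutations everything is unknown.
#'
#' @param rvaf rVAFs to classify.
#' @param trunk_rvaf Trunk-mutation rVAFs of the same sample.
#' @param min_trunk Minimum trunk count for a stable IQR (default 10).
#' @return Character vector: "clonal", "subclonal" or "unknown".
#' @export
classify_clonality <- function(rvaf, trunk_rvaf, min_trunk = 10L) {
  trunk_rvaf <- trunk_rvaf[is.finite(trunk_rvaf)]
  if (length(trunk_rvaf) < min_trunk) {
    warning("fewer than ", min_trunk,
            " trunk mutations; clonality unknown", call. = FALSE)
    return(rep("unknown", length(rvaf)))
  }
  q <- stats::quantile(trunk_rvaf, c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  lower <- q[1] - 1.5 * (q[3] - q[1])
  ifelse(rvaf < lower, "subclonal",
         ifelse(rvaf >= 0.5 * q[2], "clonal", "unknown"))
}

#' Polyclonal-seeding evidence for a patient
#'
#' A lesion carrying at least one clonal private mutation cannot have been
#' seeded polyclonally. Mutations subclonal in two or more samples are
#' listed as possible evidence of a shared subclone.
#'
#' @param mutations Long annotated table with `sample_id`, `label`,
#'   `clonality`, `present`, and locus columns.
#' @return List: `has_clonal_private` (named logical per sample),
#'   `shared_subclonal` (table of loci subclonal in >= 2 samples).
#' @export
evaluate_polyclonal_seeding <- function(mutations) {
  mutations <- data.table::as.data.table(mutations)
  by_sample <- mutations[present == TRUE,
                         .(flag = any(label == "private" &
                                        clonality == "clonal", na.rm = TRUE)),
                         by = sample_id]
  shared <- mutations[present == TRUE & clonality == "subclonal",
                      .(n_subclonal = .N), by = .(chrom, pos0, ref, alt)]
  shared <- shared[n_subclonal >= 2L]
  list(has_clonal_private = stats::setNames(by_sample$flag,
                                            by_sample$sample_id),
       shared_subclonal = shared)
}

#' Mutational diversity of a patient
#'
#' Average over lesions of the number of branch mutations (private included)
#' present in the lesion. Undefined for single-sample patients.
#'
#' @param mutations Long annotated table with `sample_id`, `label`,
#'   `present`.
#' @return Scalar mean branch-mutation count (`NA` if not applicable).
#' @export
mutational_diversity <- function(mutations) {
  mutations <- data.table::as.data.table(mutations)
  samples <- unique(mutations$sample_id)
  if (length(samples) < 2L) return(NA_real_)
  counts <- vapply(samples, function(s) {
    nrow(mutations[sample_id == s & present == TRUE &
                     label %in% c("branch", "private")])
  }, 0L)
  mean(counts)
}
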