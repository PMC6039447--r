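# Simulation machinery behind the segmentation cutoffs.
#
# Two simulations: (1) equal-BAF datasets quantifying how far the mean BAFs
# of two adjacent segments drift apart by chance alone, giving the empirical
# p-value of a candidate cutoff (0.015 <-> p = 0.05); (2) a purity x total
# copy number grid scoring how often the confirmation cutoff (0.018) falsely
# splits identical allelic states (FPR) or misses genuinely different ones
# (FNR). Segment BAF is the mean of per-SNP allele-fraction ratios, the
# statistic whose noise scale reproduces the calibrated cutoff.

# Mean per-SNP allele fraction of `n_segments` segments with SNP counts
# drawn uniformly from k_range, depths geometric(p_geom), counts B(N, baf).
# `baf` may be a vector (one theoretical BAF per segment).
.sim_segment_means <- function(n_segments, baf, k_range, p_geom) {
  baf <- rep_len(baf, n_segments)
  k <- sample.int(k_range[2] - k_range[1] + 1L, n_segments,
                  replace = TRUE) + k_range[1] - 1L
  seg <- rep.int(seq_len(n_segments), k)
  N <- rdepth_geom(length(seg), p_geom)
  B <- stats::rbinom(length(seg), N, rep.int(baf, k))
  as.numeric(rowsum(B / N, seg) / k)
}

#' Equal-BAF calibration simulation
#'
#' For every theoretical BAF on `baf_grid`, simulates `n_datasets` datasets
#' of `n_segments` segments sharing that BAF (SNP counts uniform on
#' `k_range`, depths geometric `p_geom`, allelic counts binomial) and records
#' all absolute differences in mean BAF between adjacent segments.
#'
#' @param baf_grid Theoretical BAFs (default 0 to 1 by 0.01).
#' @param n_datasets Datasets per BAF (1000 at full scale).
#' @param n_segments Segments per dataset (40).
#' @param k_range SNP count range per segment (40 to 1200).
#' @param p_geom Geometric depth parameter (0.01).
#' @param seed Integer seed.
#' @return Object of class `cne_calibration`: per-BAF multisets of
#'   adjacent-segment differences plus the simulation dimensions.
#' @export
simulate_equal_baf <- function(baf_grid = seq(0, 1, by = 0.01),
                               n_datasets = 1000L, n_segments = 40L,
                               k_range = c(40L, 1200L), p_geom = 0.01,
                               seed = 1L) {
  stopifnot(all(baf_grid >= 0), all(baf_grid <= 1), n_segments >= 2)
  deltas <- withr::with_seed(seed, lapply(baf_grid, function(baf) {
    means <- matrix(.sim_segment_means(n_datasets * n_segments, baf,
                                       k_range, p_geom),
                    nrow = n_segments)
    abs(means[-1L, , drop = FALSE] - means[-n_segments, , drop = FALSE])
  }))
  structure(list(baf_grid = baf_grid, deltas = deltas,
                 n_datasets = n_datasets, n_segments = n_segments,
                 k_range = k_range, p_geom = p_geom),
            class = "cne_calibration")
}

#' Empirical p-value of a BAF-difference cutoff
#'
#' `p = #(delta >= cutoff) / ((n_segments - 1) * n_datasets)` per theoretical
#' BAF; the pooled value averages over the BAF grid.
#'
#' @param calib A [simulate_equal_baf()] result.
#' @param cutoff BAF-difference cutoff in (0, 1).
#' @return List with `per_baf` (vector along the grid) and `pooled`.
#' @export
empirical_p <- function(calib, cutoff) {
  stopifnot(inherits(calib, "cne_calibration"))
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  denom <- (calib$n_segments - 1L) * calib$n_datasets
  per_baf <- vapply(calib$deltas, function(d) sum(d >= cutoff) / denom, 0)
  list(per_baf = per_baf, pooled = mean(per_baf))
}

#' Cutoff at which the pooled empirical p crosses a target
#'
#' @param calib A [simulate_equal_baf()] result.
#' @param target_p Target pooled empirical p (default 0.05).
#' @param grid Cutoff grid scanned (default 0.001 steps).
#' @return Smallest cutoff with pooled empirical p `<= target_p`.
#' @export
calibration_cutoff <- function(calib, target_p = 0.05,
                               grid = seq(0.001, 0.1, by = 0.001)) {
  pooled <- vapply(grid, function(ct) empirical_p(calib, ct)$pooled, 0)
  if (all(pooled > target_p)) return(NA_real_)
  grid[which(pooled <= target_p)[1L]]
}

#' Maximum adjacent-segment difference across the simulation
#' @param calib A [simulate_equal_baf()] result.
#' @return List with `max_delta` (global maximum), `per_baf` maxima and the
#'   per-BAF mean absolute differences.
#' @export
calibration_max_error <- function(calib) {
  per_baf <- vapply(calib$deltas, max, 0)
  list(max_delta = max(per_baf), per_baf = per_baf,
       mean_per_baf = vapply(calib$deltas, mean, 0))
}

#' False positive / negative rates of the segmentation cutoff
#'
#' For every (tumor purity, total copy number) cell, simulates `n_segments`
#' adjacent segments whose allele-specific state (major/minor split of the
#' cell's total copy number) is drawn uniformly per segment; the expected
#' major allele frequency follows the purity mixture formula. Adjacent pairs
#' sharing a state score the false positive rate (split although identical);
#' pairs with different states score the false negative rate (not split
#' although different), both at the confirmation cutoff.
#'
#' @param purities Tumor purity grid (default 1-100%).
#' @param total_cn Total copy numbers (default 1:8).
#' @param n_segments Segments per cell (1000 at full scale).
#' @param cutoff Split cutoff on the mean-BAF difference (default 0.018).
#' @param k_range,p_geom As in [simulate_equal_baf()].
#' @param seed Integer seed.
#' @return Object of class `cne_fdr`: per-cell grid (data.table with `fpr`,
#'   `fnr`, pair counts) and `global_fpr` / `global_fnr` averages (percent
#'   scale is left to the caller; values are proportions).
#' @export
estimate_fpr_fnr <- function(purities = seq(0.01, 1, by = 0.01),
                             total_cn = 1:8, n_segments = 1000L,
                             cutoff = 0.018, k_range = c(40L, 1200L),
                             p_geom = 0.01, seed = 1L) {
  stopifnot(all(purities > 0), all(purities <= 1), all(total_cn >= 1))
  cells <- data.table::CJ(purity = purities, cn = total_cn)
  res <- withr::with_seed(seed, lapply(seq_len(nrow(cells)), function(i) {
    alpha <- cells$purity[i]
    cn <- cells$cn[i]
    cnh <- seq.int(ceiling(cn / 2), cn)        # uniform major/minor splits
    state <- sample.int(length(cnh), n_segments, replace = TRUE)
    f <- (alpha * cnh[state] + (1 - alpha)) /
      (alpha * cn + 2 * (1 - alpha))
    means <- .sim_segment_means(n_segments, f, k_range, p_geom)
    delta <- abs(diff(means))
    same <- state[-1L] == state[-n_segments]
    split <- delta > cutoff
    list(fpr = if (any(same)) mean(split[same]) else NA_real_,
         fnr = if (any(!same)) mean(!split[!same]) else NA_real_,
         n_same = sum(same), n_diff = sum(!same))
  }))
  cells[, fpr := vapply(res, `[[`, 0, "fpr")]
  cells[, fnr := vapply(res, `[[`, 0, "fnr")]
  cells[, n_same := vapply(res, `[[`, 0L, "n_same")]
  cells[, n_diff := vapply(res, `[[`, 0L, "n_diff")]
  structure(list(grid = cells,
                 global_fpr = mean(cells$fpr, na.rm = TRUE),
                 global_fnr = mean(cells$fnr, na.rm = TRUE),
                 cutoff = cutoff, n_segments = n_segments),
            class = "cne_fdr")
}
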