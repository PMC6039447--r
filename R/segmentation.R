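# BAF segmentation: split each tumor genome into segments of constant
# allelic imbalance from shifts in heterozygous-SNP allele frequencies.
#
# Stages: sliding 4 Mb bins (1 Mb step, >= 40 SNPs after merging); bin BAF
# b_i (0.5 when the tumor's per-SNP major-allele-frequency spread does not
# differ from the normal's, otherwise the tumor median); candidate
# breakpoints where adjacent bins differ by more than 0.015; windowed
# refinement at 0.018 within +/- 4 Mb; final segments tile the SNP-covered
# genome between refined breakpoints.

# Segment major allele frequency by method of moments on the unfolded
# B-allele ratios. Folding per-SNP ratios (max of the two alleles) biases
# the median upward near balanced states; instead, with b the per-SNP ratio
# and N its depth, E[(b - 1/2)^2] = (f - 1/2)^2 + f(1-f) E[1/N] and
# E[b(1-b)] = f(1-f)(1 - E[1/N]) identify (f - 1/2)^2 without bias,
# independent of SNP phase. Negative estimates clamp to a balanced 0.5.
.segment_major_freq <- function(s) {
  depth <- s$tumor_alt + s$tumor_ref
  b <- s$tumor_alt / depth
  u <- mean(1 / depth)
  if (u >= 1) return(stats::median(s$m_tumor))
  A <- mean(b * (1 - b)) / (1 - u)     # estimates f(1-f)
  B <- mean((b - 0.5)^2)
  0.5 + sqrt(max(0, B - u * A))
}

# Per-SNP major allele frequency in tumor and normal.
.add_major_freq <- function(snps) {
  snps <- data.table::as.data.table(snps)
  snps[, m_tumor := pmax(tumor_alt, tumor_ref) / (tumor_alt + tumor_ref)]
  snps[, m_normal := pmax(normal_alt, normal_ref) / (normal_alt + normal_ref)]
  snps
}

#' Sliding genomic bins
#'
#' Cuts each chromosome into `bin_size_bp` windows advancing by
#' `step_size_bp`; windows with fewer than `min_snps_per_bin` SNPs are merged
#' with the nearest neighboring bin (midpoint distance, ties to the left)
#' until every bin satisfies the minimum. A chromosome whose total SNP count
#' is below the minimum yields a single bin with a warning.
#'
#' @param snps Single-sample SNP table (from [read_snp_counts()] or
#'   [simulate_reads()]).
#' @param config A [pipeline_config()].
#' @return data.table of bins: `chrom`, `start`, `end` (0-based half-open),
#'   `k` (SNP count), `first`/`last` SNP row indices.
#' @export
bin_genome <- function(snps, config = pipeline_config()) {
  snps <- data.table::as.data.table(snps)[order(chrom, pos0)]
  out <- lapply(unique(snps$chrom), function(ch) {
    pos <- snps[chrom == ch, pos0]
    if (length(pos) == 0L) {
      warning("chromosome ", ch, " has no SNPs; no bins produced",
              call. = FALSE)
      return(NULL)
    }
    span_end <- max(pos) + 1
    if (length(pos) < config$min_snps_per_bin) {
      warning("chromosome ", ch, " has fewer than ", config$min_snps_per_bin,
              " SNPs; using a single bin", call. = FALSE)
      return(data.table::data.table(chrom = ch, start = min(pos),
                                    end = span_end, k = length(pos)))
    }
    # bins live on the step lattice; round the SNP span up to it
    lattice_end <- ceiling(span_end / config$step_size_bp) *
      config$step_size_bp
    starts <- seq(0, max(0, lattice_end - config$bin_size_bp),
                  by = config$step_size_bp)
    bins <- data.table::data.table(chrom = ch, start = starts,
                                   end = pmin(starts + config$bin_size_bp,
                                              span_end))
    bins[, k := findInterval(end - 1e-9, pos) - findInterval(start - 1e-9, pos)]
    .merge_small_bins(bins, config$min_snps_per_bin, pos)
  })
  data.table::rbindlist(out)
}

# Iteratively merge deficient bins with their nearest neighbor (by midpoint
# distance; ties broken toward the smaller coordinate).
.merge_small_bins <- function(bins, min_k, pos) {
  count <- function(s, e) {
    findInterval(e - 1e-9, pos) - findInterval(s - 1e-9, pos)
  }
  while (nrow(bins) > 1L && any(bins$k < min_k)) {
    i <- which(bins$k < min_k)[1L]
    mid <- (bins$start + bins$end) / 2
    left_d <- if (i > 1L) mid[i] - mid[i - 1L] else Inf
    right_d <- if (i < nrow(bins)) mid[i + 1L] - mid[i] else Inf
    j <- if (left_d <= right_d) i - 1L else i + 1L
    a <- min(i, j); b <- max(i, j)
    bins$start[a] <- min(bins$start[a], bins$start[b])
    bins$end[a] <- max(bins$end[a], bins$end[b])
    # sliding windows overlap: recount the union span rather than add counts
    bins$k[a] <- count(bins$start[a], bins$end[a])
    bins <- bins[-b, ]
  }
  bins
}

#' Bin B-allele frequency
#'
#' Compares the spread of per-SNP major allele frequencies between tumor and
#' normal with a two-sided variance-ratio test. When the spreads do not
#' differ (p >= `sd_test_alpha`) the bin is balanced and `b = 0.5`; otherwise
#' `b` is the median tumor major allele frequency.
#'
#' @param m_tumor,m_normal Per-SNP major allele frequencies inside the bin.
#' @param config A [pipeline_config()].
#' @return Scalar bin BAF in `[0.5, 1]`.
#' @export
bin_baf <- function(m_tumor, m_normal, config = pipeline_config()) {
  vt <- stats::var(m_tumor)
  vn <- stats::var(m_normal)
  if (!is.finite(vt) || !is.finite(vn) || (vt == 0 && vn == 0)) return(0.5)
  p <- tryCatch(stats::var.test(m_tumor, m_normal)$p.value,
                error = function(e) 1)
  if (is.na(p) || p >= config$sd_test_alpha) 0.5 else
    max(0.5, stats::median(m_tumor))
}

# Bin BAFs for a whole bin table; returns the bins with columns b, k.
.bins_with_baf <- function(snps, bins, config) {
  snps <- .add_major_freq(snps)
  b <- vapply(seq_len(nrow(bins)), function(i) {
    sel <- snps$chrom == bins$chrom[i] & snps$pos0 >= bins$start[i] &
      snps$pos0 < bins$end[i]
    bin_baf(snps$m_tumor[sel], snps$m_normal[sel], config)
  }, 0)
  bins <- data.table::copy(bins)
  bins[, b := b]
  bins
}

#' Candidate breakpoints from adjacent-bin BAF differences
#'
#' Flags adjacent bin pairs whose BAF differs by strictly more than
#' `candidate_cutoff`; runs of consecutive exceedances collapse to the pairs
#' at local maxima of the difference (a run can straddle two nearby true
#' boundaries, so collapsing to the single global maximum loses breakpoints;
#' spurious local maxima are discarded downstream by refinement). The
#' candidate position is the midpoint between the two bin midpoints.
#'
#' @param bins Bin table with column `b` (see [bin_baf()]).
#' @param config A [pipeline_config()].
#' @return data.table of candidates: `chrom`, `position`, `delta_baf`.
#' @export
find_candidate_breakpoints <- function(bins, config = pipeline_config()) {
  out <- lapply(unique(bins$chrom), function(ch) {
    bb <- bins[bins$chrom == ch, ]
    if (nrow(bb) < 2L) return(NULL)
    delta <- abs(diff(bb$b))
    exceed <- delta > config$candidate_cutoff
    if (!any(exceed)) return(NULL)
    runs <- rle(exceed)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    picks <- unlist(lapply(which(runs$values), function(r) {
      idx <- starts[r]:ends[r]
      d <- delta[idx]
      n <- length(d)
      local_max <- d >= c(-Inf, d[-n]) & d > c(d[-1], -Inf)
      idx[local_max]
    }))
    mids <- (bb$start + bb$end) / 2
    data.table::data.table(chrom = ch,
                           position = (mids[picks] + mids[picks + 1L]) / 2,
                           delta_baf = delta[picks],
                           source = "candidate")
  })
  data.table::rbindlist(out)
}

#' Refine one candidate breakpoint
#'
#' SNPs within `refine_flank_bp` of the candidate are cut into consecutive
#' windows of `refine_window_snps` SNPs. For every prefix/remainder split the
#' contrast between read-weighted mean major allele frequencies is computed
#' (read pooling keeps the heavy low-depth tail of exome coverage from
#' dominating the statistic); among splits whose contrast exceeds
#' `refine_cutoff` and leave at least 40 SNPs on each side (the floor of the
#' cutoff calibration), the split maximizing the size-standardized contrast
#' (`|m1 - m2| * sqrt(n1 n2 / n)`, the two-sample change-point statistic,
#' whose noiseless maximum sits exactly at the step) fixes the breakpoint at
#' the midpoint between the two sub-regions. If no split qualifies the
#' candidate is discarded (`NULL`).
#'
#' @param snps Single-sample SNP table.
#' @param candidate One-row candidate (or list with `chrom`, `position`).
#' @param config A [pipeline_config()].
#' @return One-row data.table (`chrom`, `position`, `delta_baf`, `source =
#'   "refined"`) or `NULL`.
#' @export
refine_breakpoint <- function(snps, candidate, config = pipeline_config()) {
  snps <- .add_major_freq(snps)
  sel <- snps$chrom == candidate$chrom &
    snps$pos0 >= candidate$position - config$refine_flank_bp &
    snps$pos0 < candidate$position + config$refine_flank_bp
  flank <- snps[sel][order(pos0)]
  w <- config$refine_window_snps
  n_windows <- nrow(flank) %/% w
  if (n_windows < 2L) {
    warning("candidate at ", candidate$chrom, ":", round(candidate$position),
            " has fewer than 2 refinement windows; discarded", call. = FALSE)
    return(NULL)
  }
  use <- seq_len(n_windows * w)
  split <- .best_split(maj = pmax(flank$tumor_alt, flank$tumor_ref)[use],
                       depth = (flank$tumor_alt + flank$tumor_ref)[use],
                       window = w, cutoff = config$refine_cutoff,
                       min_side = min(config$min_snps_per_bin,
                                      floor(length(use) / 3)))
  if (is.null(split)) return(NULL)
  bp <- (flank$pos0[split$cut] + flank$pos0[split$cut + 1L]) / 2
  data.table::data.table(chrom = candidate$chrom, position = bp,
                         delta_baf = split$contrast, source = "refined")
}

# Best prefix/remainder split of a SNP run at window granularity: contrast
# is the difference of read-pooled major allele frequencies; qualifying
# splits exceed `cutoff` with at least `min_side` SNPs per side; the
# size-standardized contrast picks among them. NULL when nothing qualifies.
.best_split <- function(maj, depth, window, cutoff, min_side) {
  n <- length(maj)
  n_windows <- n %/% window
  if (n_windows < 2L) return(NULL)
  cuts <- seq_len(n_windows - 1L) * window
  cmaj <- cumsum(as.numeric(maj))
  cdep <- cumsum(as.numeric(depth))
  pre <- cmaj[cuts] / cdep[cuts]
  post <- (cmaj[n] - cmaj[cuts]) / (cdep[n] - cdep[cuts])
  contrast <- abs(pre - post)
  ok <- contrast > cutoff & cuts >= min_side & (n - cuts) >= min_side
  if (!any(ok)) return(NULL)
  standardized <- contrast * sqrt(cuts * (n - cuts) / n)
  best <- which(ok)[which.max(standardized[ok])]
  list(cut = cuts[best], contrast = contrast[best])
}

#' Segment a tumor genome
#'
#' Runs the full segmentation for one sample: bins, bin BAFs, candidate
#' detection, refinement, and tiling of each chromosome between refined
#' breakpoints. Per segment it reports the SNP count, the median (`m_seg`)
#' and maximum per-SNP major allele frequency, and the tumor/normal depth
#' ratio normalized so its SNP-weighted genome-wide mean is 1.
#'
#' @param snps Single-sample SNP table.
#' @param config A [pipeline_config()].
#' @return data.table of segments (0-based half-open), one chromosome tiling.
#' @export
segment_genome <- function(snps, config = pipeline_config()) {
  snps <- .add_major_freq(data.table::as.data.table(snps))[order(chrom, pos0)]
  bins <- bin_genome(snps, config)
  bins <- .bins_with_baf(snps, bins, config)
  cands <- find_candidate_breakpoints(bins, config)
  breakpoints <- if (nrow(cands) == 0L) cands else data.table::rbindlist(
    Filter(Negate(is.null), lapply(seq_len(nrow(cands)), function(i) {
      refine_breakpoint(snps, cands[i, ], config)
    })))
  # merging of segments: refined breakpoints closer than one bin step are
  # duplicate detections of the same boundary; keep the strongest
  if (nrow(breakpoints) > 1L) {
    breakpoints <- breakpoints[order(chrom, position)]
    keep <- rep(TRUE, nrow(breakpoints))
    for (i in 2:nrow(breakpoints)) {
      prev <- max(which(keep[1:(i - 1L)]))
      if (breakpoints$chrom[i] == breakpoints$chrom[prev] &&
          breakpoints$position[i] - breakpoints$position[prev] <
            config$step_size_bp) {
        drop_i <- if (breakpoints$delta_baf[i] >=
                        breakpoints$delta_baf[prev]) prev else i
        keep[drop_i] <- FALSE
      }
    }
    breakpoints <- breakpoints[keep]
  }
  segs <- lapply(unique(snps$chrom), function(ch) {
    sc <- snps[chrom == ch]
    pos <- sc$pos0
    bps <- sort(breakpoints[breakpoints$chrom == ch, ]$position)
    edges <- c(min(pos), bps, max(pos) + 1)
    # recursive pass: a refinement flank can contain more than one true
    # boundary (only the strongest survives above), so re-scan every
    # assembled segment with the same split statistic until stable
    maj <- pmax(sc$tumor_alt, sc$tumor_ref)
    dep <- sc$tumor_alt + sc$tumor_ref
    queue <- Map(c, head(edges, -1), tail(edges, -1))
    final <- numeric(0)
    guard <- 0L
    while (length(queue) && guard < 200L) {
      guard <- guard + 1L
      iv <- queue[[1L]]
      queue <- queue[-1L]
      sel <- which(pos >= iv[1] & pos < iv[2])
      split <- if (length(sel) >= 2L * config$min_snps_per_bin) {
        .best_split(maj[sel], dep[sel], config$refine_window_snps,
                    config$refine_cutoff, config$min_snps_per_bin)
      }
      if (is.null(split)) {
        final <- c(final, iv[1])
      } else {
        mid <- (pos[sel[split$cut]] + pos[sel[split$cut + 1L]]) / 2
        queue <- c(list(c(iv[1], mid), c(mid, iv[2])), queue)
      }
    }
    edges <- sort(unique(c(final, max(pos) + 1)))
    data.table::data.table(chrom = ch, start = edges[-length(edges)],
                           end = edges[-1])
  })
  segs <- data.table::rbindlist(segs)
  stats_ <- lapply(seq_len(nrow(segs)), function(i) {
    s <- snps[chrom == segs$chrom[i] & pos0 >= segs$start[i] &
                pos0 < segs$end[i]]
    list(nsnp = nrow(s), m_seg = .segment_major_freq(s),
         m_med = stats::median(s$m_tumor),
         m_max = suppressWarnings(max(s$m_tumor)),
         depth_t = mean(s$tumor_alt + s$tumor_ref),
         depth_n = mean(s$normal_alt + s$normal_ref))
  })
  segs[, nsnp := vapply(stats_, `[[`, 0, "nsnp")]
  segs[, m_seg := vapply(stats_, `[[`, 0, "m_seg")]
  segs[, m_med := vapply(stats_, `[[`, 0, "m_med")]
  segs[, m_max := vapply(stats_, `[[`, 0, "m_max")]
  depth_t <- vapply(stats_, `[[`, 0, "depth_t")
  depth_n <- vapply(stats_, `[[`, 0, "depth_n")
  genome_ratio <- sum(depth_t * segs$nsnp) / sum(depth_n * segs$nsnp)
  segs[, ratio := (depth_t / depth_n) / genome_ratio]
  segs <- segs[nsnp > 0L]
  if ("sample_id" %in% names(snps)) {
    segs[, sample_id := snps$sample_id[1L]]
  }
  segs[]
}
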