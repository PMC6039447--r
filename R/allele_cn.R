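# Relative and absolute allele-specific copy numbers and tumor purity.
#
# Relative copy numbers come straight from segment major-allele frequency and
# depth ratio (CNAH = m * ratio, CNAL = (1 - m) * ratio). The SNP-weighted
# distribution of minor-allele relative values anchors the integer grid: its
# lowest peak is copy number 0 and the second peak copy number 1 or 2,
# whichever interpretation leaves relative values closest to integers.
# Purity inverts the expected-major-allele-frequency mixture on allelically
# imbalanced segments, falling back to mutation VAFs in balanced CN 2 regions
# when no imbalance exists. Multi-sample patients re-anchor non-reference
# samples on the highest-purity ("reference") sample, and K-means clustering
# of shared mutation VAFs can re-derive copy numbers where both purity and
# ploidy are extreme.

#' Relative allele-specific copy numbers of segments
#'
#' `CNAH = m * ratio`, `CNAL = (1 - m) * ratio` with `m` the segment major
#' allele frequency and `ratio` the normalized tumor/normal depth ratio.
#'
#' @param segments Segment table from [segment_genome()] (columns `m_seg`,
#'   `ratio`).
#' @return The table with `cnah` and `cnal` columns added.
#' @export
compute_rcn <- function(segments) {
  segments <- data.table::as.data.table(segments)
  if (any(segments$ratio <= 0)) stop("depth ratio must be positive")
  segments[, cnah := m_seg * ratio]
  segments[, cnal := (1 - m_seg) * ratio]
  segments[]
}

#' Infer the integer copy-number grid from minor-allele relative values
#'
#' SNP-weighted kernel density of `cnal`; the lowest peak normally
#' corresponds to copy number 0 (loss of both copies of the minor allele)
#' but can equally be copy number 1 when no LOH exists (e.g. after genome
#' duplication), and the second peak one or two copy states up. All four
#' (anchor, spacing) hypotheses are scored by the SNP-weighted distance of
#' relative values from integers; hypotheses within `residual_tol` of the
#' best are disambiguated by the binomial likelihood of observed mutation
#' VAFs under the implied purity (`alpha = DIS / (DIS + CN0)`), preferring
#' the CN 0 anchor when no mutations are supplied. A unimodal distribution
#' cannot anchor the grid and raises a `cne_grid_error` (the caller falls
#' back to mutation-based purity).
#'
#' @param segments Segment table with `cnah`, `cnal`, `nsnp`.
#' @param mutations Optional mutation table (`chrom`, `pos0`, `alt_reads`,
#'   `depth`, ideally `called`) used to break the anchor ambiguity.
#' @param min_peak_frac Peaks below this fraction of the tallest are ignored.
#' @param min_peak_sep Minimum separation of usable peaks on the relative
#'   copy-number scale; closer maxima are noise lobes of one state (the
#'   smallest real spacing, `DIS = alpha / (alpha ploidy + 2 (1 - alpha))`,
#'   stays above 0.06 for purities above 20% and ploidies up to 8).
#' @param residual_tol Residual slack within which hypotheses count as tied.
#' @return List of class `cne_grid`: `cn0`, `dis`, `interpretation`,
#'   `anchor` (0 or 1), `implied_alpha`, `residual`, `provenance`.
#' @export
infer_grid <- function(segments, mutations = NULL, min_peak_frac = 0.05,
                       min_peak_sep = 0.05, residual_tol = 0.03) {
  segments <- data.table::as.data.table(segments)
  if (nrow(segments) < 2L) {
    stop(.grid_error("fewer than 2 segments; grid not inferable"))
  }
  pk <- density_peaks(segments$cnal, segments$nsnp, min_frac = min_peak_frac,
                      min_sep = min_peak_sep)
  if (nrow(pk) < 2L) {
    stop(.grid_error(
      "minor-allele relative copy numbers are unimodal; grid not inferable"))
  }
  p1 <- pk$x[1L]
  p2 <- pk$x[2L]
  hyp <- data.frame(anchor = c(0L, 0L, 1L, 1L), gap = c(1L, 2L, 1L, 2L))
  hyp$dis <- (p2 - p1) / hyp$gap
  hyp$cn0 <- p1 - hyp$anchor * hyp$dis
  hyp <- hyp[hyp$cn0 > -0.2 * hyp$dis, , drop = FALSE]
  hyp$alpha <- hyp$dis / (hyp$dis + pmax(hyp$cn0, 0))
  hyp$cn0 <- pmax(hyp$cn0, 0)
  hyp <- hyp[hyp$alpha > 0.01 & hyp$alpha <= 1, , drop = FALSE]
  if (nrow(hyp) == 0L) stop(.grid_error("no admissible grid hypothesis"))
  w <- rep(segments$nsnp, 2L)
  hyp$residual <- vapply(seq_len(nrow(hyp)), function(i) {
    x <- c((segments$cnah - hyp$cn0[i]) / hyp$dis[i],
           (segments$cnal - hyp$cn0[i]) / hyp$dis[i])
    sum(abs(x - round(x)) * w) / sum(w)
  }, 0)
  # a half-spaced grid fits any data at least as well; it is only supported
  # when odd copy-number states actually occur on it
  hyp$odd_frac <- vapply(seq_len(nrow(hyp)), function(i) {
    x <- round(c((segments$cnah - hyp$cn0[i]) / hyp$dis[i],
                 (segments$cnal - hyp$cn0[i]) / hyp$dis[i]))
    sum(w[x %% 2 == 1]) / sum(w)
  }, 0)
  supported <- hyp$gap == 1L | hyp$odd_frac >= 0.05
  if (any(supported)) hyp <- hyp[supported, , drop = FALSE]
  # self-consistency: the purity implied by the grid geometry
  # (DIS/(DIS+CN0)) must agree with the purity the major-allele-frequency
  # inversion gives under the hypothesis's own integer calls; mixture
  # artifacts (states merged across BAF-invisible boundaries) fake peaks
  # whose geometry contradicts the formula by a wide margin
  self_ok <- vapply(seq_len(nrow(hyp)), function(i) {
    calls <- absolute_cn(data.table::copy(segments),
                         list(cn0 = hyp$cn0[i], dis = hyp$dis[i]))
    af <- tryCatch(
      suppressWarnings(purity_from_imbalanced(
        calls, alpha_ref = hyp$alpha[i])$alpha),
      error = function(e) NA_real_)
    is.na(af) || abs(af - hyp$alpha[i]) <= 0.2
  }, NA)
  if (!any(self_ok)) {
    stop(.grid_error(paste("no grid hypothesis consistent with the",
                           "imbalanced-segment purity formula")))
  }
  hyp <- hyp[self_ok, , drop = FALSE]
  # with mutation evidence the binomial likelihood arbitrates between all
  # near-admissible hypotheses; without it the residual must decide alone
  tol <- if (!is.null(mutations) && nrow(mutations) > 0L) {
    max(residual_tol, 0.1)
  } else {
    residual_tol
  }
  tied <- hyp$residual <= min(hyp$residual) + tol
  hyp <- hyp[tied, , drop = FALSE]
  if (nrow(hyp) > 1L && !is.null(mutations) && nrow(mutations) > 0L) {
    hyp$loglik <- vapply(seq_len(nrow(hyp)), function(i) {
      .grid_mutation_loglik(segments, mutations,
                            list(cn0 = hyp$cn0[i], dis = hyp$dis[i]),
                            hyp$alpha[i])
    }, 0)
    # a doubled grid with purity alpha/(2 - alpha) reproduces every VAF
    # exactly, so likelihood ties are broken toward the parsimonious
    # (coarser-grid, CN0-anchored) solution; a complex hypothesis must win
    # by a clear margin
    ord <- order(hyp$gap, hyp$anchor, hyp$residual)
    best <- ord[1L]
    for (i in ord[-1L]) {
      if (hyp$loglik[i] > hyp$loglik[best] + 10) best <- i
    }
    # referee against the balanced fallback model (every segment 1:1,
    # purity twice the mutation-VAF peak): when no peak pair represents
    # the real grid, every hypothesis loses to it and the distribution is
    # effectively unimodal for grid purposes
    ll_null <- .null_mutation_loglik(mutations)
    if (!is.na(ll_null) && hyp$loglik[best] < ll_null - 10) {
      stop(.grid_error(paste("mutation VAFs reject every peak-based grid",
                             "hypothesis; falling back to balanced-genome",
                             "purity")))
    }
  } else {
    # default reading: the lowest peak is copy number zero; lower residual wins
    best <- order(hyp$anchor, hyp$residual)[1L]
  }
  h <- hyp[best, ]
  structure(list(cn0 = h$cn0, dis = h$dis,
                 interpretation = sprintf("anchor_cn%d_gap%d", h$anchor,
                                          h$gap),
                 anchor = h$anchor, implied_alpha = min(1, h$alpha),
                 residual = h$residual, provenance = "two-peak"),
            class = "cne_grid")
}

# Log-likelihood of the mutation alt counts under the balanced fallback
# model: every locus diploid 1:1, one mutated allele, purity anchored at
# twice the VAF density peak (expected VAF alpha/2).
.null_mutation_loglik <- function(mutations) {
  muts <- data.table::as.data.table(mutations)
  if ("called" %in% names(muts)) muts <- muts[called == TRUE]
  muts <- muts[is.finite(alt_reads) & is.finite(depth) & depth > 0 &
                 alt_reads > 0]
  if (nrow(muts) < 5L) return(NA_real_)
  vafs <- muts$alt_reads / muts$depth
  alpha <- min(1, 2 * density_mode(vafs))
  if (!is.finite(alpha) || alpha <= 0) return(NA_real_)
  sum(stats::dbinom(muts$alt_reads, muts$depth, alpha / 2, log = TRUE))
}

# Total log-likelihood of observed mutation alt counts given the integer
# copy numbers implied by a grid hypothesis and its implied purity. The
# mutated-allele count is marginalized under a uniform prior (1..CNH) so
# hypotheses offering more candidate multiplicities gain no free fit.
.grid_mutation_loglik <- function(segments, mutations, grid, alpha) {
  segs <- absolute_cn(data.table::copy(segments), grid)
  muts <- data.table::as.data.table(mutations)
  if ("called" %in% names(muts)) muts <- muts[called == TRUE]
  muts <- muts[is.finite(alt_reads) & is.finite(depth) & depth > 0 &
                 alt_reads > 0]
  if (nrow(muts) == 0L) return(0)
  idx <- .overlap_rows(muts, segs)
  ok <- !is.na(idx)
  muts <- muts[ok]
  idx <- idx[ok]
  cnh <- pmax(segs$cnh[idx], 1L)
  ctot <- pmax(segs$cn_total[idx], 1L)
  ll <- vapply(seq_len(nrow(muts)), function(j) {
    n <- seq_len(cnh[j])
    f <- pmin(1 - 1e-9, pmax(1e-9, n * alpha /
                               (alpha * ctot[j] + 2 * (1 - alpha))))
    lp <- stats::dbinom(muts$alt_reads[j], muts$depth[j], f, log = TRUE)
    m <- max(lp)
    m + log(mean(exp(lp - m)))
  }, 0)
  sum(ll)
}

.grid_error <- function(msg) {
  structure(class = c("cne_grid_error", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Absolute allele-specific copy numbers
#'
#' Maps relative values through `round((cn - cn0) / dis)` (round half to
#' even, the R default) and clamps negatives to zero.
#'
#' @param segments Segment table with `cnah`, `cnal`.
#' @param grid A [infer_grid()] result (or any list with `cn0`, `dis`).
#' @return The table with integer `cnh`, `cnl` and `cn_total` added.
#' @export
absolute_cn <- function(segments, grid) {
  segments <- data.table::as.data.table(segments)
  dcna <- function(x) pmax(0L, as.integer(round((x - grid$cn0) / grid$dis)))
  segments[, cnh := dcna(cnah)]
  segments[, cnl := dcna(cnal)]
  # rounding can invert the order when values straddle a midpoint
  swap <- segments$cnl > segments$cnh
  if (any(swap)) {
    tmp <- segments$cnh[swap]
    segments[swap, cnh := cnl]
    segments[swap, cnl := tmp]
  }
  segments[, cn_total := cnh + cnl]
  segments[]
}

#' Tumor purity from allelically imbalanced segments
#'
#' Inverts the expected major allele frequency of a mixture of tumor and
#' normal cells: `alpha = (2 m - 1) / (CNH - 1 + m (2 - CN_total))` per
#' segment with `CNH != CNL`; the sample purity is the SNP-weighted density
#' peak of the per-segment values. When `alpha_ref` (e.g. the grid-implied
#' purity, exact in the noiseless model) is supplied and several peaks
#' exist, the peak nearest the reference is taken — segments that merged
#' states invisible to BAF segmentation otherwise drag the global peak to
#' an inconsistent value.
#'
#' @param segments Segment table with `m_seg`, `cnh`, `cnl`, `cn_total`.
#' @param alpha_ref Optional reference purity for peak selection; also used
#'   to drop segments whose observed `m_seg` is inconsistent (by more than
#'   `m_tol`) with the expected major allele frequency of their called state
#'   — the footprint of segments that merged states invisible to BAF
#'   segmentation.
#' @param m_tol Consistency tolerance on the major allele frequency.
#' @return List: `alpha` (scalar purity), `per_segment` values.
#' @export
purity_from_imbalanced <- function(segments, alpha_ref = NULL,
                                   m_tol = 0.025) {
  segments <- data.table::as.data.table(segments)
  imb <- segments[cnh != cnl]
  if (nrow(imb) == 0L) stop("no allelically imbalanced segments")
  if (!is.null(alpha_ref)) {
    f_pred <- (alpha_ref * imb$cnh + (1 - alpha_ref)) /
      (alpha_ref * imb$cn_total + 2 * (1 - alpha_ref))
    consistent <- abs(imb$m_seg - f_pred) <= m_tol
    if (any(consistent)) imb <- imb[consistent]
  }
  denom <- imb$cnh - 1 + imb$m_seg * (2 - imb$cn_total)
  bad <- abs(denom) < 1e-9
  if (any(bad)) {
    warning(sum(bad), " segment(s) with zero purity denominator skipped",
            call. = FALSE)
  }
  alpha_seg <- (2 * imb$m_seg - 1) / denom
  keep <- !bad & is.finite(alpha_seg) & alpha_seg > 0 & alpha_seg <= 1.2
  if (!any(keep)) stop("no usable imbalanced segments for purity")
  if (sum(keep) == 1L) {
    alpha <- alpha_seg[keep]
  } else {
    pk <- density_peaks(alpha_seg[keep], imb$nsnp[keep], min_frac = 0.05)
    alpha <- if (nrow(pk) == 0L) {
      stats::median(alpha_seg[keep])
    } else if (!is.null(alpha_ref) && nrow(pk) > 1L) {
      pk$x[which.min(abs(pk$x - alpha_ref))]
    } else {
      pk$x[which.max(pk$height)]
    }
  }
  list(alpha = min(1, alpha), per_segment = alpha_seg[keep],
       weights = imb$nsnp[keep])
}

#' Tumor purity from mutation VAFs in balanced copy-number-2 segments
#'
#' Without allelic imbalance the mutation allele frequency in CN 2 balanced
#' regions peaks at `alpha / 2`, so `alpha = 2 * peak`.
#'
#' @param mutations Mutation table for one sample (column `vaf_obs`).
#' @param segments Segment table with integer calls (`cnh`, `cnl`).
#' @param min_mutations Minimum usable mutations (default 5).
#' @return List with `alpha` and the number of mutations used.
#' @export
purity_from_balanced <- function(mutations, segments, min_mutations = 5L) {
  mutations <- data.table::as.data.table(mutations)
  segments <- data.table::as.data.table(segments)
  bal <- segments[cnh == 1L & cnl == 1L]
  if (nrow(bal) == 0L) stop("no balanced copy-number-2 segments")
  idx <- .overlap_rows(mutations, bal)
  vafs <- mutations$vaf_obs[!is.na(idx)]
  vafs <- vafs[is.finite(vafs) & vafs > 0]
  if (length(vafs) < min_mutations) {
    stop("fewer than ", min_mutations,
         " usable mutations in balanced segments; sample cannot be profiled")
  }
  list(alpha = min(1, 2 * density_mode(vafs)), n_used = length(vafs))
}

# Row index of the segment containing each mutation (NA when none).
.overlap_rows <- function(points, segments) {
  out <- rep(NA_integer_, nrow(points))
  for (ch in unique(segments$chrom)) {
    rows <- which(segments$chrom == ch)
    o <- order(segments$start[rows])
    rows <- rows[o]
    sel <- which(points$chrom == ch)
    if (!length(sel)) next
    i <- findInterval(points$pos0[sel], segments$start[rows])
    ok <- i >= 1L & points$pos0[sel] < segments$end[rows][pmax(i, 1L)]
    out[sel[ok]] <- rows[i[ok]]
  }
  out
}

#' Profile one sample: copy numbers, purity, ploidy
#'
#' Orchestrates [compute_rcn()], [infer_grid()], [absolute_cn()] and the two
#' purity estimators (imbalanced-segment inversion preferred; mutation-based
#' fallback when the minor-allele distribution is unimodal, in which case the
#' genome is treated as balanced CN 2).
#'
#' @param segments Segment table from [segment_genome()].
#' @param mutations Optional mutation table for the fallback estimator.
#' @param config A [pipeline_config()].
#' @return List: `segments` (with integer calls), `profile` (purity, ploidy,
#'   purity source, exclusion flag; `wgd` left `NA` for [infer_wgd()]).
#' @export
profile_sample <- function(segments, mutations = NULL,
                           config = pipeline_config()) {
  segments <- compute_rcn(segments)
  if (config$exclude_sex_chroms) {
    segments <- segments[!chrom %in% c("chrX", "chrY", "X", "Y")]
  }
  grid <- tryCatch(infer_grid(segments, mutations),
                   cne_grid_error = function(e) NULL)
  if (!is.null(grid)) {
    segments <- absolute_cn(segments, grid)
    pur <- purity_from_imbalanced(segments, alpha_ref = grid$implied_alpha)
    alpha <- pur$alpha
    source <- "imbalanced_segments"
  } else {
    segments[, `:=`(cnh = 1L, cnl = 1L, cn_total = 2L)]
    if (is.null(mutations)) {
      stop("no allelic imbalance and no mutations; sample cannot be profiled")
    }
    pur <- purity_from_balanced(mutations, segments)
    alpha <- pur$alpha
    source <- "balanced_mutations"
  }
  ploidy <- with(segments, sum(cn_total * nsnp) / sum(nsnp))
  profile <- list(sample_id = segments$sample_id[1L] %||% NA_character_,
                  purity = alpha, ploidy = ploidy,
                  purity_source = source, wgd = NA,
                  excluded = alpha < config$min_purity,
                  grid = if (!is.null(grid)) grid[c("cn0", "dis")] else NULL)
  list(segments = segments[], profile = profile)
}

# ---- multi-sample refinement -------------------------------------------

#' Intersect segmentations across samples
#'
#' Splits every sample's segments on the union of all breakpoints so each
#' (chrom, start, end) interval exists in every sample, carrying that
#' sample's values.
#'
#' @param seg_list Named list of per-sample segment tables.
#' @return Long data.table over the shared interval grid.
#' @export
intersect_segments <- function(seg_list) {
  stopifnot(length(seg_list) >= 1L)
  edges <- data.table::rbindlist(lapply(seg_list, function(s) {
    data.table::as.data.table(s)[, c("chrom", "start", "end")]
  }))
  grid <- edges[, .(edge = sort(unique(c(start, end)))), by = chrom]
  grid <- grid[, .(start = edge[-.N], end = edge[-1L]), by = chrom]
  out <- lapply(names(seg_list), function(nm) {
    s <- data.table::as.data.table(seg_list[[nm]])
    g <- data.table::copy(grid)
    idx <- .overlap_rows(g[, .(chrom, pos0 = start)], s)
    keep <- !is.na(idx)
    g <- g[keep]
    vals <- s[idx[keep]]
    for (col in setdiff(names(s), c("chrom", "start", "end", "sample_id"))) {
      g[, (col) := vals[[col]]]
    }
    if ("nsnp" %in% names(s)) {
      # prorate SNP weight by overlap so sub-intervals are not double-counted
      frac <- (g$end - g$start) / pmax(1, vals$end - vals$start)
      g[, nsnp := pmax(1, round(vals$nsnp * pmin(1, frac)))]
    }
    g[, sample_id := nm]
    g
  })
  data.table::rbindlist(out, fill = TRUE)
}

#' Refine copy numbers and purity of non-reference samples
#'
#' The patient's highest-purity sample is the reference. Non-reference
#' grids are re-anchored on the intervals where the reference calls minor
#' allele copy number 0 and 1 (weighted medians of the non-reference
#' relative values give CN0 and CN1, hence DIS). If after anchoring the
#' total copy number disagrees with the reference on more than half the
#' genome length, grid scalings x2 and x3 (genome doubling / tripling of
#' the non-reference lesion) are tried and the scaling minimizing the
#' distance of relative values from integers is kept. Purity is then
#' re-estimated from the refined integer calls.
#'
#' @param sample_results Named list of [profile_sample()] results (>= 2 for
#'   any refinement to happen).
#' @param config A [pipeline_config()].
#' @return The list with non-reference entries updated (`profile$refined`
#'   records the anchoring; single-sample input is returned unchanged).
#' @export
refine_non_reference <- function(sample_results, config = pipeline_config()) {
  if (length(sample_results) < 2L) return(sample_results)
  purities <- vapply(sample_results, function(r) r$profile$purity, 0)
  ref_name <- names(which.max(purities))
  shared <- intersect_segments(lapply(sample_results, `[[`, "segments"))
  ref <- shared[sample_id == ref_name]
  for (nm in setdiff(names(sample_results), ref_name)) {
    nonref <- shared[sample_id == nm]
    common <- merge(ref[, .(chrom, start, end, ref_cnl = cnl,
                            ref_cn_total = cn_total)],
                    nonref, by = c("chrom", "start", "end"))
    if (nrow(common) == 0L) {
      warning("no overlapping segments for ", nm, "; left unrefined",
              call. = FALSE)
      next
    }
    # anchor on the two lowest reference minor-allele levels with support
    # (copy number 0 and 1 where LOH exists; otherwise e.g. 1 and 2)
    lev <- common[, .(len = sum(pmax(nsnp, 1))), by = ref_cnl][order(ref_cnl)]
    lev <- lev[len >= 40]
    if (nrow(lev) < 2L) {
      warning("reference lacks two distinct minor-allele anchor levels for ",
              nm, "; left unrefined", call. = FALSE)
      next
    }
    L1 <- lev$ref_cnl[1L]
    L2 <- lev$ref_cnl[2L]
    a0 <- common[ref_cnl == L1]
    a1 <- common[ref_cnl == L2]
    lev1 <- weighted_median(a0$cnal, pmax(a0$nsnp, 1))
    lev2 <- weighted_median(a1$cnal, pmax(a1$nsnp, 1))
    dis <- (lev2 - lev1) / (L2 - L1)
    cn0 <- lev1 - L1 * dis
    if (!is.finite(dis) || dis <= 0) {
      warning("degenerate anchor grid for ", nm, "; left unrefined",
              call. = FALSE)
      next
    }
    segs <- sample_results[[nm]]$segments
    segs <- absolute_cn(segs, list(cn0 = cn0, dis = dis))
    scale_used <- 1L
    common2 <- merge(ref[, .(chrom, start, end, ref_cn_total = cn_total)],
                     intersect_segments(list(x = segs))[, -"sample_id"],
                     by = c("chrom", "start", "end"))
    len <- common2$end - common2$start
    disagree <- sum(len[common2$cn_total != common2$ref_cn_total]) / sum(len)
    if (is.finite(disagree) && disagree > 0.5) {
      resid <- vapply(1:3, function(s) {
        x <- c((segs$cnah - cn0) / (dis / s), (segs$cnal - cn0) / (dis / s))
        w <- rep(pmax(segs$nsnp, 1), 2L)
        sum(abs(x - round(x)) * w) / sum(w)
      }, 0)
      scale_used <- which.min(resid)
      if (scale_used > 1L) {
        segs <- absolute_cn(segs, list(cn0 = cn0, dis = dis / scale_used))
      }
    }
    pur <- tryCatch(purity_from_imbalanced(segs), error = function(e) NULL)
    sample_results[[nm]]$segments <- segs
    sample_results[[nm]]$profile$ploidy <-
      with(segs, sum(cn_total * nsnp) / sum(nsnp))
    if (!is.null(pur)) sample_results[[nm]]$profile$purity <- pur$alpha
    sample_results[[nm]]$profile$refined <-
      list(reference = ref_name, cn0 = cn0, dis = dis, scale = scale_used)
  }
  sample_results
}

# ---- mutation-VAF clustering across samples ----------------------------

#' Tune copy numbers by clustering shared mutation VAFs
#'
#' K-means over the VAF matrix of mutations shared by every pair of a
#' patient's samples. The average sum of squared errors E(C) over all
#' sample pairs is reported for every `k`, but — being monotone
#' non-increasing in `k` — it cannot select the cluster count by literal
#' minimization; `k` is chosen by the maximum mean silhouette width across
#' pairs. The optimal pair maximizes the summed inter-centroid distance,
#' ties broken by the minimum average intra-cluster point distance.
#' Cluster centroid VAFs are then mapped to integer mutated-allele counts:
#' the lowest centroid corresponds to one mutated allele, the mean spacing
#' of successive centroids to one allele step.
#'
#' @param vaf_matrix Numeric matrix, mutations x samples (>= 20 rows,
#'   >= 2 columns), shared mutations only.
#' @param k_range Cluster counts tried (default 2:5).
#' @param nstart K-means restarts (default 50).
#' @param seed Integer seed for the stochastic initialization.
#' @return List of class `cne_cluster_state`: `k`, `ec` (per k), `combo`
#'   (chosen sample pair), `centroids`, `multiplicity` (per mutation, from
#'   the chosen pair), `f1`, `spacing`, `effective_states`.
#' @export
cluster_tune <- function(vaf_matrix, k_range = 2:5, nstart = 50L, seed = 1L) {
  vaf_matrix <- as.matrix(vaf_matrix)
  if (nrow(vaf_matrix) < 20L) {
    stop("fewer than 20 shared mutations; clustering skipped")
  }
  if (ncol(vaf_matrix) < 2L) stop("need at least 2 samples")
  combos <- utils::combn(ncol(vaf_matrix), 2L, simplify = FALSE)
  withr::with_seed(seed, {
    fits <- lapply(k_range, function(k) {
      lapply(combos, function(cb) {
        stats::kmeans(vaf_matrix[, cb], centers = k, nstart = nstart)
      })
    })
    ec <- vapply(fits, function(fk) {
      mean(vapply(fk, function(f) f$tot.withinss, 0))
    }, 0)
    sil <- vapply(seq_along(k_range), function(ki) {
      mean(vapply(seq_along(combos), function(ci) {
        f <- fits[[ki]][[ci]]
        s <- cluster::silhouette(f$cluster,
                                 stats::dist(vaf_matrix[, combos[[ci]]]))
        mean(s[, "sil_width"])
      }, 0))
    }, 0)
    k_best <- k_range[which.max(sil)]
    fk <- fits[[which.max(sil)]]
    inter <- vapply(fk, function(f) sum(stats::dist(f$centers)), 0)
    best_ids <- which(inter >= max(inter) - 1e-12)
    if (length(best_ids) > 1L) {
      intra <- vapply(best_ids, function(i) {
        f <- fk[[i]]
        x <- vaf_matrix[, combos[[i]]]
        num <- 0; den <- 0
        for (t in seq_len(k_best)) {
          pts <- x[f$cluster == t, , drop = FALSE]
          if (nrow(pts) >= 2L) {
            num <- num + sum(stats::dist(pts))
            den <- den + choose(nrow(pts), 2L)
          }
        }
        if (den == 0) Inf else num / den
      }, 0)
      best_ids <- best_ids[which.min(intra)]
    }
    chosen <- best_ids[1L]
    fit <- fk[[chosen]]
    cen <- fit$centers
    cen_level <- rowMeans(cen)
    o <- order(cen_level)
    f1 <- cen_level[o][1L]
    spacing <- if (k_best > 1L) mean(diff(cen_level[o])) else NA_real_
    # clusters carving one unimodal cloud are not copy-number states:
    # require centroid spacing to clear the within-cluster spread
    sd_within <- sqrt(fit$tot.withinss / (nrow(vaf_matrix) * 2))
    degenerate <- is.na(spacing) || spacing <= 2 * sd_within
    mult <- if (degenerate) {
      spacing <- NA_real_
      rep(1L, nrow(vaf_matrix))
    } else {
      pmax(1L, 1L + as.integer(round((cen_level[fit$cluster] - f1) / spacing)))
    }
    structure(list(k = k_best, ec = stats::setNames(ec, k_range),
                   silhouette = stats::setNames(sil, k_range),
                   combo = combos[[chosen]], centroids = cen,
                   inter_distance = inter[chosen],
                   multiplicity = mult, f1 = f1, spacing = spacing,
                   effective_states = length(unique(mult))),
              class = "cne_cluster_state")
  })
}

#' Re-derive segment copy numbers from clustered mutation multiplicities
#'
#' Raises a segment's major-allele copy number when the clustering assigns
#' its mutations a higher mutated-allele count than the SNP-based call.
#'
#' @param segments Segment table with integer calls.
#' @param mutations Mutation table for one clustered sample (`chrom`,
#'   `pos0`).
#' @param state A [cluster_tune()] result (order matching `mutations` rows).
#' @return Updated segment table.
#' @export
recn_from_clusters <- function(segments, mutations, state) {
  segments <- data.table::as.data.table(segments)
  idx <- .overlap_rows(data.table::as.data.table(mutations), segments)
  mult <- state$multiplicity
  for (row in unique(idx[!is.na(idx)])) {
    m_seg <- max(mult[which(idx == row)])
    if (m_seg > segments$cnh[row]) {
      segments[row, `:=`(cnh = m_seg, cn_total = m_seg + cnl)]
    }
  }
  segments[]
}
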