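# Whole-genome duplication: detection, relative timing of copy-number events
# and mutations, mutated-allele assignment, and genome-level complexity /
# diversity metrics.

#' Infer whole-genome duplication for a sample
#'
#' Deterministic replacement for a manual call: WGD when the SNP-weighted
#' ploidy is at least `wgd_ploidy_hi`, or at least `wgd_ploidy_lo` with at
#' least `wgd_minor2_frac` of the genome carrying the minor allele at copy
#' number 2 or more. Both features are returned so borderline samples can be
#' overridden.
#'
#' @param segments Segment table with integer calls and `nsnp`.
#' @param config A [pipeline_config()].
#' @return List: `wgd` (logical), `ploidy`, `minor2_fraction`.
#' @export
infer_wgd <- function(segments, config = pipeline_config()) {
  segments <- data.table::as.data.table(segments)
  w <- pmax(segments$nsnp, 1)
  ploidy <- sum(segments$cn_total * w) / sum(w)
  minor2 <- sum(w[segments$cnl >= 2L]) / sum(w)
  wgd <- ploidy >= config$wgd_ploidy_hi ||
    (ploidy >= config$wgd_ploidy_lo && minor2 >= config$wgd_minor2_frac)
  list(wgd = wgd, ploidy = ploidy, minor2_fraction = minor2)
}

#' Minimal copy-number events before and after genome duplication
#'
#' A change before duplication moves the observed allele copy number by two
#' from the unaltered state of two; a change afterwards moves it by one.
#' Solves `2 + 2 a + b = cn` for the minimum total number of events
#' `|a| + |b|`; ties break toward more pre-duplication events.
#'
#' @param allele_cn Non-negative integer allele copy number.
#' @return Integer vector `c(n_pre, n_post)`.
#' @export
time_cn_events <- function(allele_cn) {
  if (allele_cn < 0) stop("allele copy number must be non-negative")
  best <- NULL
  for (a in -4:4) {
    b <- allele_cn - 2L - 2L * a
    cand <- c(pre = abs(a), post = abs(b))
    if (is.null(best) || sum(cand) < sum(best) ||
        (sum(cand) == sum(best) && cand[1] > best[1])) {
      best <- cand
    }
  }
  as.integer(best)
}

#' Fraction of mutations preceding genome duplication
#'
#' In regions with major:minor states 2:2, 2:1 or 2:0 the multiplicity-two
#' mutations (`n2`) predate the duplication. The fraction of mutations
#' preceding it is `m1 = 3 n2 / (n1 - n2)` for 2:1 and `m1 = n2 / (2 n1)`
#' for 2:2 and 2:0 (`n1`: multiplicity-one count). The 2:1 expression can
#' leave `[0, 1]`; the raw value is reported alongside a clamped copy and a
#' flag rather than hidden.
#'
#' @param state Allelic state, one of `"2:2"`, `"2:1"`, `"2:0"`.
#' @param n1,n2 Mutation counts at multiplicity 1 and 2.
#' @return List: `m1_raw`, `m1` (clamped to `[0, 1]`), `clamped`, `state`.
#' @export
time_mutations <- function(state, n1, n2) {
  state <- match.arg(state, c("2:2", "2:1", "2:0"))
  stopifnot(n1 >= 0, n2 >= 0)
  m1 <- if (state == "2:1") {
    if (n1 == n2) stop("m1 undefined for state 2:1 when n1 == n2")
    3 * n2 / (n1 - n2)
  } else {
    if (n1 == 0) stop("m1 undefined for state ", state, " when n1 == 0")
    n2 / (2 * n1)
  }
  clamped <- min(1, max(0, m1))
  list(m1_raw = m1, m1 = clamped, clamped = clamped != m1, state = state)
}

#' Mutated-allele multiplicity and major/minor assignment
#'
#' Chooses the mutated-allele count maximizing the binomial likelihood of
#' the observed variant reads, with expected VAF
#' `n_mut * alpha / (alpha * cn_total + 2 (1 - alpha))`. Counts above the
#' minor-allele copy number can only sit on the major allele; counts at or
#' below it cannot be attributed to either allele and are reported
#' ambiguous, as are fits whose top two likelihoods differ by less than a
#' factor of e. Depths below `min_depth` are uninformative.
#'
#' @param alt_reads,depth Observed variant support.
#' @param cnh,cnl Local allele-specific copy numbers.
#' @param alpha Tumor purity.
#' @param min_depth Sample detection-depth threshold (optional).
#' @return List: `n_mut`, `allele` ("major", "ambiguous", "uninformative"),
#'   `loglik` per candidate.
#' @export
mutation_allele_state <- function(alt_reads, depth, cnh, cnl, alpha,
                                  min_depth = 0L) {
  if (depth < min_depth) {
    return(list(n_mut = NA_integer_, allele = "uninformative",
                loglik = NULL))
  }
  cn_total <- cnh + cnl
  cand <- seq_len(max(cnh, 1L))
  f <- pmin(1 - 1e-9, cand * alpha / (alpha * cn_total + 2 * (1 - alpha)))
  ll <- stats::dbinom(alt_reads, depth, f, log = TRUE)
  n_best <- cand[which.max(ll)]
  close <- sort(ll, decreasing = TRUE)
  near_tie <- length(close) > 1L && (close[1] - close[2]) < 1
  allele <- if (near_tie || n_best <= cnl) "ambiguous" else "major"
  list(n_mut = n_best, allele = allele,
       loglik = stats::setNames(ll, cand))
}

#' Genomic complexity
#'
#' Length-weighted fraction of the genome in an aberrant state: any
#' deviation from 1:1 for diploid samples or 2:2 for genome-duplicated
#' samples (allelically imbalanced states with a balanced total count as
#' aberrant).
#'
#' @param segments Segment table with integer calls.
#' @param wgd Logical whole-genome-duplication flag.
#' @return Fraction in `[0, 1]`.
#' @export
genomic_complexity <- function(segments, wgd) {
  segments <- data.table::as.data.table(segments)
  base <- if (wgd) 2L else 1L
  len <- segments$end - segments$start
  aberrant <- !(segments$cnh == base & segments$cnl == base)
  sum(len[aberrant]) / sum(len)
}

#' Copy-number diversity of a patient
#'
#' Mean, over sample pairs, of the number of copy-number alterations
#' separating the pair: segments are intersected onto a shared grid and each
#' maximal run of consecutive intervals with differing `(CNH, CNL)` counts
#' as one alteration. Intervals shorter than `min_len` (slivers from
#' breakpoint-localization jitter between samples) are ignored.
#'
#' @param seg_list Named list of per-sample segment tables (>= 2 samples).
#' @param min_len Minimum interval length considered (default 500 kb).
#' @return Mean pairwise alteration count (`NA` for a single sample).
#' @export
copy_number_diversity <- function(seg_list, min_len = 5e5) {
  if (length(seg_list) < 2L) return(NA_real_)
  shared <- intersect_segments(seg_list)
  shared <- shared[end - start >= min_len]
  samples <- names(seg_list)
  pairs <- utils::combn(samples, 2L, simplify = FALSE)
  counts <- vapply(pairs, function(p) {
    a <- shared[sample_id == p[1]][order(chrom, start)]
    b <- shared[sample_id == p[2]][order(chrom, start)]
    m <- merge(a[, .(chrom, start, end, cnh_a = cnh, cnl_a = cnl)],
               b[, .(chrom, start, cnh_b = cnh, cnl_b = cnl)],
               by = c("chrom", "start"))[order(chrom, start)]
    total <- 0L
    for (ch in unique(m$chrom)) {
      diff_run <- m[chrom == ch, cnh_a != cnh_b | cnl_a != cnl_b]
      r <- rle(diff_run)
      total <- total + sum(r$values)
    }
    total
  }, 0L)
  mean(counts)
}

#' Time every copy-number event of a duplicated sample
#'
#' Applies [time_cn_events()] to both alleles of every segment and sums the
#' pre- and post-duplication event counts (length-weighted summary is left
#' to the caller; counts are per segment-allele).
#'
#' @param segments Segment table with integer calls.
#' @return List: `per_segment` table with `pre`/`post` per allele, `n_pre`,
#'   `n_post`, `fraction_post`.
#' @export
time_sample_cn_events <- function(segments) {
  segments <- data.table::as.data.table(segments)
  ev <- lapply(seq_len(nrow(segments)), function(i) {
    h <- time_cn_events(segments$cnh[i])
    l <- time_cn_events(segments$cnl[i])
    c(pre = h[1] + l[1], post = h[2] + l[2])
  })
  pre <- vapply(ev, `[[`, 0L, "pre")
  post <- vapply(ev, `[[`, 0L, "post")
  tab <- data.table::data.table(segments[, c("chrom", "start", "end",
                                             "cnh", "cnl")],
                                n_pre = pre, n_post = post)
  n_pre <- sum(pre)
  n_post <- sum(post)
  list(per_segment = tab, n_pre = n_pre, n_post = n_post,
       fraction_post = if (n_pre + n_post > 0) n_post / (n_pre + n_post)
       else NA_real_)
}
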