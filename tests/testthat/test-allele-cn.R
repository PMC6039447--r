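test_that("relative copy numbers follow the m * ratio formulas", {
  segs <- data.table::data.table(
    chrom = "chr1", start = c(0, 1e6, 2e6), end = c(1e6, 2e6, 3e6),
    nsnp = 100L, m_seg = c(0.5, 1.0, 0.6), ratio = c(2, 1, 1.5))
  r <- compute_rcn(segs)
  expect_equal(r$cnah, c(1, 1, 0.9))
  expect_equal(r$cnal, c(1, 0, 0.6))
  expect_error(compute_rcn(data.table::data.table(m_seg = 0.5, ratio = 0)),
               "positive")
})

test_that("grid inference anchors on minor-allele peaks and errors when unimodal", {
  # two minor states {0, 1} at alpha 0.6, diploid-normalized ratios
  alpha <- 0.6
  mk <- function(cnh, cnl, n) {
    ploidy <- 2.5  # genome-wide mixture ploidy used for normalization
    ctot <- cnh + cnl
    denom <- alpha * ploidy + 2 * (1 - alpha)
    f <- (alpha * cnh + (1 - alpha)) / (alpha * ctot + 2 * (1 - alpha))
    ratio <- (alpha * ctot + 2 * (1 - alpha)) / denom
    data.table::data.table(chrom = "chr1", start = 0, end = 1e6,
                           nsnp = n, m_seg = f, ratio = ratio)
  }
  segs <- data.table::rbindlist(list(
    mk(1, 0, 1000), mk(1, 0, 900), mk(2, 0, 300),
    mk(1, 1, 1200), mk(2, 1, 800), mk(1, 1, 700)))
  segs[, start := cumsum(c(0, rep(1e6, .N - 1)))]
  segs[, end := start + 1e6]
  segs <- compute_rcn(segs)
  grid <- infer_grid(segs)
  denom <- alpha * 2.5 + 2 * (1 - alpha)
  expect_equal(grid$cn0, (1 - alpha) / denom, tolerance = 0.05)
  expect_equal(grid$dis, alpha / denom, tolerance = 0.05)
  expect_equal(grid$implied_alpha, alpha, tolerance = 0.05)
  called <- absolute_cn(segs, grid)
  expect_equal(called$cnl, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(called$cnh, c(1L, 1L, 2L, 1L, 2L, 1L))

  # all balanced: unimodal -> grid error (fallback path)
  flat <- data.table::rbindlist(replicate(6, mk(1, 1, 500), simplify = FALSE))
  flat[, start := cumsum(c(0, rep(1e6, .N - 1)))][, end := start + 1e6]
  expect_error(infer_grid(compute_rcn(flat)), class = "cne_grid_error")
})

test_that("absolute copy numbers round half to even and clamp at zero", {
  grid <- list(cn0 = 0.2, dis = 0.4)
  segs <- data.table::data.table(
    chrom = "chr1", start = 0, end = 1e6, nsnp = 10L,
    cnah = c(0.2 + 2 * 0.4, 0.2 + 1.4 * 0.4, 0.2 + 0.5 * 0.4, 0.05),
    cnal = c(0.2, 0.2, 0.2, 0.0))
  out <- absolute_cn(segs, grid)
  expect_equal(out$cnh, c(2L, 1L, 0L, 0L))   # 1.4 -> 1; 0.5 -> 0 (half-even)
  expect_equal(out$cnl, c(0L, 0L, 0L, 0L))   # negatives clamp to 0
})

test_that("purity inversion is exact on the forward model", {
  # alpha -> f_major(alpha) -> alpha for any imbalanced state
  for (alpha in c(0.1, 0.3, 0.5, 0.8, 1)) {
    for (st in list(c(2L, 1L), c(1L, 0L), c(3L, 1L), c(2L, 0L), c(3L, 2L))) {
      cnh <- st[1]; ctot <- sum(st)
      f <- (alpha * cnh + (1 - alpha)) / (alpha * ctot + 2 * (1 - alpha))
      est <- (2 * f - 1) / (cnh - 1 + f * (2 - ctot))
      expect_equal(est, alpha, tolerance = 1e-12)
    }
  }
  # the spec's hand examples
  expect_equal((2 * 2 / 3 - 1) / (2 - 1 + 2 / 3 * (2 - 3)), 1)
  f <- (0.5 * 1 + 0.5) / (0.5 * 1 + 2 * 0.5)        # CNH 1, CN_total 1
  expect_equal((2 * f - 1) / (1 - 1 + f * (2 - 1)), 0.5)
  f <- (0.8 * 3 + 0.2) / (0.8 * 4 + 2 * 0.2)        # CNH 3, CN_total 4
  expect_equal((2 * f - 1) / (3 - 1 + f * (2 - 4)), 0.8, tolerance = 1e-12)

  segs <- make_called_segments(list(c(2L, 1L), c(2L, 0L), c(1L, 1L)),
                               c(6e6, 5e6, 8e6))
  alpha <- 0.7
  segs[, m_seg := (alpha * cnh + (1 - alpha)) /
         (alpha * cn_total + 2 * (1 - alpha))]
  pur <- purity_from_imbalanced(segs)
  expect_equal(pur$alpha, alpha, tolerance = 0.01)
  expect_error(purity_from_imbalanced(segs[cnh == cnl]), "imbalanced")
})

test_that("mutation-based purity fallback and its failure modes", {
  segs <- make_called_segments(list(c(1L, 1L)), 2e7)
  withr::with_seed(8, {
    vafs <- stats::rbinom(200, 120, 0.25) / 120   # clonal at alpha 0.5
    sub <- stats::rbinom(80, 120, 0.10) / 120     # 30% subclonal tail
    muts <- data.table::data.table(
      chrom = "chr1", pos0 = sort(sample.int(2e7, 280)),
      vaf_obs = c(vafs, sub))
  })
  est <- purity_from_balanced(muts, segs)
  expect_equal(est$alpha, 0.5, tolerance = 0.05)
  expect_error(purity_from_balanced(muts[1:3], segs), "fewer than 5")
  expect_error(purity_from_balanced(muts, make_called_segments(
    list(c(2L, 1L)), 2e7)), "balanced")
})

test_that("end-to-end purity and copy-number recovery on synthetic samples", {
  # alpha_true >= 0.2, >= 3 distinct imbalanced states, depth ~100, 20 seeds
  errs <- c(); cn_ok <- c()
  for (s in 1:20) {
    alpha <- withr::with_seed(100 + s, stats::runif(1, 0.25, 0.95))
    spec <- cohort_spec(n_patients = 1, samples_per_patient = 1,
                        purity_range = c(alpha, alpha), wgd_probability = 0,
                        cna_per_chrom = 3, n_chrom = 3,
                        chrom_length_bp = 4e7, n_trunk = 150, n_private = 0)
    truth <- generate_truth(spec, seed = 200 + s)
    pat <- truth$patients[[1]]
    tseg <- pat$segments
    n_states <- nrow(unique(tseg[cnh_true != cnl_true,
                                 .(cnh_true, cnl_true)]))
    if (n_states < 3) next
    reads <- simulate_reads(truth, seed = 300 + s)
    res <- profile_sample(segment_genome(reads$snps),
                          reads$mutations)
    errs <- c(errs, abs(res$profile$purity - alpha))
    shared <- intersect_segments(list(est = res$segments,
                                      truth = data.table::copy(tseg)[
                                        , `:=`(cnh = cnh_true,
                                               cnl = cnl_true)]))
    m <- merge(shared[sample_id == "est", .(chrom, start, end, cnh, cnl)],
               shared[sample_id == "truth",
                      .(chrom, start, cnh_t = cnh, cnl_t = cnl)],
               by = c("chrom", "start"))
    frac <- m[, sum((end - start) * (cnh == cnh_t & cnl == cnl_t)) /
                sum(end - start)]
    cn_ok <- c(cn_ok, frac)
  }
  expect_gte(length(errs), 10)
  expect_true(all(errs <= 0.05))
  expect_gte(mean(cn_ok >= 0.9), 0.9)
})

test_that("depth scale invariance: mean coverage level does not move calls", {
  spec <- cohort_spec(n_patients = 1, samples_per_patient = 1,
                      purity_range = c(0.7, 0.7), wgd_probability = 0,
                      n_chrom = 2, chrom_length_bp = 3e7)
  truth <- generate_truth(spec, seed = 77)
  base <- profile_sample(
    segment_genome(simulate_reads(truth, depth_p = 0.01, seed = 78)$snps),
    simulate_reads(truth, depth_p = 0.01, seed = 78)$mutations)
  deep <- profile_sample(
    segment_genome(simulate_reads(truth, depth_p = 1 / 300, seed = 78)$snps),
    simulate_reads(truth, depth_p = 1 / 300, seed = 78)$mutations)
  expect_equal(deep$profile$purity, base$profile$purity, tolerance = 0.05)
  expect_equal(deep$profile$ploidy, base$profile$ploidy, tolerance = 0.25)
})

test_that("non-reference samples are refined onto the reference grid", {
  spec <- cohort_spec(n_patients = 1, samples_per_patient = 2,
                      purity_range = c(0.3, 0.9), wgd_probability = 0,
                      divergence_rate = 0, cna_per_chrom = 3,
                      n_chrom = 3, chrom_length_bp = 4e7)
  truth <- generate_truth(spec, seed = 55)
  pat <- truth$patients[[1]]
  # force a strong purity contrast
  pat$purity[1:2] <- c(0.9, 0.3)
  truth$patients[[1]] <- pat
  reads <- simulate_reads(truth, seed = 56)
  res <- lapply(pat$sample_ids, function(s) {
    profile_sample(segment_genome(reads$snps[sample_id == s]),
                   reads$mutations[sample_id == s])
  })
  names(res) <- pat$sample_ids
  refined <- refine_non_reference(res)
  expect_identical(refine_non_reference(res[1]), res[1])  # single sample no-op
  shared <- intersect_segments(lapply(refined, `[[`, "segments"))
  a <- shared[sample_id == pat$sample_ids[1]]
  b <- shared[sample_id == pat$sample_ids[2]]
  m <- merge(a[, .(chrom, start, end, cnh, cnl)],
             b[, .(chrom, start, cnh_b = cnh, cnl_b = cnl)],
             by = c("chrom", "start"))
  agree <- m[, sum((end - start) * (cnh == cnh_b & cnl == cnl_b)) /
               sum(end - start)]
  expect_gte(agree, 0.95)
})

test_that("clustering shared-mutation VAFs recovers planted multiplicities", {
  withr::with_seed(5, {
    n <- 120
    alphas <- c(0.4, 0.3)
    ctot <- 4
    mult <- sample(1:2, n, replace = TRUE)
    X <- vapply(alphas, function(a) {
      f <- mult * a / (a * ctot + 2 * (1 - a))
      stats::rbinom(n, 200, f) / 200
    }, numeric(n))
  })
  st <- cluster_tune(X, seed = 9)
  expect_equal(st$k, 2L)
  expect_equal(mean(st$multiplicity == mult), 1)
  lev <- sort(unname(rowMeans(st$centroids)))
  expect_equal(lev[2] / lev[1], 2, tolerance = 0.15)
  expect_true(all(diff(st$ec) <= 1e-9))  # E(C) is monotone in k (reported)

  # all multiplicity 1: single effective state
  withr::with_seed(6, {
    X1 <- vapply(alphas, function(a) {
      stats::rbinom(60, 200, a / (a * 2 + 2 * (1 - a))) / 200
    }, numeric(60))
  })
  st1 <- cluster_tune(X1, seed = 10)
  expect_equal(st1$effective_states, 1L)
  expect_error(cluster_tune(X[1:10, ]), "fewer than 20")

  # stability: chosen sample pair is stable across seeds
  withr::with_seed(7, {
    mult3 <- sample(1:2, 80, replace = TRUE)
    X3 <- cbind(
      stats::rbinom(80, 300, mult3 * 0.10) / 300,
      stats::rbinom(80, 300, mult3 * 0.12) / 300,
      stats::rbinom(80, 300, 0.05 + 0 * mult3) / 300)
  })
  combos <- vapply(1:10, function(s) {
    paste(cluster_tune(X3, seed = s)$combo, collapse = "-")
  }, "")
  expect_gte(max(table(combos)), 9)
})
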