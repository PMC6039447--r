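test_that("detection depth thresholds match the exact binomial oracle", {
  # brute-force tail oracle over a rho grid
  oracle <- function(rho, power = 0.95) {
    p <- rho / (2 * (1 - rho) + 4 * rho)
    for (d in 2:5000) {
      if (sum(stats::dbinom(2:d, d, p)) >= power) return(d)
    }
    NA_integer_
  }
  rhos <- seq(0.2, 1, by = 0.05)
  thr <- vapply(rhos, detection_depth_threshold, 0L)
  expect_equal(thr, vapply(rhos, oracle, 0L))
  expect_true(all(diff(thr) <= 0))          # non-increasing in rho
  expect_equal(detection_depth_threshold(0.20), 56L)
  expect_equal(detection_depth_threshold(1.00), 18L)
  expect_equal(detection_depth_threshold(0.50), 27L)
  expect_error(detection_depth_threshold(0), "rho")
})

test_that("rescue rule needs >1 read and a significant binomial tail", {
  expect_false(rescue_uncalled(1, 10000))      # "over 1" fails at any depth
  expect_false(rescue_uncalled(0, 100))
  expect_true(rescue_uncalled(4, 200))         # tail ~0.019 < 0.05
  expect_false(rescue_uncalled(3, 200))        # tail ~0.080
  # exact tails behind those calls
  expect_lt(stats::pbinom(3, 200, 1 / 200, lower.tail = FALSE), 0.05)
  expect_gt(stats::pbinom(2, 200, 1 / 200, lower.tail = FALSE), 0.05)
})

test_that("trunk/branch/private labels follow presence and excuse rules", {
  samples <- c("S1", "S2", "S3")
  seg_list <- stats::setNames(lapply(samples, function(s) {
    make_called_segments(list(c(1L, 1L), c(1L, 0L)), c(1.5e7, 5e6),
                         sample_id = s)
  }), samples)
  # S3 has a deletion over [1.5e7, 2e7) relative to carriers
  profiles <- stats::setNames(lapply(c(0.8, 0.8, 0.8), function(a) {
    list(purity = a)
  }), samples)
  mk <- function(pos0, alt) {
    data.table::data.table(
      sample_id = samples, chrom = "chr1", pos0 = pos0, ref = "C",
      alt = "T", alt_reads = alt, depth = 150L,
      vaf_obs = alt / 150, called = alt >= 3)
  }
  muts <- data.table::rbindlist(list(
    mk(1000L, c(60L, 55L, 58L)),     # present everywhere -> trunk
    mk(1.6e7, c(60L, 58L, 0L)),      # absent only where CN lost -> trunk
    mk(2000L, c(60L, 0L, 0L)),       # absent, depth fine, no loss -> private
    mk(3000L, c(60L, 62L, 0L))       # absent in one informative sample -> branch
  ))
  seg_list$S3 <- make_called_segments(list(c(1L, 1L), c(0L, 0L)),
                                      c(1.5e7, 5e6), sample_id = "S3")
  out <- classify_heterogeneity(muts, seg_list, profiles)
  lab <- out[, .(label = label[1]), by = pos0][order(pos0)]
  expect_equal(lab$label, c("trunk", "private", "branch", "trunk"))

  # single-sample patient: labels not applicable
  one <- classify_heterogeneity(muts[sample_id == "S1"],
                                seg_list["S1"], profiles["S1"])
  expect_true(all(is.na(one$label)))
})

test_that("label recovery on synthetic patients at depth 150 exceeds 98%", {
  accs <- vapply(1:20, function(s) {
    withr::with_seed(700 + s, {
      samples <- c("A", "B", "C")
      seg_list <- stats::setNames(lapply(samples, function(x) {
        make_called_segments(list(c(1L, 1L)), 2e7, sample_id = x)
      }), samples)
      profiles <- stats::setNames(
        lapply(stats::runif(3, 0.4, 0.9), function(a) list(purity = a)),
        samples)
      n_trunk <- 120; n_branch <- 15; n_private <- 30
      presence <- rbind(
        matrix(TRUE, n_trunk, 3),
        t(replicate(n_branch, sample(c(TRUE, TRUE, FALSE)))),
        t(vapply(seq_len(n_private), function(i) {
          v <- c(FALSE, FALSE, FALSE); v[i %% 3 + 1] <- TRUE; v
        }, logical(3))))
      colnames(presence) <- samples
      truth_lab <- rep(c("trunk", "branch", "private"),
                       c(n_trunk, n_branch, n_private))
      muts <- make_patient_mutations(presence, seg_list, profiles,
                                     depth = 150, seed = 800 + s)
      out <- classify_heterogeneity(muts, seg_list, profiles)
      lab <- out[, .(label = label[1]), by = pos0][order(pos0)]
      mean(lab$label == truth_lab, na.rm = TRUE)
    })
  }, 0)
  expect_gte(mean(accs), 0.98)
})

test_that("rVAF follows the expectation formula", {
  expect_equal(compute_rvaf(0.5, 1, 2, 1), 1)
  expect_equal(compute_rvaf(0.25, 1, 2, 0.5), 1)
  expect_equal(compute_rvaf(0.125, 1, 2, 0.5), 0.5)
  expect_error(compute_rvaf(0.5, 0, 2, 1), "positive")
  expect_error(compute_rvaf(0.5, 1, 2, 0), "positive")
})

test_that("clonality classes partition by the trunk IQR rule", {
  trunk <- c(0.8, 0.9, 1.0, 1.1, 1.2, 0.85, 0.95, 1.05, 1.15, 1.0)
  cl <- classify_clonality(c(0.55, 0.95, 0.2), trunk)
  q <- stats::quantile(trunk, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  lower <- q[1] - 1.5 * (q[3] - q[1])
  expect_equal(cl[2], "clonal")
  expect_equal(cl[3], "subclonal")
  expect_equal(cl[1], if (0.55 < lower) "subclonal" else
    if (0.55 >= 0.5 * q[2]) "clonal" else "unknown")
  # dispersed trunk: negative subclonal bound, below half-median -> unknown
  wide <- rep(c(0.1, 0.4, 1.0, 1.6, 1.9), 2)
  expect_equal(classify_clonality(0.3, wide), "unknown")
  # partition property: every value gets exactly one of the three labels
  vals <- seq(0, 2, by = 0.05)
  expect_true(all(classify_clonality(vals, trunk) %in%
                    c("clonal", "subclonal", "unknown")))
  # too few trunk mutations: everything unknown, with a warning
  expect_warning(small <- classify_clonality(1, trunk[1:5]), "fewer than")
  expect_equal(small, "unknown")
})

test_that("polyclonal seeding evidence and mutational diversity", {
  muts <- data.table::data.table(
    sample_id = rep(c("A", "B"), each = 4),
    chrom = "chr1", pos0 = rep(c(10L, 20L, 30L, 40L), 2),
    ref = "C", alt = "T",
    present = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    label = rep(c("trunk", "trunk", "private", "private"), 2),
    clonality = c("clonal", "clonal", "clonal", NA,
                  "clonal", "subclonal", NA, "subclonal"))
  ev <- evaluate_polyclonal_seeding(muts)
  expect_true(ev$has_clonal_private[["A"]])
  expect_false(ev$has_clonal_private[["B"]])
  expect_equal(nrow(ev$shared_subclonal), 0L)  # subclonal in only one sample

  shared <- data.table::copy(muts)
  shared[pos0 == 20L, clonality := "subclonal"]
  expect_equal(nrow(evaluate_polyclonal_seeding(shared)$shared_subclonal), 1L)

  # diversity: mean branch (incl. private) count per lesion
  expect_equal(mutational_diversity(muts), 1)   # one private present in each
  allt <- data.table::copy(muts)[, label := "trunk"]
  expect_equal(mutational_diversity(allt), 0)
  expect_true(is.na(mutational_diversity(muts[sample_id == "A"])))
  # 4 and 6 private mutations, nothing else -> 5
  m2 <- data.table::data.table(
    sample_id = rep(c("A", "B"), c(4, 6)), chrom = "chr1",
    pos0 = 1:10 * 10L, ref = "C", alt = "T", present = TRUE,
    label = "private", clonality = "clonal")
  expect_equal(mutational_diversity(m2), 5)
})

test_that("monoclonal synthetic patients rarely show shared-subclonal evidence", {
  false_pos <- vapply(1:20, function(s) {
    withr::with_seed(900 + s, {
      samples <- c("A", "B")
      seg_list <- stats::setNames(lapply(samples, function(x) {
        make_called_segments(list(c(1L, 1L)), 2e7, sample_id = x)
      }), samples)
      profiles <- list(A = list(purity = 0.7), B = list(purity = 0.6))
      presence <- cbind(A = rep(TRUE, 80), B = rep(TRUE, 80))
      muts <- make_patient_mutations(presence, seg_list, profiles,
                                     depth = 150, seed = 950 + s)
      out <- classify_heterogeneity(muts, seg_list, profiles)
      out[, rvaf := compute_rvaf(pmax(vaf_obs, 1e-9), 1, 2,
                                 ifelse(sample_id == "A", 0.7, 0.6))]
      for (sm in samples) {
        trunk <- out[sample_id == sm & label == "trunk", rvaf]
        out[sample_id == sm,
            clonality := classify_clonality(rvaf, trunk)]
      }
      ev <- evaluate_polyclonal_seeding(out)
      nrow(ev$shared_subclonal) > 0
    })
  }, NA)
  expect_lte(mean(false_pos), 0.05)
})
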