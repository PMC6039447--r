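test_that("WGD rule responds to ploidy and duplicated minor alleles", {
  cfg <- pipeline_config()
  dup <- make_called_segments(list(c(2L, 2L), c(2L, 2L)), c(3e7, 3e7))
  w <- infer_wgd(dup, cfg)
  expect_true(w$wgd)
  expect_equal(w$ploidy, 4)
  expect_equal(w$minor2_fraction, 1)

  dip <- make_called_segments(list(c(1L, 1L), c(2L, 1L)), c(5e7, 5e6))
  w2 <- infer_wgd(dip, cfg)
  expect_false(w2$wgd)
  expect_lt(w2$ploidy, 2.2)
})

test_that("WGD classification is perfect on clean truths, robust to divergence", {
  # default genome model: ~32% altered fraction, matching the observed
  # complexity of near-diploid tumors
  hits <- c()
  for (s in 1:25) {
    spec <- cohort_spec(n_patients = 1, samples_per_patient = 1,
                        purity_range = c(0.4, 0.9),
                        wgd_probability = 0.4, divergence_rate = 0.2)
    truth <- generate_truth(spec, seed = 400 + s)
    pat <- truth$patients[[1]]
    segs <- data.table::copy(pat$segments)[, `:=`(cnh = cnh_true,
                                                  cnl = cnl_true,
                                                  cn_total = cnh_true +
                                                    cnl_true)]
    segs[, nsnp := pmax(1L, as.integer((end - start) / 3000))]
    hits <- c(hits, infer_wgd(segs)$wgd == pat$wgd)
  }
  expect_equal(mean(hits), 1)   # exact states: classification is clean

  # estimated states end-to-end: the grid anchor is not identifiable for
  # every sample (duplicated genomes with a single minor-allele state,
  # large balanced mixtures), so allow occasional misses
  hits2 <- vapply(1:10, function(s) {
    spec <- cohort_spec(n_patients = 1, samples_per_patient = 1,
                        purity_range = c(0.45, 0.9),
                        wgd_probability = 0.5, divergence_rate = 0.2,
                        n_chrom = 3, chrom_length_bp = 5e7)
    truth <- generate_truth(spec, seed = 500 + s)
    reads <- simulate_reads(truth, seed = 600 + s)
    res <- profile_sample(segment_genome(reads$snps), reads$mutations)
    infer_wgd(res$segments)$wgd == truth$patients[[1]]$wgd
  }, NA)
  expect_gte(mean(hits2), 0.8)
})

test_that("event timing matches the exhaustive enumeration oracle", {
  oracle <- function(cn) {
    best <- NULL
    for (a in -4:4) for (b in -10:10) {
      if (2 + 2 * a + b == cn) {
        cand <- c(abs(a), abs(b))
        if (is.null(best) || sum(cand) < sum(best) ||
            (sum(cand) == sum(best) && cand[1] > best[1])) best <- cand
      }
    }
    best
  }
  for (cn in 0:8) expect_equal(time_cn_events(cn), oracle(cn), info = cn)
  expect_equal(time_cn_events(2L), c(0L, 0L))
  expect_equal(time_cn_events(4L), c(1L, 0L))
  expect_equal(time_cn_events(3L), c(0L, 1L))
  expect_equal(time_cn_events(0L), c(1L, 0L))
  expect_error(time_cn_events(-1), "non-negative")
})

test_that("m1 formulas are applied verbatim with clamping surfaced", {
  expect_equal(time_mutations("2:2", 10, 10)$m1, 0.5)
  expect_equal(time_mutations("2:0", 10, 10)$m1, 0.5)
  expect_equal(time_mutations("2:1", 70, 10)$m1, 0.5)
  path <- time_mutations("2:1", 12, 4)       # 3*4/8 = 1.5: clamp + flag
  expect_equal(path$m1_raw, 1.5)
  expect_equal(path$m1, 1)
  expect_true(path$clamped)
  expect_error(time_mutations("2:1", 5, 5), "undefined")
  expect_error(time_mutations("2:2", 0, 3), "undefined")
})

test_that("timing limits: mutations planted pre/post duplication", {
  # all mutations at multiplicity 2 on 2:2 regions (pre-WGD): m1 -> 1
  pre <- time_mutations("2:2", n1 = 2, n2 = 198)
  expect_gte(pre$m1, 0.99)
  # all at multiplicity 1 (post-WGD): m1 -> 0
  post <- time_mutations("2:2", n1 = 200, n2 = 0)
  expect_equal(post$m1, 0)

  segs <- make_called_segments(list(c(2L, 2L), c(4L, 2L), c(2L, 0L)),
                               c(2e7, 1e7, 5e6))
  tt <- time_sample_cn_events(segs)
  # 2:2 -> (0,0)+(0,0); 4:2 -> (1,0)+(0,0); 2:0 -> (0,0)+(1,0)
  expect_equal(tt$n_pre, 2L)
  expect_equal(tt$n_post, 0L)
})

test_that("mutated-allele assignment maximizes the binomial likelihood", {
  # 2:1 at alpha 1, VAF 2/3: two mutated copies on the major allele
  st <- mutation_allele_state(alt_reads = 100, depth = 150, cnh = 2L,
                              cnl = 1L, alpha = 1)
  expect_equal(st$n_mut, 2L)
  expect_equal(st$allele, "major")
  # VAF 1/3: single copy, side unknowable
  st2 <- mutation_allele_state(alt_reads = 50, depth = 150, cnh = 2L,
                               cnl = 1L, alpha = 1)
  expect_equal(st2$n_mut, 1L)
  expect_equal(st2$allele, "ambiguous")
  # balanced 1:1, VAF 0.5
  st3 <- mutation_allele_state(alt_reads = 75, depth = 150, cnh = 1L,
                               cnl = 1L, alpha = 1)
  expect_equal(st3$n_mut, 1L)
  # below detection threshold: uninformative
  st4 <- mutation_allele_state(alt_reads = 3, depth = 10, cnh = 2L,
                               cnl = 1L, alpha = 1, min_depth = 18L)
  expect_equal(st4$allele, "uninformative")
})

test_that("genomic complexity is a length fraction, invariant to subdivision", {
  dip <- make_called_segments(list(c(1L, 1L), c(2L, 1L), c(1L, 1L)),
                              c(4e7, 3e7, 3e7))
  expect_equal(genomic_complexity(dip, wgd = FALSE), 0.3)
  expect_equal(genomic_complexity(make_called_segments(
    list(c(1L, 1L)), 1e8), FALSE), 0)
  expect_equal(genomic_complexity(make_called_segments(
    list(c(2L, 2L)), 1e8), TRUE), 0)
  # 3:1 under WGD: balanced total four but allelically aberrant
  expect_equal(genomic_complexity(make_called_segments(
    list(c(3L, 1L)), 1e8), TRUE), 1)
  # subdivision invariance
  split <- make_called_segments(list(c(1L, 1L), c(2L, 1L), c(2L, 1L),
                                     c(1L, 1L), c(1L, 1L)),
                                c(4e7, 1.5e7, 1.5e7, 2e7, 1e7))
  expect_equal(genomic_complexity(split, FALSE),
               genomic_complexity(dip, FALSE))
})

test_that("copy-number diversity counts contiguous differing runs per pair", {
  a <- make_called_segments(list(c(1L, 1L), c(2L, 1L), c(1L, 1L)),
                            c(3e7, 2e7, 3e7), sample_id = "A")
  b <- data.table::copy(a)[, sample_id := "B"]
  expect_equal(copy_number_diversity(list(A = a, B = b)), 0)

  b2 <- make_called_segments(list(c(1L, 1L), c(2L, 1L), c(3L, 1L)),
                             c(3e7, 2e7, 3e7), sample_id = "B")
  expect_equal(copy_number_diversity(list(A = a, B = b2)), 1)
  expect_true(is.na(copy_number_diversity(list(A = a))))

  # planted divergence: 5 separated differing blocks -> count 5
  states_a <- list(c(1L, 1L), c(2L, 1L), c(1L, 1L), c(2L, 0L), c(1L, 1L),
                   c(3L, 1L), c(1L, 1L), c(2L, 2L), c(1L, 1L), c(2L, 1L))
  states_b <- list(c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L),
                   c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L))
  lens <- rep(1e7, 10)
  a3 <- make_called_segments(states_a, lens, sample_id = "A")
  b3 <- make_called_segments(states_b, lens, sample_id = "B")
  expect_equal(copy_number_diversity(list(A = a3, B = b3)), 5)
})
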