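# Shared fixture builders. Everything is generated in code; no binary data.

# Minimal well-formed SNP count table (internal form, 0-based pos0).
make_snp_table <- function(n = 100, chrom = "chr1", depth = 60,
                           baf = 0.5, spacing = 3000, seed = 1) {
  withr::with_seed(seed, {
    nd <- rep(depth, n)
    nb <- stats::rbinom(n, nd, 0.5)
    td <- rep(depth, n)
    tb <- stats::rbinom(n, td, baf)
    data.table::data.table(
      chrom = chrom, pos0 = seq(0L, by = as.integer(spacing),
                                length.out = n),
      ref = "A", alt = "G",
      normal_ref = nd - nb, normal_alt = nb,
      tumor_ref = td - tb, tumor_alt = tb,
      normal_depth = nd, tumor_depth = td)
  })
}

# SNP table for a genome of constant-state segments at given purity.
# states: list of c(cnh, cnl); lengths_bp same length; fixed depth.
make_state_genome <- function(states, lengths_bp, alpha, depth = 100,
                              spacing = 2000, chrom = "chr1", seed = 1) {
  withr::with_seed(seed, {
    tabs <- list()
    offset <- 0
    for (i in seq_along(states)) {
      cnh <- states[[i]][1]
      cnl <- states[[i]][2]
      ctot <- cnh + cnl
      n <- floor(lengths_bp[i] / spacing)
      f <- (alpha * cnh + (1 - alpha)) / (alpha * ctot + 2 * (1 - alpha))
      mix <- (alpha * ctot + 2 * (1 - alpha)) / 2
      nd <- rep(depth, n)
      nb <- stats::rbinom(n, nd, 0.5)
      td <- rep(round(depth * mix), n)
      phase <- stats::runif(n) < 0.5
      tb <- stats::rbinom(n, td, ifelse(phase, f, 1 - f))
      tabs[[i]] <- data.table::data.table(
        chrom = chrom,
        pos0 = as.integer(offset + seq(0, by = spacing, length.out = n)),
        ref = "A", alt = "G",
        normal_ref = nd - nb, normal_alt = nb,
        tumor_ref = td - tb, tumor_alt = tb,
        normal_depth = nd, tumor_depth = td)
      offset <- offset + lengths_bp[i]
    }
    data.table::rbindlist(tabs)
  })
}

# Long-format mutation table for a multi-sample patient at fixed depth.
# presence: mutations x samples logical matrix; mult integer vector.
make_patient_mutations <- function(presence, seg_list, profiles,
                                   mult = NULL, depth = 150, seed = 1) {
  withr::with_seed(seed, {
    n <- nrow(presence)
    samples <- colnames(presence)
    if (is.null(mult)) mult <- rep(1L, n)
    chrom <- "chr1"
    pos0 <- sort(sample.int(2e7, n))
    rows <- lapply(samples, function(s) {
      segs <- seg_list[[s]]
      idx <- cnevolve:::.overlap_rows(
        data.table::data.table(chrom = chrom, pos0 = pos0), segs)
      ctot <- segs$cn_total[idx]
      alpha <- profiles[[s]]$purity
      f <- ifelse(presence[, s],
                  mult * alpha / (alpha * ctot + 2 * (1 - alpha)), 0)
      alt <- stats::rbinom(n, depth, pmin(f, 1))
      data.table::data.table(
        sample_id = s, chrom = chrom, pos0 = pos0,
        ref = "C", alt = "T", alt_reads = alt, depth = depth,
        vaf_obs = alt / depth,
        called = alt >= 3L & alt / depth > 0.05)
    })
    data.table::rbindlist(rows)
  })
}

# One-segment-per-state segment table with integer calls already set.
make_called_segments <- function(states, lengths_bp, chrom = "chr1",
                                 sample_id = "S1") {
  starts <- cumsum(c(0, head(lengths_bp, -1)))
  data.table::data.table(
    sample_id = sample_id, chrom = chrom, start = starts,
    end = starts + lengths_bp,
    nsnp = pmax(1L, as.integer(lengths_bp / 2000)),
    cnh = vapply(states, `[`, 0L, 1L),
    cnl = vapply(states, `[`, 0L, 2L))[
      , cn_total := cnh + cnl][]
}
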