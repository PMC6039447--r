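# Synthetic multi-lesion cohorts with known ground truth.
#
# The generator states a world resembling the analyzed cohort: multi-lesion
# patients, exome-like SNP spacing, geometric read depths (p = 0.01, mean
# 100x), binomial allelic counts, a two-level clone tree (trunk / branch /
# private), near-diploid versus genome-duplicated samples, and per-sample
# segment overrides that create inter-lesion copy-number divergence.

# Allele-specific states used for simulated copy-number alterations.
# Near-diploid tumors: single-copy gains/losses and LOH around 1:1.
# Duplicated tumors: mostly post-WGD single-copy events around 2:2,
# including losses to minor allele 1 and 0 (LOH), as observed after
# genome duplication.
.CNA_STATES <- list(c(1L, 0L), c(2L, 0L), c(2L, 1L), c(3L, 1L), c(3L, 2L),
                    c(4L, 2L), c(2L, 2L))
.CNA_STATES_WGD <- list(c(2L, 1L), c(2L, 0L), c(3L, 1L), c(3L, 2L),
                        c(4L, 2L), c(4L, 1L), c(3L, 3L))

#' Specification of a synthetic cohort
#'
#' @param n_patients Number of patients.
#' @param samples_per_patient Lesions sequenced per patient.
#' @param purity_range Tumor purity drawn uniformly from this interval.
#' @param wgd_probability Probability that a patient's tumor underwent
#'   whole-genome duplication (shared by all lesions, as duplications predate
#'   metastatic divergence).
#' @param n_trunk,n_branch,n_private Mutation counts: trunk (all lesions),
#'   branch (a strict subset of >= 2 lesions; only generated when a patient
#'   has >= 3 samples), private (exactly one lesion), per sample.
#' @param cna_per_chrom Expected number of altered segments per chromosome.
#' @param divergence_rate Probability that a non-reference lesion overrides a
#'   given altered segment with a different allele-specific state.
#' @param n_chrom,chrom_length_bp,snp_spacing_bp Genome model: autosome count,
#'   length, and mean spacing of heterozygous SNPs (~3 kb, exome-like).
#' @param signature_mixture Named weights over the synthetic signature catalog
#'   used to draw mutation channels.
#' @param pre_wgd_mutation_fraction For duplicated genomes, the probability
#'   that a trunk mutation predates the duplication (multiplicity 2 on
#'   duplicated segments).
#' @return List of class `cne_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1L,
                        samples_per_patient = 2L,
                        purity_range = c(0.3, 0.9),
                        wgd_probability = 0.4,
                        n_trunk = 200L,
                        n_branch = 10L,
                        n_private = 20L,
                        cna_per_chrom = 2,
                        divergence_rate = 0.15,
                        n_chrom = 4L,
                        chrom_length_bp = 60e6,
                        snp_spacing_bp = 3000,
                        signature_mixture = c(uv = 0.8, aging = 0.1, flat = 0.1),
                        pre_wgd_mutation_fraction = 0.89) {
  stopifnot(n_patients >= 1, samples_per_patient >= 1,
            length(purity_range) == 2L,
            purity_range[1] <= purity_range[2], purity_range[2] <= 1,
            wgd_probability >= 0, wgd_probability <= 1)
  if (purity_range[1] < 0.01) stop("purities below 0.01 are degenerate")
  spec <- as.list(environment())
  class(spec) <- "cne_cohort_spec"
  spec
}

#' Generate cohort ground truth
#'
#' Deterministic given `seed`. Produces the genome model, per-patient clone
#' tree (depth <= 2: trunk, branch, private), per-sample purity and segment
#' states, and per-mutation clone assignment, multiplicity and trinucleotide
#' channel.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List of class `cne_cohort_truth`.
#' @export
generate_truth <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cne_cohort_spec"))
  withr::with_seed(seed, .generate_truth(spec))
}

.generate_truth <- function(spec) {
  chroms <- paste0("chr", seq_len(spec$n_chrom))
  snps <- data.table::rbindlist(lapply(chroms, function(ch) {
    n <- floor(spec$chrom_length_bp / spec$snp_spacing_bp)
    data.table::data.table(
      chrom = ch,
      pos0 = sort(sample.int(spec$chrom_length_bp, n)) - 1L)
  }))
  genome <- list(chroms = chroms,
                 chrom_length_bp = spec$chrom_length_bp,
                 snps = snps)
  catalog <- synthetic_signature_catalog()
  patients <- lapply(seq_len(spec$n_patients), function(i) {
    .generate_patient(spec, genome, catalog,
                      patient_id = sprintf("P%02d", i))
  })
  names(patients) <- vapply(patients, `[[`, "", "patient_id")
  structure(list(spec = spec, genome = genome, patients = patients),
            class = "cne_cohort_truth")
}

.generate_patient <- function(spec, genome, catalog, patient_id) {
  n_s <- spec$samples_per_patient
  sample_ids <- sprintf("%s_S%d", patient_id, seq_len(n_s))
  purity <- stats::runif(n_s, spec$purity_range[1], spec$purity_range[2])
  wgd <- stats::runif(1) < spec$wgd_probability
  base_state <- if (wgd) c(2L, 2L) else c(1L, 1L)

  # Trunk segmentation shared by all lesions; breakpoints on 1 Mb lattice,
  # altered segments at least 4 Mb so they are detectable at bin scale.
  segs <- data.table::rbindlist(lapply(genome$chroms, function(ch) {
    L <- genome$chrom_length_bp
    n_cna <- stats::rpois(1, spec$cna_per_chrom)
    bounds <- 0
    while (n_cna > 0 && max(bounds) < L - 8e6) {
      gap <- sample(4:12, 1) * 1e6
      start <- max(bounds) + gap
      len <- sample(4:15, 1) * 1e6
      if (start + len > L) break
      bounds <- c(bounds, start, start + len)
      n_cna <- n_cna - 1
    }
    bounds <- sort(unique(c(bounds, L)))
    dt <- data.table::data.table(chrom = ch,
                                 start = bounds[-length(bounds)],
                                 end = bounds[-1])
    altered <- seq_len(nrow(dt)) %% 2 == 0  # every second interval is a CNA
    pool <- if (wgd) .CNA_STATES_WGD else .CNA_STATES
    st <- lapply(seq_len(nrow(dt)), function(j) {
      if (altered[j]) pool[[sample.int(length(pool), 1)]] else base_state
    })
    dt[, cnh_true := vapply(st, `[`, 0L, 1L)]
    dt[, cnl_true := vapply(st, `[`, 0L, 2L)]
    dt[, altered := altered]
    dt
  }))
  if (wgd && !any(segs$cnl_true >= 2L)) {
    segs[which.max(end - start), `:=`(cnh_true = 2L, cnl_true = 2L)]
  }

  # Per-sample divergence: non-reference lesions override altered segments.
  per_sample <- data.table::rbindlist(lapply(seq_len(n_s), function(s) {
    d <- data.table::copy(segs)
    d[, sample_id := sample_ids[s]]
    if (s > 1L && spec$divergence_rate > 0) {
      pool <- if (wgd) .CNA_STATES_WGD else .CNA_STATES
      hit <- d$altered & stats::runif(nrow(d)) < spec$divergence_rate
      for (j in which(hit)) {
        st <- pool[[sample.int(length(pool), 1)]]
        d[j, `:=`(cnh_true = st[1], cnl_true = st[2])]
      }
    }
    d
  }))
  per_sample[, altered := NULL]

  n_mut <- spec$n_trunk + ifelse(n_s >= 3, spec$n_branch, 0L) +
    spec$n_private * n_s
  muts <- .draw_mutations(n_mut, genome, catalog, spec$signature_mixture)
  clone <- c(rep("trunk", spec$n_trunk),
             rep("branch", ifelse(n_s >= 3, spec$n_branch, 0L)),
             rep("private", spec$n_private * n_s))
  muts[, clone := clone]
  carriers <- lapply(seq_len(nrow(muts)), function(j) {
    switch(muts$clone[j],
           trunk = sample_ids,
           branch = sort(sample(sample_ids, sample(2:(n_s - 1), 1))),
           private = sample_ids[(j - spec$n_trunk -
                                   ifelse(n_s >= 3, spec$n_branch, 0L) - 1L) %%
                                  n_s + 1L])
  })
  muts[, carriers := vapply(carriers, paste, "", collapse = ",")]

  # Multiplicity: trunk mutations on duplicated genomes predate the WGD with
  # probability pre_wgd_mutation_fraction (multiplicity 2); everything else
  # sits on one copy. Capped by the local major-allele copy number later.
  muts[, mult_true := 1L]
  if (wgd) {
    pre <- muts$clone == "trunk" &
      stats::runif(nrow(muts)) < spec$pre_wgd_mutation_fraction
    muts[pre, mult_true := 2L]
  }
  list(patient_id = patient_id, sample_ids = sample_ids,
       purity = stats::setNames(purity, sample_ids), wgd = wgd,
       segments = per_sample, mutations = muts)
}

.draw_mutations <- function(n, genome, catalog, mixture) {
  mixture <- mixture / sum(mixture)
  sig <- sample(names(mixture), n, replace = TRUE, prob = mixture)
  # observed channel rates are the process signature modulated by how often
  # each trinucleotide occurs in the captured exome (the analysis side
  # undoes exactly this modulation)
  tri <- load_exome_trinuc()
  ctx <- vapply(rownames(catalog), function(chn) {
    paste0(substr(chn, 1, 1), substr(chn, 3, 3), substr(chn, 7, 7))
  }, "")
  avail <- tri[ctx] / mean(tri)
  channel <- vapply(sig, function(s) {
    p <- catalog[, s] * avail
    sample(rownames(catalog), 1, prob = p / sum(p))
  }, "")
  parsed <- parse_channel96(channel)
  chrom <- sample(genome$chroms, n, replace = TRUE)
  pos0 <- sample.int(genome$chrom_length_bp, n, replace = TRUE) - 1L
  data.table::data.table(chrom = chrom, pos0 = pos0,
                         ref = parsed$ref, alt = parsed$alt,
                         context = parsed$context, channel96 = channel,
                         signature = sig)[order(chrom, pos0)]
}

# Look up the true allele-specific state of a locus for one sample.
.truth_state_at <- function(segments, sample, chrom, pos0) {
  hit <- segments[segments$sample_id == sample & segments$chrom == chrom &
                    segments$start <= pos0 & segments$end > pos0, ]
  if (nrow(hit) == 0L) stop("locus outside simulated genome")
  c(cnh = hit$cnh_true[1], cnl = hit$cnl_true[1])
}

#' Simulate read counts for a synthetic cohort
#'
#' Total depth of every SNP and mutation is geometric on \{1, 2, ...\} with
#' parameter `depth_p` (mean `1/depth_p`), scaled by the local copy-number
#' mixture so the tumor/normal depth ratio carries copy-number signal.
#' Allelic counts are binomial `B(N, f)` where `f` is the expected major
#' allele frequency (SNPs, random phase) or the expected mutation VAF, both
#' computed from purity and the true allele-specific copy numbers via the
#' same mixture formulas the analysis inverts.
#'
#' @param truth A [generate_truth()] result.
#' @param depth_p Geometric depth parameter (default 0.01).
#' @param seed Integer seed; identical seed and truth give identical output.
#' @return List with `snps` and `mutations` long data.tables.
#' @export
simulate_reads <- function(truth, depth_p = 0.01, seed = 1L) {
  stopifnot(inherits(truth, "cne_cohort_truth"))
  withr::with_seed(seed, .simulate_reads(truth, depth_p))
}

.simulate_reads <- function(truth, depth_p) {
  snp_tabs <- list()
  mut_tabs <- list()
  for (pat in truth$patients) {
    for (s in pat$sample_ids) {
      alpha <- pat$purity[[s]]
      segs <- pat$segments[sample_id == s]
      snp <- data.table::copy(truth$genome$snps)
      idx <- .locate_in_segments(snp$chrom, snp$pos0, segs)
      cnh <- segs$cnh_true[idx]
      cnl <- segs$cnl_true[idx]
      ctot <- cnh + cnl
      f_major <- (alpha * cnh + (1 - alpha)) / (alpha * ctot + 2 * (1 - alpha))
      mix <- (alpha * ctot + 2 * (1 - alpha)) / 2
      n <- nrow(snp)
      normal_depth <- rdepth_geom(n, depth_p)
      normal_b <- stats::rbinom(n, normal_depth, 0.5)
      tumor_depth <- rdepth_geom(n, pmin(1, depth_p / mix))
      phase <- stats::runif(n) < 0.5  # which observed allele is the major one
      f_b <- ifelse(phase, f_major, 1 - f_major)
      tumor_b <- stats::rbinom(n, tumor_depth, f_b)
      snp_tabs[[length(snp_tabs) + 1L]] <- data.table::data.table(
        sample_id = s, chrom = snp$chrom, pos0 = snp$pos0,
        ref = "A", alt = "G",
        normal_ref = normal_depth - normal_b, normal_alt = normal_b,
        tumor_ref = tumor_depth - tumor_b, tumor_alt = tumor_b,
        normal_depth = normal_depth, tumor_depth = tumor_depth)

      mu <- data.table::copy(pat$mutations)
      midx <- .locate_in_segments(mu$chrom, mu$pos0, segs)
      mcnh <- segs$cnh_true[midx]
      mctot <- mcnh + segs$cnl_true[midx]
      present <- vapply(strsplit(mu$carriers, ","), function(cc) s %in% cc,
                        NA)
      n_mut <- pmin(mu$mult_true, pmax(mcnh, 1L)) * present
      f_mut <- (alpha * n_mut) / (alpha * mctot + 2 * (1 - alpha))
      mmix <- (alpha * mctot + 2 * (1 - alpha)) / 2
      depth <- rdepth_geom(nrow(mu), pmin(1, depth_p / mmix))
      alt_reads <- stats::rbinom(nrow(mu), depth, f_mut)
      mut_tabs[[length(mut_tabs) + 1L]] <- data.table::data.table(
        patient_id = pat$patient_id, sample_id = s,
        chrom = mu$chrom, pos0 = mu$pos0, ref = mu$ref, alt = mu$alt,
        context = mu$context, alt_reads = alt_reads, depth = depth,
        vaf_obs = alt_reads / depth,
        called = alt_reads >= 3L & alt_reads / depth > 0.05,
        clone_true = mu$clone, mult_true = n_mut, present_true = present)
    }
  }
  list(snps = data.table::rbindlist(snp_tabs),
       mutations = data.table::rbindlist(mut_tabs))
}

# Vectorized interval lookup: index of the segment containing each position.
.locate_in_segments <- function(chrom, pos0, segs) {
  out <- integer(length(pos0))
  for (ch in unique(segs$chrom)) {
    rows <- which(segs$chrom == ch)
    sel <- chrom == ch
    out[sel] <- rows[findInterval(pos0[sel], segs$start[rows])]
  }
  out
}
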