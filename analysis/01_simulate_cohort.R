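#!/usr/bin/env Rscript
# Simulate a desk-scale multi-lesion cohort with known ground truth.
# Writes per-sample SNP-count and mutation tables plus truth.json under
# results/cohort/ for the downstream analysis scripts.

suppressPackageStartupMessages(library(cnevolve))
suppressPackageStartupMessages(library(data.table))

seed <- 42L
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config(random_seed = seed)

# the stated world: multi-lesion patients, ~40% genome-duplicated, purities
# spanning the inclusion range, UV-dominated trunk mutation spectra
spec <- cohort_spec(n_patients = 4, samples_per_patient = 3,
                    purity_range = c(0.3, 0.9), wgd_probability = 0.4,
                    n_trunk = 200, n_branch = 12, n_private = 20)
truth <- generate_truth(spec, seed = seed)
reads <- simulate_reads(truth, seed = seed + 1L)

for (s in unique(reads$snps$sample_id)) {
  write_snp_counts(reads$snps[sample_id == s],
                   file.path(out_dir, paste0(s, "_snps.tsv")), cfg)
}
write_mutation_table(reads$mutations,
                     file.path(out_dir, "mutations.tsv"), cfg)

truth_json <- lapply(truth$patients, function(p) {
  list(patient_id = p$patient_id, wgd = p$wgd,
       purity = as.list(p$purity),
       segments = p$segments, mutations = p$mutations)
})
write_profiles_json(truth_json, file.path(out_dir, "truth.json"), cfg)

cat(sprintf("Simulated %d patients x %d lesions (%d SNPs, %d mutation rows).\n",
            spec$n_patients, spec$samples_per_patient,
            nrow(truth$genome$snps), nrow(reads$mutations)))
cat(sprintf("WGD patients: %s\n",
            paste(names(which(vapply(truth$patients, `[[`, NA, "wgd"))),
                  collapse = ", ")))
cat("Inputs written under", out_dir, "\n")
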