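#!/usr/bin/env Rscript
# Reduced-replicate run of the simulation machinery that calibrates the
# segmentation cutoffs: the equal-BAF empirical-p calibration and the
# purity x copy-number false-positive/negative grid. Full-scale versions
# run in scripts/acceptance.R.

suppressPackageStartupMessages(library(cnevolve))
suppressPackageStartupMessages(library(data.table))

cfg <- pipeline_config(random_seed = 42L)
out_dir <- "results/calibration"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cat("Equal-BAF simulation (reduced: 60 datasets/BAF, step 0.02) ...\n")
calib <- simulate_equal_baf(baf_grid = seq(0, 1, by = 0.02),
                            n_datasets = 60L, seed = 42L)
cutoff <- calibration_cutoff(calib, target_p = 0.05)
me <- calibration_max_error(calib)
cat(sprintf("  cutoff at pooled p = 0.05: %.3f\n", cutoff))
cat(sprintf("  max adjacent-segment difference: %.4f (mean at BAF 0.5: %.4f)\n",
            me$max_delta, me$mean_per_baf[which.min(abs(calib$baf_grid - 0.5))]))

cat("FPR/FNR grid (reduced: purity step 5%, 150 segments/cell) ...\n")
fdr <- estimate_fpr_fnr(purities = seq(0.05, 1, by = 0.05), total_cn = 1:8,
                        n_segments = 150L, seed = 43L)
cat(sprintf("  global FPR %.2f%%, global FNR %.2f%%\n",
            100 * fdr$global_fpr, 100 * fdr$global_fnr))
hi <- fdr$grid[purity > 0.2]
cat(sprintf("  purity > 20%%: max FPR %.2f%%, max FNR %.2f%%\n",
            100 * max(hi$fpr, na.rm = TRUE), 100 * max(hi$fnr, na.rm = TRUE)))
cat("  (per-cell maxima at this replication are Monte-Carlo dominated;\n",
    "  scripts/acceptance.R re-runs the restricted grid at 1500 segments/cell)\n")

fwrite(fdr$grid, file.path(out_dir, "fpr_fnr_grid.tsv"), sep = "\t")
write_profiles_json(list(cutoff_p05 = cutoff, max_error = me$max_delta,
                         global_fpr = fdr$global_fpr,
                         global_fnr = fdr$global_fnr),
                    file.path(out_dir, "calibration.json"), cfg)
cat("Calibration outputs written under", out_dir, "\n")
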