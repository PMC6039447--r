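#!/usr/bin/env Rscript
# Mutation-type spectra (with the C>T split by 5' pyrimidine/purine),
# signature decomposition of trunk versus branch mutations, and the
# deletion-length profile.

suppressPackageStartupMessages(library(cnevolve))
suppressPackageStartupMessages(library(data.table))

cfg <- pipeline_config(random_seed = 42L)
muts <- read_mutation_table("results/heterogeneity/mutations_annotated.tsv")
out_dir <- "results/spectra"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

catalog <- load_signature_catalog()
trinuc <- load_exome_trinuc()

one_per_locus <- muts[present == TRUE,
                      .(label = label[1], ref = ref[1], alt = alt[1],
                        context = context[1]),
                      by = .(chrom, pos0)]
fit_group <- function(rows, name) {
  cl <- classify_mutation(rows$ref, rows$alt, rows$context)
  sv <- spectrum_vector(cl)
  fit <- tryCatch(
    fit_signatures(sv, catalog, exome_trinuc = trinuc,
                   min_n = cfg$signature_min_mutations,
                   report_threshold = cfg$signature_report_threshold),
    error = function(e) NULL)
  if (is.null(fit)) {
    yc <- sv$counts7[["YC>T"]] / max(1, sv$n)
    cat(sprintf("%s: n = %d below threshold; YC>T fraction %.2f (manual check)\n",
                name, sv$n, yc))
    return(NULL)
  }
  cat(sprintf("%s (n = %d): %s\n", name, sv$n,
              paste(sprintf("%s %.0f%%", names(fit$weights[fit$weights > 0]),
                            100 * fit$weights[fit$weights > 0]),
                    collapse = ", ")))
  data.table(group = name, signature = names(fit$weights),
             weight = round(fit$weights, 4), n = sv$n)
}
weights <- rbindlist(Filter(Negate(is.null), list(
  fit_group(one_per_locus[label == "trunk"], "trunk"),
  fit_group(one_per_locus[label %in% c("branch", "private")], "branch"))))
fwrite(weights, file.path(out_dir, "signature_weights.tsv"), sep = "\t")

# block substitutions and deletion lengths on the raw calls of one sample
s1 <- muts[sample_id == unique(muts$sample_id)[1] & present == TRUE]
blocks <- merge_block_substitutions(s1)
cat(sprintf("Sample %s: %d calls -> %d events after block merging (%d blocks)\n",
            s1$sample_id[1], nrow(s1), nrow(blocks),
            sum(blocks$block_size > 1)))
dls <- deletion_length_spectrum(s1)
cat(sprintf("Deletions: %d (length-2 fraction %s)\n", dls$n_deletions,
            ifelse(is.na(dls$fraction_length2), "NA",
                   sprintf("%.2f", dls$fraction_length2))))
cat("Signature weights written under", out_dir, "\n")
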