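Package: cnevolve
Title: Allele-Specific Copy Number, Purity and Clonal Evolution from Multi-Lesion Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for genomic evolution of multi-metastasis tumors from
    whole-exome sequencing. Segments each tumor genome by shifts in B-allele frequency
    of heterozygous SNPs, derives relative and absolute allele-specific copy numbers and
    tumor purity (with cross-sample refinement for multi-lesion patients), infers and
    times whole-genome duplication, classifies mutations as trunk, branch or private
    with detectability-aware rules, computes relative VAF based clonality and
    polyclonal-seeding evidence, fits mutational-signature contributions, and includes
    the simulation machinery that calibrates the segmentation cutoffs and estimates
    their false positive and negative rates. A synthetic-cohort generator with known
    ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    cluster
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
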