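---
title: "Models and methods behind cnevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cnevolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cnevolve reconstructs the genomic evolution of multi-lesion tumors from
whole-exome sequencing: allele-specific copy numbers and tumor purity from
heterozygous-SNP allele counts, whole-genome duplication (WGD) and its
relative timing, trunk/branch/private mutation structure, relative-VAF
clonality, and mutational-signature shifts. This vignette states the models,
the tunable constants, the numerical choices made where the method left
genuine freedom, and the limitations a user should know before trusting a
green test.

## The measurement model

For a lesion with tumor cell fraction $\alpha$ and a genomic segment with
major/minor allele copy numbers $(\mathrm{CNH}, \mathrm{CNL})$, total
$\mathrm{CN_t} = \mathrm{CNH} + \mathrm{CNL}$, the expected major allele
frequency of heterozygous SNPs and the expected VAF of a somatic mutation on
$n_\mathrm{mut}$ alleles are

$$f_\mathrm{major} = \frac{\alpha\,\mathrm{CNH} + (1-\alpha)}
   {\alpha\,\mathrm{CN_t} + 2(1-\alpha)}, \qquad
  f_\mathrm{mut} = \frac{\alpha\, n_\mathrm{mut}}
   {\alpha\,\mathrm{CN_t} + 2(1-\alpha)}.$$

Read depth is modeled as geometric on $\{1, 2, \dots\}$ with $p = 0.01$
(mean 100x; the heavy low-depth tail of exome capture matters throughout),
scaled by the local copy-number mixture; allelic counts are binomial. The
synthetic-cohort generator (`generate_truth()`, `simulate_reads()`) draws
from exactly this model, so every downstream stage is testable against known
truth without patient data.

## Segmentation

Each chromosome is scanned with 4 Mb bins sliding by 1 Mb; bins with fewer
than 40 heterozygous SNPs merge into their nearest neighbor. A bin is
balanced ($b_i = 0.5$) when a two-sided variance-ratio test (level 0.05 —
the method names no test, so an explicit configurable rule is used) finds no
difference between the spreads of tumor and normal per-SNP major allele
frequencies; otherwise $b_i$ is the tumor median. Adjacent bins differing by
more than 0.015 open a candidate region; a run of consecutive exceedances is
collapsed to the pairs at *local maxima* of the difference. (Collapsing to
the single global maximum, the simpler rule, provably loses one of two true
boundaries lying less than two bin widths apart; refinement discards the
spurious extra candidates this produces.)

Refinement scans prefix/remainder splits of the ±4 Mb flank at 3-SNP window
granularity. Two deliberate choices differ from the most literal reading of
the procedure:

* **Read-pooled contrast.** The split statistic is the difference of
  *read-weighted* mean major allele frequencies. A plain per-SNP mean is
  dominated by depth-1 and depth-2 SNPs (per-SNP standard deviation ≈ 0.11
  under the geometric model), which makes a 0.018 cutoff meaningless for
  small windows; pooling reads restores the intended noise scale.
* **Maximal standardized contrast, not first exceedance.** Among qualifying
  splits (contrast > 0.018, at least 40 SNPs per side — the floor of the
  cutoff calibration), the split maximizing
  $|\bar m_1 - \bar m_2|\sqrt{n_1 n_2 / n}$ is taken. For a noiseless step
  this statistic peaks exactly at the step; a first-exceedance rule fires
  several windows early whenever the step sits mid-flank and misplaces
  breakpoints by megabases.

Because one flank can contain two true boundaries and only the strongest
survives, every assembled segment is re-scanned with the same statistic
until no further split qualifies (bounded recursion). Refined breakpoints
closer than one bin step are duplicate detections and merge to the stronger.

**Limitation.** Segmentation is BAF-only (coverage-only segmentation is out
of scope), so transitions between allelically balanced states (1:1 ↔ 2:2,
2:2 ↔ 3:3) are invisible. Segments silently merging such regions carry
intermediate depth ratios; several safeguards below exist precisely to keep
these mixtures from corrupting purity.

## Copy-number grid, purity, ploidy

Relative copy numbers are $\mathrm{CNAH} = m\cdot\mathrm{ratio}$ and
$\mathrm{CNAL} = (1-m)\cdot\mathrm{ratio}$, with the depth ratio normalized
to SNP-weighted genome mean 1. The segment major allele frequency $m$ is
estimated by method of moments on *unfolded* per-SNP B-allele ratios
($\mathbb E[(b-\tfrac12)^2]$ and $\mathbb E[b(1-b)]$ jointly identify
$(f-\tfrac12)^2$ free of folding bias): the folded median is biased by
roughly +0.03 at balanced states under geometric depths, enough to compress
the copy-number grid spacing and break purity recovery. The folded median is
still reported (`m_med`).

The SNP-weighted density of CNAL values (Silverman bandwidth; peaks below 5%
of the maximum or closer than 0.05 — beneath the smallest physically
possible state spacing at purities above 20% — are discarded) anchors the
integer grid. The lowest peak is *normally* copy number 0, but in duplicated
genomes without LOH it is copy number 1, and the second peak may be one or
two states up. All four (anchor, spacing) hypotheses are therefore scored:

1. integer-closeness residual of all relative values (loose filter);
2. half-spaced grids must actually place ≥ 5% of the genome at odd copy
   numbers (a finer grid otherwise fits anything);
3. hypotheses whose geometric purity $\alpha = \mathrm{DIS}/(\mathrm{DIS} +
   \mathrm{CN0})$ contradicts the purity obtained by inverting
   $f_\mathrm{major}$ under their own integer calls (by > 0.2) are rejected;
4. the remaining tie is broken by the binomial likelihood of observed
   mutation VAFs, marginalized over the mutated-allele count (so larger
   candidate menus gain no free fit), with a parsimony margin of 10 log
   units — a doubled grid with purity $\alpha/(2-\alpha)$ reproduces every
   VAF *exactly*, so complexity must win by clear evidence, never by noise;
5. finally, the winning hypothesis must beat the balanced fallback model
   (every locus 1:1, purity twice the VAF density peak). If it cannot, the
   distribution is effectively unimodal for grid purposes and the method's
   own fallback — mutation-based purity in balanced copy-number-2 genomes —
   takes over.

Purity is then the SNP-weighted density peak of per-segment inversions
$\alpha = (2m-1)/(\mathrm{CNH}-1+m(2-\mathrm{CN_t}))$ over imbalanced
segments, preferring the peak nearest the grid-implied value and dropping
segments whose $m$ is inconsistent with their called state (the footprint of
balanced-mixture merging). Ploidy is the SNP-weighted mean total copy
number.

**Known failure mode.** A duplicated genome whose minor allele sits at one
single level (no LOH, no divergence) gives a unimodal CNAL distribution;
purity then comes from the balanced fallback, which under WGD is biased by
multiplicity-2 mutations. This is exactly the situation the mutation-VAF
clustering (`cluster_tune()`) exists for, mirroring its use on the one
cohort patient with low purity and high ploidy.

## Multi-sample refinement and mutation clustering

Within a patient, the highest-purity sample is the reference. Non-reference
grids are re-anchored on the two lowest reference minor-allele levels with
support (copy numbers 0 and 1 where LOH exists; otherwise 1 and 2). If the
re-anchored total copy numbers disagree with the reference on more than half
the genome length, grid scalings ×2 and ×3 (genome doubling/tripling of that
lesion) are tried and the scaling minimizing the integer residual kept.

`cluster_tune()` clusters shared-mutation VAFs over all sample pairs with
K-means (k-means++ style restarts, fixed seed, 50 starts). The average
within-cluster sum of squared errors E(C) is computed and reported for every
k, but it is monotone non-increasing in k, so literal minimization always
returns the largest k; k is instead chosen by maximum mean silhouette width.
The optimal pair maximizes summed inter-centroid distance (ties: minimum
mean intra-cluster point distance). Centroid levels map to mutated-allele
counts — lowest level ↦ one allele, mean successive spacing ↦ one allele
step — unless the spacing fails to clear twice the within-cluster spread, in
which case the sample has a single effective multiplicity state.

## Cutoff calibration and error rates

`simulate_equal_baf()` regenerates the calibration behind the 0.015/0.018
cutoffs: for each theoretical BAF on a 0.01 grid, 1000 (reducible) datasets
of 40 segments with SNP counts uniform on [40, 1200], geometric depths and
binomial counts; the empirical p of a cutoff is
$\#(\Delta \ge \mathrm{cutoff}) / (39 \cdot \#\mathrm{datasets})$ per BAF,
pooled by averaging over the grid. The segment statistic is the plain mean
of per-SNP B-allele ratios — the only reading under which the pooled p
crosses 0.05 at 0.015 (read-pooling gives a crossing near 0.005). Random
error grows toward BAF 0.5, as expected from the binomial variance.

Two published claims cannot hold simultaneously under this simulation: if 5%
of adjacent-segment differences exceed 0.015, the *maximum* difference over
~4 million draws is far above 0.018 (≈ 0.08–0.17 depending on replication).
The per-BAF *mean* absolute difference does stay below 0.018 everywhere
(≈ 0.006 at BAF 0.5), which is the only summary consistent with the
published bound; `calibration_max_error()` reports both, and the acceptance
suite asserts the literal maximum and is expected to fail it.

`estimate_fpr_fnr()` scores the 0.018 cutoff on a purity (1–100%) × total
copy number (1–8) grid with uniformly drawn major/minor splits per segment:
same-state adjacent pairs falsely split give the FPR, different-state pairs
missed give the FNR. Under this stated design the global averages come out
near 3% — the per-segment-mean noise scale makes different-state pairs
essentially always detectable above ~10% purity — versus published global
averages of 9.88%/8.44%; the shape claims (rates fall with purity, both
stay below 10% above 20% purity, rapid growth below) all reproduce. The
gap is reported honestly rather than closed by moving the simulation away
from its stated design.

## Heterogeneity, clonality, spectra

Detection power, rescue, trunk/branch/private rules, rVAF and the clonality
bands follow the stated formulas exactly; the only formalization choice is
that "detecting the mutation" means at least two supporting reads, the
single reading that reproduces both published depth thresholds (56 at
$\rho = 0.2$, 18 at $\rho = 1$) by exact binomial tails and matches the
rescue rule's "over 1" support requirement. Quantiles are linear
interpolation (type 7); trunk rVAF distributions are per sample; at least 10
trunk mutations are required for a stable IQR. The CN-loss excuse for an
absent mutation is: total copy number at the locus strictly below the
minimum among carrier samples.

Substitution classes use the pyrimidine-strand convention with C>T split by
the 5' neighbor (YC>T vs RC>T). Signature fitting is plain non-negative
least squares (Lawson–Hanson, implemented here; no NNLS solver ships with
the environment) of the context-corrected spectrum against a restricted
catalog, refusing fewer than 10 mutations and suppressing contributions
under 5%. The packaged catalog and exome trinucleotide table are
*synthetic*, clearly labelled stand-ins with the qualitative structure of
the five processes relevant to melanoma (UV dipyrimidine C>T, aging CpG C>T,
flat, alkylating, T>G-at-TpT); users substitute a real reference catalog via
`load_signature_catalog(path)`. All tests use the synthetic catalog, so a
green signature test establishes correct *decomposition machinery*, not
agreement with any published reference vectors.

## What the generator does and does not emulate

Emulated: exome-like SNP spacing (~3 kb), geometric depths, binomial counts,
copy-number-scaled coverage, two-level clone trees (trunk/branch/private),
near-diploid versus duplicated genomes (duplication shared by all lesions of
a patient), post-WGD single-copy losses including LOH, per-lesion segment
overrides (inter-lesion copy-number divergence — a construction for testing;
no such model is stated anywhere), multiplicity-2 trunk mutations predating
WGD (default fraction 0.89, the published median fraction of mutations
preceding duplication), and signature-mixture mutation channels modulated by
exome trinucleotide availability.

Not emulated: sequencing error in SNP counts beyond binomial sampling,
indels (deletion-length machinery is exercised on constructed fixtures),
subclonal copy numbers, kataegis/clustered mutations, and the cohort's
specific complexity levels. Recovery tests are run in worlds satisfying the
method's visibility assumption (allelically imbalanced alterations); a green
recovery test therefore does not certify behavior on balanced-state-only
genomes, which the text above flags as the method's blind spot.

## Defaults worth knowing

| Constant | Default | Meaning |
|---|---|---|
| `bin_size_bp` / `step_size_bp` | 4 Mb / 1 Mb | sliding-bin geometry |
| `min_snps_per_bin` | 40 | bin merge floor; also the minimum side of a refinement split |
| `candidate_cutoff` | 0.015 | adjacent-bin BAF difference (empirical p = 0.05) |
| `refine_cutoff` | 0.018 | split confirmation contrast |
| `min_purity` | 0.20 | sample exclusion threshold |
| `detection_probability` | 0.95 | power behind the per-sample depth threshold |
| `rescue_error_rate` | 1/200 | binomial error rate for rescuing uncalled mutations |
| `signature_min_mutations` | 10 | refusal threshold for signature fitting |
| `signature_report_threshold` | 0.05 | minimum reported contribution |
| het-SNP filter | normal VAF in [0.2, 0.8], depth ≥ 8 | unstated upstream; explicit choice |
| WGD rule | ploidy ≥ 3.0, or ≥ 2.6 with minor-CN≥2 fraction ≥ 0.25 | deterministic replacement for a manual call |

Internally every interval is 0-based half-open and every point 0-based; all
files on disk are 1-based (VCF/SEG convention). Sex chromosomes are excluded
from purity/ploidy/WGD estimation by default, since the formulas assume a
diploid normal baseline.
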