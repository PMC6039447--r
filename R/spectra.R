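# Mutation-type classification, block substitutions, signature fitting and
# deletion-length spectra.
#
# Substitutions are normalized to the pyrimidine strand. Beyond the usual
# six classes and 96 trinucleotide channels, a seven-class scheme splits
# C>T by the 5' neighbor: downstream of a pyrimidine (YC>T, the
# UV-dimer-prone context) versus a purine (RC>T).

CLASS6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' 96-channel order
#' @return Character vector of the 96 trinucleotide channels
#'   (`"A[C>A]A"`, ...), grouped by substitution class.
#' @export
channels96 <- function() {
  unlist(lapply(CLASS6, function(cl) {
    ref <- substr(cl, 1, 1)
    as.vector(t(outer(BASES, BASES, function(p5, p3) {
      paste0(p5, "[", cl, "]", p3)
    })))
  }))
}

.revcomp <- function(s) {
  chartr("ACGT", "TGCA", vapply(strsplit(s, ""), function(x) {
    paste(rev(x), collapse = "")
  }, ""))
}

#' Parse 96-channel labels into ref / alt / context
#' @param channel Labels like `"T[C>T]G"`.
#' @return data.frame with `ref`, `alt`, `context` (reference trinucleotide).
#' @export
parse_channel96 <- function(channel) {
  p5 <- substr(channel, 1, 1)
  ref <- substr(channel, 3, 3)
  alt <- substr(channel, 5, 5)
  p3 <- substr(channel, 7, 7)
  data.frame(ref = ref, alt = alt, context = paste0(p5, ref, p3))
}

#' Classify a substitution into 6-class, 7-class and 96-channel schemes
#'
#' Purine-reference mutations are reverse-complemented to the pyrimidine
#' strand. C>T transitions split into YC>T when the (strand-normalized) 5'
#' neighbor is a pyrimidine and RC>T otherwise. An ambiguous base in the
#' context leaves the 96-channel undefined but still assigns the 6-class.
#'
#' @param ref,alt Single reference / alternate bases.
#' @param context Reference trinucleotide centered on the mutated base.
#' @return data.frame with `class6`, `class7`, `channel96` (vectorized).
#' @export
classify_mutation <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  flip <- ref %in% c("A", "G")
  ref_n <- ifelse(flip, chartr("ACGT", "TGCA", ref), ref)
  alt_n <- ifelse(flip, chartr("ACGT", "TGCA", alt), alt)
  ctx_n <- ifelse(flip, .revcomp(context), context)
  class6 <- paste0(ref_n, ">", alt_n)
  class6[!class6 %in% CLASS6] <- NA_character_
  p5 <- substr(ctx_n, 1, 1)
  p3 <- substr(ctx_n, 3, 3)
  class7 <- class6
  is_ct <- !is.na(class6) & class6 == "C>T"
  class7[is_ct] <- ifelse(p5[is_ct] %in% c("C", "T"), "YC>T", "RC>T")
  channel <- paste0(p5, "[", class6, "]", p3)
  bad_ctx <- !p5 %in% BASES | !p3 %in% BASES |
    substr(ctx_n, 2, 2) != ref_n
  channel[bad_ctx | is.na(class6)] <- NA_character_
  data.frame(class6 = class6, class7 = class7, channel96 = channel)
}

#' Build a spectrum vector from classified mutations
#'
#' @param classified A [classify_mutation()] result (or data.frame with the
#'   same columns).
#' @return List of class `cne_spectrum`: `counts6`, `counts7`, `counts96`
#'   (named vectors), `n` total mutations.
#' @export
spectrum_vector <- function(classified) {
  counts6 <- table(factor(classified$class6, levels = CLASS6))
  class7_levels <- c("C>A", "C>G", "YC>T", "RC>T", "T>A", "T>C", "T>G")
  counts7 <- table(factor(classified$class7, levels = class7_levels))
  counts96 <- table(factor(classified$channel96, levels = channels96()))
  structure(list(counts6 = c(unclass(counts6)),
                 counts7 = c(unclass(counts7)),
                 counts96 = c(unclass(counts96)),
                 n = nrow(classified)),
            class = "cne_spectrum")
}

#' Merge block substitutions
#'
#' Somatic SNVs at consecutive positions whose VAFs both lie within 0.05 of
#' the pair's mean VAF are one mutational event; merging is transitive along
#' runs of consecutive positions.
#'
#' @param mutations Table with `chrom`, `pos0`, `ref`, `alt`, `vaf_obs`
#'   (single sample, sorted or not).
#' @param tol Absolute VAF deviation allowed (default 0.05, inclusive).
#' @return Table with merged rows: `ref`/`alt` concatenated, `vaf_obs`
#'   averaged, `block_size` column added.
#' @export
merge_block_substitutions <- function(mutations, tol = 0.05) {
  mutations <- data.table::as.data.table(mutations)[order(chrom, pos0)]
  n <- nrow(mutations)
  if (n == 0L) {
    mutations[, block_size := integer(0)]
    return(mutations[])
  }
  adjacent <- c(FALSE, diff(mutations$pos0) == 1L &
                  mutations$chrom[-1L] == mutations$chrom[-n])
  pair_mean <- c(NA, (mutations$vaf_obs[-1L] + mutations$vaf_obs[-n]) / 2)
  close <- adjacent &
    abs(mutations$vaf_obs - pair_mean) <= tol &
    abs(c(NA, mutations$vaf_obs[-n]) - pair_mean) <= tol
  close[is.na(close)] <- FALSE
  block <- cumsum(!close)
  mutations[, .(pos0 = pos0[1L], ref = paste(ref, collapse = ""),
                alt = paste(alt, collapse = ""),
                vaf_obs = mean(vaf_obs), block_size = .N),
            by = .(chrom, block)][, block := NULL][]
}

#' Load a signature catalog from a TSV fixture
#'
#' Expected schema: column `channel` (96 labels) plus one probability column
#' per signature; each signature column sums to 1.
#'
#' @param path TSV path; defaults to the packaged synthetic catalog.
#' @return Matrix 96 x n_signatures, rownames the channels.
#' @export
load_signature_catalog <- function(path = system.file(
  "extdata", "synthetic_signatures.tsv", package = "cnevolve")) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -"channel"])
  rownames(m) <- dt$channel
  m <- m[channels96(), , drop = FALSE]
  if (any(m < 0) || any(abs(colSums(m) - 1) > 1e-6)) {
    stop("signature columns must be non-negative and sum to 1")
  }
  m
}

#' Load exome trinucleotide frequencies
#' @param path TSV with columns `trinucleotide`, `frequency` (pyrimidine-
#'   centered, 32 rows); defaults to the packaged synthetic table.
#' @return Named numeric vector summing to 1.
#' @export
load_exome_trinuc <- function(path = system.file(
  "extdata", "synthetic_exome_trinuc.tsv", package = "cnevolve")) {
  dt <- data.table::fread(path, sep = "\t")
  stats::setNames(dt$frequency / sum(dt$frequency), dt$trinucleotide)
}

#' In-memory synthetic signature catalog
#'
#' Five synthetic stand-ins for processes described in melanoma: `aging`
#' (C>T at NpCpG), `flat` (near-uniform), `uv` (C>T at dipyrimidines,
#' YC>T-dominated), `alkylating` (C>T-rich across contexts) and `seventeen`
#' (T>G at NpTpT). They reproduce the qualitative structure of the
#' reference processes, not their exact published vectors.
#'
#' @return Matrix 96 x 5, columns the signature names.
#' @export
synthetic_signature_catalog <- function() {
  ch <- channels96()
  p5 <- substr(ch, 1, 1)
  cls <- substr(ch, 3, 5)
  p3 <- substr(ch, 7, 7)
  w <- function(x) x / sum(x)
  aging <- w(ifelse(cls == "C>T" & p3 == "G", 1, 0.01))
  flat <- w(rep(1, 96))
  uv <- w(ifelse(cls == "C>T" & p5 %in% c("C", "T"), 1,
                 ifelse(cls == "C>T", 0.15, 0.005)))
  alkyl <- w(ifelse(cls == "C>T", 0.6, 0.02))
  seventeen <- w(ifelse(cls == "T>G" & p5 != "G" & p3 == "T", 1, 0.01))
  m <- cbind(aging = aging, flat = flat, uv = uv, alkylating = alkyl,
             seventeen = seventeen)
  rownames(m) <- ch
  m
}

#' Fit signature contributions by non-negative least squares
#'
#' The observed 96-channel spectrum is corrected for the trinucleotide
#' composition of the exome (counts divided by the relative context
#' frequency), normalized, and decomposed over the catalog with
#' [nnls_fit()]. Weights are reported as fractions of the fitted mass;
#' contributions below `report_threshold` are zeroed and the remainder
#' renormalized. Fitting is refused below `min_n` mutations (manual
#' inspection of UV-type YC>T mutations is the fallback there).
#'
#' @param spectrum A [spectrum_vector()] result or named 96-vector of
#'   counts.
#' @param catalog Signature matrix (96 x k), as from
#'   [load_signature_catalog()].
#' @param exome_trinuc Named trinucleotide frequency vector (optional; no
#'   correction when `NULL`).
#' @param min_n Minimum mutation count (default 10).
#' @param report_threshold Minimum reported contribution (default 0.05).
#' @return List: `weights` (reported, sums to 1), `raw_weights`,
#'   `residual`, `n`.
#' @export
fit_signatures <- function(spectrum, catalog,
                           exome_trinuc = NULL,
                           min_n = 10L, report_threshold = 0.05) {
  counts <- if (inherits(spectrum, "cne_spectrum")) spectrum$counts96
  else spectrum
  counts <- counts[rownames(catalog)]
  n <- sum(counts, na.rm = TRUE)
  if (n < min_n) {
    stop("only ", n, " mutations (< ", min_n, "); signature fitting ",
         "refused - inspect UV-type (YC>T) mutations manually instead")
  }
  counts[is.na(counts)] <- 0
  if (!is.null(exome_trinuc)) {
    ctx <- vapply(rownames(catalog), function(chn) {
      paste0(substr(chn, 1, 1), substr(chn, 3, 3), substr(chn, 7, 7))
    }, "")
    rel <- exome_trinuc[ctx] / mean(exome_trinuc)
    counts <- counts / pmax(rel, 1e-9)
  }
  b <- counts / sum(counts)
  fit <- nnls_fit(catalog, b)
  raw <- stats::setNames(fit$x, colnames(catalog))
  if (sum(raw) <= 0) stop("degenerate fit: all weights zero")
  prop <- raw / sum(raw)
  prop[prop < report_threshold] <- 0
  prop <- prop / sum(prop)
  list(weights = prop, raw_weights = raw, residual = fit$residual, n = n)
}

#' Deletion-length spectrum
#'
#' Tabulates deletion lengths (`nchar(ref) - nchar(alt)` where positive);
#' insertions are tabulated separately. SNVs are ignored.
#'
#' @param indels Table with `ref`, `alt` character columns.
#' @return List: `deletion_lengths` (table), `insertion_lengths` (table),
#'   `fraction_length2` (share of deletions of length 2), `n_deletions`,
#'   `n_insertions`.
#' @export
deletion_length_spectrum <- function(indels) {
  indels <- data.table::as.data.table(indels)
  dl <- nchar(indels$ref) - nchar(indels$alt)
  del <- dl[dl > 0]
  ins <- -dl[dl < 0]
  list(deletion_lengths = table(del), insertion_lengths = table(ins),
       fraction_length2 = if (length(del)) mean(del == 2) else NA_real_,
       n_deletions = length(del), n_insertions = length(ins))
}
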