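# Cancer cell fraction, multiplicity, purity-corrected VAF and
# mutation-versus-gain ordering.
#
# The core relation ties the variant-allele fraction (VAF) at a locus to the
# fraction of cancer cells bearing the variant (CCF), the sample purity p,
# the local total copy number at the locus and the fraction of cancer cells
# carrying the copy-number event:
#
#   CCF = VAF * (2 + (ploidy_CNV - 2) * CCF_CNV) / purity
#
# which assumes one variant copy per mutated cancer cell. The multiplicity
# enumeration below relaxes that assumption for gained loci.

#' Absolute copy number from a log2 segment mean
#'
#' Under a diploid baseline, `abs_cn = 2 * 2^seg_mean`. Rounding to the
#' nearest integer (the default) gives multiplicity enumeration an integer
#' ceiling; set `round = FALSE` to keep fractional copy numbers.
#'
#' @param seg_mean log2 copy-ratio segment mean (vectorized).
#' @param round round to the nearest integer copy number (default `TRUE`).
#' @return Non-negative total copy number at the locus.
#' @export
abs_cn_from_segmean <- function(seg_mean, round = TRUE) {
  stopifnot(all(is.finite(seg_mean)))
  cn <- 2 * 2^seg_mean
  if (round) cn <- round(cn)
  cn
}

#' Cancer cell fraction of a single-nucleotide variant
#'
#' Literal single-variant-copy form: `vaf * (2 + (ploidy_cnv - 2) * ccf_cnv)
#' / purity`, unclipped. Use [apply_ccf_heuristics()] for the
#' multiplicity-aware, clipped estimate.
#'
#' @param vaf variant-allele fraction in `[0, 1]`.
#' @param purity tumor purity in `(0, 1]`.
#' @param ploidy_cnv total copy number at the locus (>= 0).
#' @param ccf_cnv fraction of cancer cells bearing the copy-number event
#'   (default 1, i.e. a clonal CNV).
#' @return Raw CCF (may exceed 1 for multi-copy variants).
#' @export
compute_ccf <- function(vaf, purity, ploidy_cnv, ccf_cnv = 1) {
  if (any(purity <= 0)) stop("purity must be > 0")
  vaf * (2 + (ploidy_cnv - 2) * ccf_cnv) / purity
}

#' Multiplicity-aware CCF with correction heuristics
#'
#' The continuous multiplicity `m_c = vaf * (purity * local_cn +
#' 2 * (1 - purity)) / purity` is the product of the true CCF and the true
#' integer multiplicity. The heuristic assigns the nearest integer
#' multiplicity `m = clamp(round(m_c), 1, max(1, round(local_cn)))` and
#' returns `ccf = m_c / m` clipped to `[0, 1]`. Among integer candidates this
#' picks the one whose implied CCF is closest to `[0, 1]`, resolving
#' ambiguity toward the smaller (more clonal) multiplicity, and — unlike a
#' hard distance-to-interval rule — it is continuous in the observed VAF, so
#' read noise around a clonal heterozygous variant cannot flip the call to a
#' half-CCF double-copy reading. A locus with `local_cn = 0` but `vaf > 0`
#' is inconsistent and yields `NA`.
#'
#' @param vaf,purity,local_cn vectors (recycled to a common length).
#' @return A tibble with columns `ccf`, `multiplicity` (the selected integer),
#'   and `inconsistent`.
#' @export
apply_ccf_heuristics <- function(vaf, purity, local_cn) {
  n <- max(length(vaf), length(purity), length(local_cn))
  vaf <- rep_len(vaf, n); purity <- rep_len(purity, n)
  local_cn <- rep_len(local_cn, n)
  if (any(purity <= 0)) stop("purity must be > 0")
  inconsistent <- local_cn <= 0 & vaf > 0
  m_cont <- vaf * (purity * local_cn + 2 * (1 - purity)) / purity
  m_max <- pmax(1, round(local_cn))
  mult <- pmin(pmax(round(m_cont), 1), m_max)
  ccf <- pmin(pmax(m_cont / mult, 0), 1)
  zero_locus <- local_cn <= 0 & vaf <= 0
  ccf[zero_locus] <- 0
  mult[zero_locus] <- 0
  ccf[inconsistent] <- NA_real_
  mult[inconsistent] <- NA_real_
  tibble::tibble(ccf = ccf, multiplicity = as.integer(mult),
                 inconsistent = inconsistent)
}

#' Clonality classification
#'
#' A mutation is clonal when its CCF strictly exceeds the threshold
#' (default 0.95). `NA` CCFs yield `NA`.
#'
#' @param ccf CCF in `[0, 1]` (vectorized).
#' @param threshold clonality threshold (default 0.95).
#' @return Logical vector.
#' @export
classify_clonality <- function(ccf, threshold = 0.95) {
  ccf > threshold
}

#' Purity-corrected VAF (cVAF)
#'
#' VAF corrected for purity but not local ploidy: `min(vaf / purity, 1)`.
#' At full purity it is the identity. A cVAF above 0.5 requires more than one
#' variant copy per cancer cell, which is the signature used by
#' [infer_gain_order()].
#'
#' @param vaf variant-allele fraction in `[0, 1]`.
#' @param purity tumor purity in `(0, 1]`.
#' @return cVAF in `[0, 1]`.
#' @export
corrected_vaf <- function(vaf, purity) {
  if (any(purity <= 0)) stop("purity must be > 0")
  pmin(vaf / purity, 1)
}

#' Phylogenetic order of mutation versus copy gain
#'
#' The VAF exceeds 0.5 (after purity correction) only when the mutation
#' precedes a copy gain that preferentially amplifies the variant allele.
#' Returns `"MUTATION_BEFORE_GAIN_VARIANT_ALLELE"` when `cvaf > 0.5` and the
#' locus is gained (`local_cn > 2`), else `"INDETERMINATE"`.
#'
#' @param cvaf purity-corrected VAF in `[0, 1]` (vectorized).
#' @param local_cn total copy number at the locus.
#' @return Character vector of order calls.
#' @export
infer_gain_order <- function(cvaf, local_cn) {
  ifelse(cvaf > 0.5 & local_cn > 2,
         "MUTATION_BEFORE_GAIN_VARIANT_ALLELE", "INDETERMINATE")
}

#' Continuous variant multiplicity
#'
#' Average variant copies per cancer cell, assuming the variant is clonal:
#' `m = vaf * (purity * local_cn + 2 * (1 - purity)) / purity`, not rounded.
#'
#' @param vaf variant-allele fraction in `[0, 1]`.
#' @param purity tumor purity in `(0, 1]`.
#' @param local_cn total copy number at the locus.
#' @return Continuous multiplicity (>= 0).
#' @export
mutation_multiplicity <- function(vaf, purity, local_cn) {
  if (any(purity <= 0)) stop("purity must be > 0")
  vaf * (purity * local_cn + 2 * (1 - purity)) / purity
}

#' Per-sample CCF table
#'
#' Runs the full per-mutation chain on a [assemble_tumor_sample()] object:
#' local copy number from the assigned segment (diploid default when
#' unassigned), multiplicity-aware CCF, clonality call, cVAF, continuous
#' multiplicity and the mutation-versus-gain order call.
#'
#' @param tumor a `tumor_sample` object.
#' @param clonal_threshold CCF threshold for clonality (default 0.95).
#' @param round_cn round absolute copy numbers to integers (default `TRUE`).
#' @return A tibble with one row per mutation: `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `alt_count`, `ref_count`, `vaf`, `purity`,
#'   `local_cn`, `multiplicity` (continuous), `mult_assigned` (integer used
#'   for the CCF), `ccf`, `clonal`, `cvaf`, `order_call`, `assigned`,
#'   `inconsistent`.
#' @export
compute_ccf_table <- function(tumor, clonal_threshold = 0.95, round_cn = TRUE) {
  stopifnot(inherits(tumor, "tumor_sample"))
  muts <- tumor$mutations
  p <- tumor$purity
  local_cn <- ifelse(muts$assigned,
                     abs_cn_from_segmean(ifelse(is.na(muts$seg_mean), 0, muts$seg_mean),
                                         round = round_cn),
                     2)
  heur <- apply_ccf_heuristics(muts$vaf, p, local_cn)
  cvaf <- corrected_vaf(muts$vaf, p)
  tibble::tibble(
    sample_id = muts$sample_id, chrom = muts$chrom, pos = muts$pos,
    ref = muts$ref, alt = muts$alt, gene = muts$gene,
    alt_count = muts$alt_count, ref_count = muts$ref_count,
    vaf = muts$vaf, purity = p, local_cn = local_cn,
    multiplicity = mutation_multiplicity(muts$vaf, p, local_cn),
    mult_assigned = heur$multiplicity,
    ccf = heur$ccf,
    clonal = classify_clonality(heur$ccf, clonal_threshold),
    cvaf = cvaf,
    order_call = infer_gain_order(cvaf, local_cn),
    assigned = muts$assigned,
    inconsistent = heur$inconsistent
  )
}

#' Write a CCF table
#'
#' @param ccf_table tibble from [compute_ccf_table()].
#' @param path output path.
#' @export
write_ccf_table <- function(ccf_table, path) {
  readr::write_tsv(ccf_table, path, progress = FALSE)
  invisible(path)
}

#' Read a CCF table written by [write_ccf_table()]
#'
#' @param path path to the TSV.
#' @return A tibble.
#' @export
read_ccf_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
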