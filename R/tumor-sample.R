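# A tumor_sample joins one sample's mutations, copy-number segments and
# purity; it is the unit of pipeline input.

#' Assemble a tumor sample from mutations, segments and purity
#'
#' Annotates each mutation with the copy-number segment that contains it
#' (1-based, closed intervals on both sides). When several segments of the
#' same sample and chromosome contain a mutation, the one with the smallest
#' interval wins and the tie is reported via `message()`. Mutations outside
#' every segment are flagged `assigned = FALSE`; downstream CCF computation
#' treats them as diploid (local copy number 2). No mutation is ever dropped.
#'
#' @param mutations tibble from [read_mutation_table()].
#' @param segments tibble from [read_seg_file()].
#' @param purity scalar purity in (0, 1] for this sample.
#' @param sample_id sample identifier shared by all inputs.
#' @param cancer_type optional cancer-type label.
#' @return An object of class `tumor_sample`: a list with elements
#'   `sample_id`, `purity`, `cancer_type`, `mutations` (with added columns
#'   `assigned`, `seg_mean`, `ccf_cnv`) and `segments`.
#' @export
assemble_tumor_sample <- function(mutations, segments, purity, sample_id,
                                  cancer_type = NA_character_) {
  stopifnot(length(purity) == 1, is.finite(purity))
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  muts <- mutations[mutations$sample_id == sample_id, , drop = FALSE]
  segs <- segments[segments$sample_id == sample_id, , drop = FALSE]

  n <- nrow(muts)
  assigned <- logical(n)
  seg_mean <- rep(NA_real_, n)
  ccf_cnv <- rep(1.0, n)
  ties <- 0L
  if (n > 0 && nrow(segs) > 0) {
    segs_by_chrom <- split(seq_len(nrow(segs)), segs$chrom)
    for (i in seq_len(n)) {
      idx <- segs_by_chrom[[muts$chrom[i]]]
      if (is.null(idx)) next
      hit <- idx[segs$start[idx] <= muts$pos[i] & muts$pos[i] <= segs$end[idx]]
      if (length(hit) == 0) next
      if (length(hit) > 1) {
        ties <- ties + 1L
        widths <- segs$end[hit] - segs$start[hit]
        hit <- hit[order(widths, segs$start[hit])][1]
      }
      assigned[i] <- TRUE
      seg_mean[i] <- segs$seg_mean[hit]
      ccf_cnv[i] <- segs$ccf_cnv[hit]
    }
  }
  if (ties > 0) {
    message(sprintf("%s: %d mutation(s) overlapped multiple segments; smallest interval chosen",
                    sample_id, ties))
  }
  muts$assigned <- assigned
  muts$seg_mean <- seg_mean
  muts$ccf_cnv <- ccf_cnv

  structure(
    list(sample_id = sample_id, purity = purity, cancer_type = cancer_type,
         mutations = muts, segments = segs),
    class = "tumor_sample"
  )
}

#' @export
print.tumor_sample <- function(x, ...) {
  cat(sprintf("<tumor_sample> %s (purity %.2f%s): %d mutations (%d assigned to %d segments)\n",
              x$sample_id, x$purity,
              if (is.na(x$cancer_type)) "" else paste0(", ", x$cancer_type),
              nrow(x$mutations), sum(x$mutations$assigned), nrow(x$segments)))
  invisible(x)
}
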