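# Readers and writers for the tabular formats the pipeline touches:
# mutation TSV (MAF subset), SEG (Broad dialect), purity TSV, expression TSV
# (genes in rows) and clone-tree JSON. readr handles gzip transparently.

#' Read a per-sample mutation table
#'
#' Expects a TSV with a header and columns `sample`, `chrom`, `pos`, `ref`,
#' `alt` plus either read counts (`alt_count`, `ref_count`) or a precomputed
#' `vaf`. The `"maf"` dialect additionally maps the standard MAF column names
#' (`Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`, `t_alt_count`, `t_ref_count`, `Hugo_Symbol`).
#'
#' Rows whose numeric fields fail coercion (or whose total depth is zero while
#' `vaf` must be derived) are dropped with a warning that reports the offending
#' line numbers.
#'
#' @param path path to a TSV file (optionally gzip-compressed).
#' @param dialect `"generic"` (default) or `"maf"`.
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `alt_count`, `ref_count`, `vaf`.
#' @export
read_mutation_table <- function(path, dialect = c("generic", "maf")) {
  dialect <- match.arg(dialect)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  names(tbl) <- tolower(names(tbl))
  if (dialect == "maf") {
    maf_map <- c(tumor_sample_barcode = "sample", chromosome = "chrom",
                 start_position = "pos", reference_allele = "ref",
                 tumor_seq_allele2 = "alt", t_alt_count = "alt_count",
                 t_ref_count = "ref_count", hugo_symbol = "gene")
    hit <- names(tbl) %in% names(maf_map)
    names(tbl)[hit] <- maf_map[names(tbl)[hit]]
  }
  required <- c("sample", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("mutation table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  has_counts <- all(c("alt_count", "ref_count") %in% names(tbl))
  has_vaf <- "vaf" %in% names(tbl)
  if (!has_counts && !has_vaf) {
    stop("mutation table must provide either (alt_count, ref_count) or vaf")
  }

  pos <- suppressWarnings(as.numeric(tbl$pos))
  alt_count <- if (has_counts) suppressWarnings(as.numeric(tbl$alt_count)) else NA_real_
  ref_count <- if (has_counts) suppressWarnings(as.numeric(tbl$ref_count)) else NA_real_
  vaf <- if (has_vaf) suppressWarnings(as.numeric(tbl$vaf)) else NA_real_

  bad <- is.na(pos)
  if (has_counts) {
    bad <- bad | is.na(alt_count) | is.na(ref_count) |
      alt_count < 0 | ref_count < 0
    if (!has_vaf) bad <- bad | (alt_count + ref_count) == 0
  }
  if (has_vaf) {
    bad_vaf <- !is.na(vaf) & (vaf < 0 | vaf > 1)
    if (!has_counts) bad_vaf <- bad_vaf | is.na(vaf)
    bad <- bad | bad_vaf
  }
  if (any(bad)) {
    warning(sprintf("dropped %d malformed mutation row(s) at line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
  }
  keep <- !bad
  out <- tibble::tibble(
    sample_id = as.character(tbl$sample)[keep],
    chrom     = as.character(tbl$chrom)[keep],
    pos       = as.integer(pos[keep]),
    ref       = as.character(tbl$ref)[keep],
    alt       = as.character(tbl$alt)[keep],
    gene      = if ("gene" %in% names(tbl)) as.character(tbl$gene)[keep] else NA_character_,
    alt_count = if (has_counts) alt_count[keep] else NA_real_,
    ref_count = if (has_counts) ref_count[keep] else NA_real_,
    vaf       = if (has_vaf) vaf[keep] else NA_real_
  )
  derive <- is.na(out$vaf) & !is.na(out$alt_count)
  out$vaf[derive] <- out$alt_count[derive] /
    (out$alt_count[derive] + out$ref_count[derive])
  out
}

#' Write a mutation table
#'
#' Inverse of [read_mutation_table()] for round-tripping.
#'
#' @param mutations tibble as returned by [read_mutation_table()].
#' @param path output path (`.gz` suffix compresses).
#' @export
write_mutation_table <- function(mutations, path) {
  out <- tibble::tibble(
    sample = mutations$sample_id, chrom = mutations$chrom, pos = mutations$pos,
    ref = mutations$ref, alt = mutations$alt, gene = mutations$gene,
    alt_count = mutations$alt_count, ref_count = mutations$ref_count,
    vaf = mutations$vaf
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a SEG-style copy-number segment file
#'
#' Accepts the Broad SEG dialect (`Sample`, `Chromosome`, `Start`, `End`,
#' `Num_Probes`, `Segment_Mean`; case-insensitive) or the generic headers
#' (`sample`, `chrom`, `start`, `end`, `seg_mean`). Rows with `start > end`
#' are dropped with a warning. Segments are returned sorted by
#' `(sample_id, chrom, start)`; overlapping segments are retained as-is (a
#' warning notes the overlap), and the absolute copy number is left for
#' downstream computation via [abs_cn_from_segmean()].
#'
#' @param path path to a SEG file (optionally gzip-compressed).
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `num_probes`, `seg_mean`, `ccf_cnv`.
#' @export
read_seg_file <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl) <- tolower(names(tbl))
  synonyms <- c(chromosome = "chrom", loc.start = "start", loc.end = "end",
                segment_mean = "seg_mean", num_mark = "num_probes")
  hit <- names(tbl) %in% names(synonyms)
  names(tbl)[hit] <- synonyms[names(tbl)[hit]]
  required <- c("sample", "chrom", "start", "end", "seg_mean")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("SEG file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  start <- as.numeric(tbl$start)
  end <- as.numeric(tbl$end)
  bad <- is.na(start) | is.na(end) | start > end
  if (any(bad)) {
    warning(sprintf("dropped %d SEG row(s) with start > end or missing bounds at line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
  }
  out <- tibble::tibble(
    sample_id  = as.character(tbl$sample)[!bad],
    chrom      = as.character(tbl$chrom)[!bad],
    start      = as.integer(start[!bad]),
    end        = as.integer(end[!bad]),
    num_probes = if ("num_probes" %in% names(tbl)) as.numeric(tbl$num_probes)[!bad] else NA_real_,
    seg_mean   = as.numeric(tbl$seg_mean)[!bad],
    ccf_cnv    = if ("ccf_cnv" %in% names(tbl)) as.numeric(tbl$ccf_cnv)[!bad] else 1.0
  )
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  has_overlap <- vapply(
    split(out, paste(out$sample_id, out$chrom)),
    function(g) nrow(g) > 1 && any(g$start[-1] <= head(g$end, -1)),
    logical(1)
  )
  if (any(has_overlap)) {
    warning("overlapping segments detected (",
            paste(names(has_overlap)[has_overlap], collapse = "; "),
            "); all segments retained")
  }
  out
}

#' Write a SEG file (Broad dialect headers)
#'
#' @param segments tibble as returned by [read_seg_file()].
#' @param path output path.
#' @export
write_seg_file <- function(segments, path) {
  out <- tibble::tibble(
    Sample = segments$sample_id, Chromosome = segments$chrom,
    Start = segments$start, End = segments$end,
    Num_Probes = segments$num_probes, Segment_Mean = segments$seg_mean,
    ccf_cnv = segments$ccf_cnv
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample purity table
#'
#' Expects columns `sample` and `purity`; purity must lie in (0, 1].
#'
#' @param path path to a TSV file.
#' @return A named numeric vector mapping sample id to purity.
#' @export
read_purity_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl) <- tolower(names(tbl))
  if (!all(c("sample", "purity") %in% names(tbl))) {
    stop("purity table must have columns 'sample' and 'purity'")
  }
  purity <- as.numeric(tbl$purity)
  if (any(is.na(purity) | purity <= 0 | purity > 1)) {
    stop("purity values must lie in (0, 1]; offending sample(s): ",
         paste(tbl$sample[is.na(purity) | purity <= 0 | purity > 1], collapse = ", "))
  }
  setNames(purity, as.character(tbl$sample))
}

#' Write a purity table
#'
#' @param purity named numeric vector (names are sample ids).
#' @param path output path.
#' @export
write_purity_table <- function(purity, path) {
  readr::write_tsv(tibble::tibble(sample = names(purity), purity = unname(purity)),
                   path, progress = FALSE)
  invisible(path)
}

#' Read an expression matrix (genes in rows)
#'
#' First column holds gene ids; remaining columns are samples. Values are
#' assumed log-scale. Duplicate gene or sample ids, or non-finite values,
#' are errors.
#'
#' @param path path to a TSV file.
#' @return A numeric matrix with genes in rows and samples in columns.
#' @export
read_expression_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  gene_ids <- as.character(tbl[[1]])
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids in expression matrix")
  if (!all(is.finite(mat))) stop("non-finite values in expression matrix")
  rownames(mat) <- gene_ids
  mat
}

#' Write an expression matrix (genes in rows)
#'
#' @param mat numeric matrix, genes in rows.
#' @param path output path.
#' @export
write_expression_matrix <- function(mat, path) {
  out <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
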