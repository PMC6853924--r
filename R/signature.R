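# Up/down gene-expression signature construction and single-sample scoring.
#
# The construction follows the standard variable-gene recipe: robust per-gene
# normalization (median-centered, SD-scaled across samples), ranking by median
# absolute deviation, greedy pruning toward a compact signature dominated by
# its first principal component, and sign-of-loading assignment of genes to
# the "up" versus "down" set. The single-sample score is the difference of
# up- and down-gene means relative to the within-sample variation of the
# signature genes.

#' Normalize an expression matrix across samples
#'
#' Each gene is re-expressed as standard deviations from its median across
#' samples: `(x - median) / sd`. Genes with zero variance are set to 0 and
#' listed in the `"zero_sd_genes"` attribute.
#'
#' @param mat numeric matrix, genes in rows, at least 3 samples.
#' @return Normalized matrix of the same shape.
#' @export
normalize_expression <- function(mat) {
  if (ncol(mat) < 3) stop("normalization requires at least 3 samples")
  med <- apply(mat, 1, median)
  s <- apply(mat, 1, sd)
  flagged <- rownames(mat)[s == 0]
  s[s == 0] <- Inf  # zero-variance rows map to 0
  out <- (mat - med) / s
  attr(out, "zero_sd_genes") <- flagged
  out
}

#' Rank genes by variability (median absolute deviation)
#'
#' Genes are ranked by MAD across samples; ties break lexicographically on
#' the gene id. Requesting more genes than available returns all genes with
#' a warning.
#'
#' @param mat numeric matrix, genes in rows. Rank on the raw log scale:
#'   per-gene standardization equalizes dispersion and defeats the ranking.
#' @param n_genes number of top genes to return.
#' @return Character vector of gene ids, most variable first.
#' @export
select_variable_genes <- function(mat, n_genes) {
  if (n_genes > nrow(mat)) {
    warning("n_genes exceeds the gene count; returning all genes")
    n_genes <- nrow(mat)
  }
  m <- apply(mat, 1, mad)
  ids <- rownames(mat)
  ids[order(-m, ids)][seq_len(n_genes)]
}

#' Prune candidate genes into a compact up/down signature
#'
#' Greedy pruning: at each step the gene whose removal most increases the
#' mean absolute inter-gene correlation (compactness) is dropped; pruning
#' stops when the variance share of the first principal component stops
#' improving, or when `target_size` is reached. Genes are assigned to the up
#' versus down set by the sign of their loading on the first principal
#' component, oriented so the gene with the largest absolute loading is "up"
#' (the orientation of an unsupervised signature is arbitrary; flip the sets
#' to reverse the score sign). Per-gene medians and SDs of `mat` are stored
#' for applying the signature to new data.
#'
#' @param mat numeric matrix, genes in rows (normalized scale recommended).
#' @param candidate_genes character vector of at least 10 candidate gene ids.
#' @param target_size optional fixed signature size.
#' @param min_size smallest size the greedy search may reach when
#'   `target_size` is `NULL` (default 10).
#' @return An object of class `gene_signature`: list with `up_genes`,
#'   `down_genes`, `per_gene_center`, `per_gene_scale`.
#' @export
prune_signature <- function(mat, candidate_genes, target_size = NULL,
                            min_size = 10) {
  if (length(candidate_genes) < 10) stop("at least 10 candidate genes are required")
  stopifnot(all(candidate_genes %in% rownames(mat)))
  if (!is.null(target_size)) {
    stopifnot(target_size >= 2, target_size <= length(candidate_genes))
  }
  x <- t(mat[candidate_genes, , drop = FALSE])  # samples x genes

  pc1_share <- function(x) {
    d <- svd(scale(x, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
    d[1]^2 / sum(d^2)
  }
  compactness <- function(cm) {
    v <- abs(cm[upper.tri(cm)])
    mean(v)
  }

  cm <- suppressWarnings(cor(x))
  if (any(!is.finite(cm))) {
    warning("degenerate correlation structure; returning candidates unpruned")
    keep <- candidate_genes
  } else {
    keep <- candidate_genes
    share <- pc1_share(x[, keep, drop = FALSE])
    stop_size <- if (is.null(target_size)) min_size else target_size
    while (length(keep) > stop_size) {
      # gene whose removal most improves compactness
      gains <- vapply(seq_along(keep), function(j) {
        compactness(cm[keep[-j], keep[-j]])
      }, numeric(1))
      j_drop <- which.max(gains)
      new_keep <- keep[-j_drop]
      new_share <- pc1_share(x[, new_keep, drop = FALSE])
      if (is.null(target_size) && new_share <= share) break
      keep <- new_keep
      share <- new_share
    }
  }

  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  loading <- pc$rotation[, 1]
  if (loading[which.max(abs(loading))] < 0) loading <- -loading
  up <- keep[loading > 0]
  down <- keep[loading <= 0]
  if (length(up) == 0 || length(down) == 0) {
    warning("first principal component has single-signed loadings; up/down split is degenerate")
  }
  structure(
    list(up_genes = up, down_genes = down,
         per_gene_center = apply(mat[keep, , drop = FALSE], 1, median),
         per_gene_scale = apply(mat[keep, , drop = FALSE], 1, sd)),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %d up + %d down genes\n",
              length(x$up_genes), length(x$down_genes)))
  invisible(x)
}

#' Score samples against an up/down signature
#'
#' Within each sample the score is the difference of the up- and down-gene
#' means relative to the within-sample variation of the signature genes:
#' `(mean(up) - mean(down)) / sd(all signature genes)`. Swapping the up and
#' down sets negates every score. Signature genes absent from the matrix are
#' dropped with a warning; a zero within-sample SD yields `NA`.
#'
#' @param mat numeric matrix, genes in rows (same scale the signature was
#'   built on).
#' @param signature a [prune_signature()] object (or any list with `up_genes`
#'   and `down_genes`).
#' @return A tibble with columns `sample_id`, `score`.
#' @export
score_samples <- function(mat, signature) {
  up <- intersect(signature$up_genes, rownames(mat))
  down <- intersect(signature$down_genes, rownames(mat))
  missing <- setdiff(c(signature$up_genes, signature$down_genes), rownames(mat))
  if (length(missing) > 0) {
    warning("signature gene(s) absent from matrix and dropped: ",
            paste(missing, collapse = ", "))
  }
  if (length(up) == 0 || length(down) == 0) {
    stop("both up and down sets must be represented in the matrix")
  }
  scores <- vapply(seq_len(ncol(mat)), function(j) {
    vals <- mat[c(up, down), j]
    s <- sd(vals)
    if (s == 0) return(NA_real_)
    (mean(mat[up, j]) - mean(mat[down, j])) / s
  }, numeric(1))
  if (anyNA(scores)) {
    warning("zero within-sample SD for sample(s): ",
            paste(colnames(mat)[is.na(scores)], collapse = ", "))
  }
  tibble::tibble(sample_id = colnames(mat), score = scores)
}

#' Serialize a gene signature to JSON
#'
#' @param signature a `gene_signature`.
#' @param path output path.
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(
    list(up_genes = signature$up_genes, down_genes = signature$down_genes,
         per_gene_center = as.list(signature$per_gene_center),
         per_gene_scale = as.list(signature$per_gene_scale)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a gene signature written by [write_signature()]
#'
#' @param path JSON path.
#' @return A `gene_signature`.
#' @export
read_signature <- function(path) {
  raw <- jsonlite::fromJSON(path)
  structure(
    list(up_genes = as.character(raw$up_genes),
         down_genes = as.character(raw$down_genes),
         per_gene_center = unlist(raw$per_gene_center),
         per_gene_scale = unlist(raw$per_gene_scale)),
    class = "gene_signature"
  )
}
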