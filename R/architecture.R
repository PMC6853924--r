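# Per-tumor clonal-architecture summaries: Shannon diversity of the 10-bin
# CCF histogram, median CCF, and linearity/branching indices over clone trees.

#' Bin a CCF value into the shared 10-bin histogram
#'
#' Bins are `[0, 0.1), [0.1, 0.2), ..., [0.9, 1.0]`: half-open except the
#' last, which is closed so clonal mutations (CCF = 1) occupy the top bin.
#' Values are clipped to `[0, 1]` first.
#'
#' @param ccf numeric vector of CCFs.
#' @return Integer bin indices in `1..10`.
#' @export
ccf_bin <- function(ccf) {
  x <- pmin(pmax(ccf, 0), 1)
  pmin(as.integer(floor(x * 10)) + 1L, 10L)
}

#' Shannon diversity of the CCF distribution
#'
#' The CCF histogram is divided into 10 equal bins and the information
#' entropy `H = -sum(p_i * ln(p_i))` (natural log, nats) is computed over the
#' bin proportions, with `0 * ln(0) = 0`. Lower values indicate collapsed
#' clonal diversity (e.g. after a hard sweep); the maximum is `ln(10)`.
#'
#' @param ccfs non-empty numeric vector of CCFs (clipped to `[0, 1]`).
#' @return A list with `h` (entropy in nats) and `bin_counts` (10 integers).
#' @export
diversity_index <- function(ccfs) {
  ccfs <- ccfs[!is.na(ccfs)]
  if (length(ccfs) == 0) stop("diversity_index requires a non-empty CCF vector")
  counts <- tabulate(ccf_bin(ccfs), nbins = 10)
  p <- counts / sum(counts)
  nz <- p > 0
  list(h = -sum(p[nz] * log(p[nz])), bin_counts = counts)
}

#' Median CCF of a tumor
#'
#' Standard median (mean of the middle two values for even counts).
#'
#' @param ccfs non-empty numeric vector.
#' @return Median CCF.
#' @export
median_ccf <- function(ccfs) {
  ccfs <- ccfs[!is.na(ccfs)]
  if (length(ccfs) == 0) stop("median_ccf requires a non-empty CCF vector")
  median(ccfs)
}

# ranking order shared by best_tree() and averaged_tree_indices()
.tree_order <- function(trees, best = c("lowest", "highest")) {
  best <- match.arg(best)
  ll <- vapply(trees, function(tr) tr$log_likelihood, numeric(1))
  nn <- vapply(trees, function(tr) nrow(tr$nodes), numeric(1))
  key <- if (best == "lowest") ll else -ll
  order(key, nn, seq_along(trees))
}

#' Select the best tree among sampled clone trees
#'
#' Returns the tree with the lowest normalized log likelihood (the reported
#' "best tree" convention of the upstream reconstructor); `best = "highest"`
#' provides the conventional maximum-likelihood reading. Ties break toward
#' fewer nodes, then first occurrence. If no tree carries a likelihood, the
#' first tree is returned with a warning.
#'
#' @param trees list of `clone_tree` objects, at least one.
#' @param best `"lowest"` (default) or `"highest"`.
#' @return A `clone_tree`.
#' @export
best_tree <- function(trees, best = c("lowest", "highest")) {
  stopifnot(length(trees) >= 1)
  ll <- vapply(trees, function(tr) tr$log_likelihood, numeric(1))
  if (all(is.na(ll))) {
    warning("no tree carries a log likelihood; returning the first tree")
    return(trees[[1]])
  }
  trees <- trees[!is.na(ll)]
  trees[[.tree_order(trees, best)[1]]]
}

#' Linearity and branching indices of a clone tree
#'
#' Over all unordered pairs of mutations sitting in distinct nodes, a pair is
#' *linear* when one node is an ancestor of the other and *branched* when the
#' nodes are incomparable (sibling lineages). The indices are the linear and
#' branched pair fractions of all cross-node pairs; same-node pairs are
#' excluded, so `linearity + branching = 1` for any non-degenerate tree.
#' Trees with fewer than two mutation-bearing nodes return both indices as 0
#' with `degenerate = TRUE`.
#'
#' @param tree a `clone_tree`.
#' @return A list with `linearity`, `branching`, `n_pairs` (cross-node
#'   mutation pairs) and `degenerate`.
#' @export
tree_indices <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  nodes <- tree$nodes
  if (sum(nodes$n_mutations > 0) < 2) {
    return(list(linearity = 0, branching = 0, n_pairs = 0L, degenerate = TRUE))
  }
  parent_of <- setNames(nodes$parent_id, nodes$node_id)
  mut_of <- setNames(nodes$n_mutations, nodes$node_id)
  # mutations in strict ancestors of each node
  anc_mut <- vapply(nodes$node_id, function(v) {
    total <- 0L
    cur <- parent_of[[as.character(v)]]
    while (!is.na(cur)) {
      total <- total + mut_of[[as.character(cur)]]
      cur <- parent_of[[as.character(cur)]]
    }
    total
  }, integer(1))
  m <- nodes$n_mutations
  total_cross <- (sum(m)^2 - sum(m^2)) / 2
  linear <- sum(as.numeric(m) * as.numeric(anc_mut))
  branched <- total_cross - linear
  list(linearity = linear / total_cross, branching = branched / total_cross,
       n_pairs = as.integer(total_cross), degenerate = FALSE)
}

#' Average linearity/branching over the top-ranked sampled trees
#'
#' Unweighted mean of the per-tree indices over the `top_k` trees under the
#' [best_tree()] ranking (all trees by default). Degenerate trees contribute
#' their zero indices.
#'
#' @param trees list of `clone_tree` objects.
#' @param top_k number of top-ranked trees to average (default all).
#' @param best ranking convention, see [best_tree()].
#' @return A list with `linearity`, `branching`, `n_trees_averaged`.
#' @export
averaged_tree_indices <- function(trees, top_k = NULL, best = c("lowest", "highest")) {
  stopifnot(length(trees) >= 1)
  ll <- vapply(trees, function(tr) tr$log_likelihood, numeric(1))
  ranked <- if (all(is.na(ll))) trees else trees[.tree_order(trees, best)]
  if (is.null(top_k)) top_k <- length(ranked)
  top_k <- min(top_k, length(ranked))
  idx <- lapply(ranked[seq_len(top_k)], tree_indices)
  list(linearity = mean(vapply(idx, `[[`, numeric(1), "linearity")),
       branching = mean(vapply(idx, `[[`, numeric(1), "branching")),
       n_trees_averaged = top_k)
}

#' Linear association between two per-sample summaries
#'
#' Ordinary least-squares fit of `y ~ x` with the standard t-test for a
#' non-zero slope; used for e.g. diversity-versus-multiplicity trends across
#' a cohort.
#'
#' @param x,y paired numeric vectors, at least 3 complete pairs.
#' @return A list with `slope`, `intercept`, `p_value`, `degenerate` (`TRUE`
#'   when `x` has zero variance, in which case the fit is skipped).
#' @export
architecture_association <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("at least 3 paired samples are required")
  if (sd(x) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  }
  fit <- lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["x", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       p_value = unname(cf["x", "Pr(>|t|)"]),
       degenerate = FALSE)
}

#' Architecture metrics for one CCF table
#'
#' Convenience wrapper computing the per-sample summary row used by the
#' pipeline: mutation count, median CCF, diversity entropy and clonal count.
#'
#' @param ccf_table tibble from [compute_ccf_table()] (one sample).
#' @return A one-row tibble.
#' @export
architecture_metrics <- function(ccf_table) {
  ccfs <- ccf_table$ccf[!is.na(ccf_table$ccf)]
  div <- diversity_index(ccfs)
  tibble::tibble(
    sample_id = ccf_table$sample_id[1],
    n_mutations = length(ccfs),
    median_ccf = median_ccf(ccfs),
    diversity_h = div$h,
    n_clonal = sum(ccf_table$clonal, na.rm = TRUE)
  )
}
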