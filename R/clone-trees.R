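# Clone trees as emitted by an external subclone reconstructor: a rooted tree
# whose nodes carry a mutation count and a cellular prevalence, optionally a
# normalized log likelihood for ranking sampled trees.

#' Construct and validate a clone tree
#'
#' @param nodes tibble (or data frame) with columns `node_id`, `parent_id`
#'   (`NA` marks the root), `n_mutations`, `prevalence`.
#' @param log_likelihood optional normalized log likelihood of the tree.
#' @param prevalence_tol tolerance for the child-prevalence-at-most-parent
#'   ("pigeonhole") invariant.
#' @return An object of class `clone_tree`.
#' @export
clone_tree <- function(nodes, log_likelihood = NA_real_, prevalence_tol = 1e-6) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("node_id", "parent_id", "n_mutations", "prevalence") %in% names(nodes)))
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$n_mutations <- as.integer(nodes$n_mutations)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node ids in clone tree")
  if (any(nodes$n_mutations < 0, na.rm = TRUE)) stop("negative mutation count")
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1) {
    stop("clone tree must have exactly one root, found ", length(roots))
  }
  nonroot <- which(!is.na(nodes$parent_id))
  if (!all(nodes$parent_id[nonroot] %in% nodes$node_id)) {
    stop("parent id refers to a missing node")
  }
  # acyclicity: climbing to the root must terminate for every node
  parent_of <- setNames(nodes$parent_id, nodes$node_id)
  for (v in nodes$node_id) {
    seen <- integer(0)
    cur <- v
    while (!is.na(parent_of[[as.character(cur)]])) {
      if (cur %in% seen) stop("cycle detected in clone tree at node ", v)
      seen <- c(seen, cur)
      cur <- parent_of[[as.character(cur)]]
      if (length(seen) > nrow(nodes)) stop("cycle detected in clone tree at node ", v)
    }
  }
  if (any(nodes$prevalence < -prevalence_tol | nodes$prevalence > 1 + prevalence_tol)) {
    stop("node prevalence outside [0, 1]")
  }
  prev_of <- setNames(nodes$prevalence, nodes$node_id)
  for (i in nonroot) {
    if (nodes$prevalence[i] > prev_of[[as.character(nodes$parent_id[i])]] + prevalence_tol) {
      stop("child prevalence exceeds parent prevalence at node ", nodes$node_id[i])
    }
  }
  structure(list(nodes = nodes, log_likelihood = as.numeric(log_likelihood)),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("<clone_tree> %d nodes, %d mutations%s\n",
              nrow(x$nodes), sum(x$nodes$n_mutations),
              if (is.na(x$log_likelihood)) ""
              else sprintf(", normalized log likelihood %.4g", x$log_likelihood)))
  invisible(x)
}

#' Read clone trees from JSON
#'
#' The file holds an array of trees; each tree is an object with a `nodes`
#' array (fields `id`, `parent` with `null` for the root, `n_mutations`,
#' `prevalence`) and an optional `log_likelihood`. Ordering is preserved.
#' Structural defects (cycles, multiple roots, dangling parents) are errors.
#'
#' @param path path to a JSON file.
#' @param prevalence_tol passed to [clone_tree()].
#' @return A list of `clone_tree` objects.
#' @export
read_clone_trees <- function(path, prevalence_tol = 1e-6) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(tr) {
    nodes <- tibble::tibble(
      node_id = vapply(tr$nodes, function(n) as.integer(n$id), integer(1)),
      parent_id = vapply(tr$nodes, function(n) {
        if (is.null(n$parent)) NA_integer_ else as.integer(n$parent)
      }, integer(1)),
      n_mutations = vapply(tr$nodes, function(n) as.integer(n$n_mutations), integer(1)),
      prevalence = vapply(tr$nodes, function(n) as.numeric(n$prevalence), numeric(1))
    )
    ll <- if (is.null(tr$log_likelihood)) NA_real_ else as.numeric(tr$log_likelihood)
    clone_tree(nodes, ll, prevalence_tol = prevalence_tol)
  })
}

#' Write clone trees to JSON
#'
#' Inverse of [read_clone_trees()].
#'
#' @param trees list of `clone_tree` objects.
#' @param path output path.
#' @export
write_clone_trees <- function(trees, path) {
  payload <- lapply(trees, function(tr) {
    nodes <- lapply(seq_len(nrow(tr$nodes)), function(i) {
      list(id = tr$nodes$node_id[i],
           parent = if (is.na(tr$nodes$parent_id[i])) NULL else tr$nodes$parent_id[i],
           n_mutations = tr$nodes$n_mutations[i],
           prevalence = tr$nodes$prevalence[i])
    })
    out <- list(nodes = nodes)
    if (!is.na(tr$log_likelihood)) out$log_likelihood <- tr$log_likelihood
    out
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
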