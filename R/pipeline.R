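# End-to-end pipeline stages over the on-disk formats, each writing a JSON
# manifest (package version, seed, parameters, input hashes) sufficient to
# reproduce the run. A thin command-line wrapper over these functions ships
# in inst/scripts/clonesweep.R.

.write_manifest <- function(out_dir, stage, params, extra = list()) {
  manifest <- c(
    list(stage = stage,
         package = "clonesweep",
         version = as.character(utils::packageVersion("clonesweep")),
         params = params),
    extra
  )
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Simulates a cohort with [simulate_cohort()] and writes the exact formats
#' the readers consume: `mutations.tsv`, `segments.seg`, `purity.tsv` and a
#' `truth.tsv` with the generating values.
#'
#' @param out_dir output directory (created if needed).
#' @param n_per_regime named vector of tumors per regime.
#' @param base_config a [sim_tumor_config()].
#' @param seed master seed.
#' @param config_overrides see [simulate_cohort()].
#' @return Invisibly, the cohort list.
#' @export
run_simulate <- function(out_dir, n_per_regime = c(NEUTRAL = 5),
                         base_config = sim_tumor_config(), seed = 1L,
                         config_overrides = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(n_per_regime, base_config, seed, config_overrides)
  mutations <- dplyr::bind_rows(lapply(cohort, function(t) t$sample$mutations))
  segments <- dplyr::bind_rows(lapply(cohort, function(t) t$sample$segments))
  purity <- setNames(vapply(cohort, function(t) t$sample$purity, numeric(1)),
                     vapply(cohort, function(t) t$sample$sample_id, character(1)))
  truth <- dplyr::bind_rows(lapply(cohort, function(t) {
    tt <- t$truth$mutations
    tt$regime <- t$truth$regime
    tt$s <- t$truth$s
    tt$purity <- t$truth$purity
    tt
  }))
  write_mutation_table(mutations, file.path(out_dir, "mutations.tsv"))
  write_seg_file(segments, file.path(out_dir, "segments.seg"))
  write_purity_table(purity, file.path(out_dir, "purity.tsv"))
  readr::write_tsv(truth, file.path(out_dir, "truth.tsv"), progress = FALSE)
  .write_manifest(out_dir, "simulate",
                  list(seed = seed, n_per_regime = as.list(n_per_regime),
                       base_config = unclass(base_config)),
                  list(n_samples = length(cohort)))
  invisible(cohort)
}

#' CCF stage: mutation + segment + purity files to CCF and metrics tables
#'
#' Assembles each sample, computes the per-mutation CCF table and the
#' per-sample architecture metrics, and writes `ccf.tsv`, `metrics.tsv` and
#' a manifest. Samples missing from the purity table are skipped and listed
#' in the manifest.
#'
#' @param mutation_file,seg_file,purity_file input paths.
#' @param out_dir output directory.
#' @param clonal_threshold CCF clonality threshold (default 0.95).
#' @param round_cn round absolute copy numbers (default `TRUE`).
#' @param dialect mutation-table dialect, see [read_mutation_table()].
#' @return Invisibly, a list with `ccf` and `metrics` tibbles.
#' @export
run_ccf <- function(mutation_file, seg_file, purity_file, out_dir,
                    clonal_threshold = 0.95, round_cn = TRUE,
                    dialect = "generic") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mutations <- read_mutation_table(mutation_file, dialect = dialect)
  segments <- read_seg_file(seg_file)
  purity <- read_purity_table(purity_file)
  samples <- unique(mutations$sample_id)
  skipped <- setdiff(samples, names(purity))
  if (length(skipped) > 0) {
    warning("sample(s) missing from purity table, skipped: ",
            paste(skipped, collapse = ", "))
  }
  samples <- intersect(samples, names(purity))
  ccf_tables <- list(); metric_rows <- list()
  for (sid in samples) {
    ts <- assemble_tumor_sample(mutations, segments, purity[[sid]], sid)
    tab <- compute_ccf_table(ts, clonal_threshold = clonal_threshold,
                             round_cn = round_cn)
    ccf_tables[[sid]] <- tab
    metric_rows[[sid]] <- architecture_metrics(tab)
  }
  ccf <- dplyr::bind_rows(ccf_tables)
  metrics <- dplyr::bind_rows(metric_rows)
  write_ccf_table(ccf, file.path(out_dir, "ccf.tsv"))
  readr::write_tsv(metrics, file.path(out_dir, "metrics.tsv"), progress = FALSE)
  .write_manifest(out_dir, "ccf",
                  list(mutation_file = mutation_file, seg_file = seg_file,
                       purity_file = purity_file,
                       clonal_threshold = clonal_threshold,
                       round_cn = round_cn),
                  list(n_samples = length(samples),
                       skipped_samples = as.list(skipped)))
  invisible(list(ccf = ccf, metrics = metrics))
}

#' Selection-fit stage: CCF table to per-sample selection estimates
#'
#' For each sample the driver CCF is taken from the highest-CCF record of
#' `driver_gene` (samples without the driver are recorded in the manifest
#' and skipped); [estimate_selection()] is then run on the sample's records.
#' Per-sample failures are caught and recorded, and the run continues.
#'
#' @param ccf_file path to a CCF table written by [write_ccf_table()].
#' @param out_dir output directory.
#' @param config a [selection_config()].
#' @param driver_gene gene symbol of the driver (default `"BRAF"`).
#' @return Invisibly, the estimates tibble.
#' @export
run_sweep_fit <- function(ccf_file, out_dir, config = selection_config(),
                          driver_gene = "BRAF") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ccf <- read_ccf_table(ccf_file)
  rows <- list(); failures <- character(0)
  for (sid in unique(ccf$sample_id)) {
    tab <- ccf[ccf$sample_id == sid, , drop = FALSE]
    driver_rows <- tab[!is.na(tab$gene) & tab$gene == driver_gene, , drop = FALSE]
    if (nrow(driver_rows) == 0) {
      failures <- c(failures, paste0(sid, ": no ", driver_gene, " record"))
      next
    }
    est <- tryCatch(
      estimate_selection(tab, driver_ccf = max(driver_rows$ccf), config = config),
      error = function(e) e
    )
    if (inherits(est, "error")) {
      failures <- c(failures, paste0(sid, ": ", conditionMessage(est)))
      next
    }
    rows[[sid]] <- tibble::tibble(
      sample_id = sid, s_hat = est$s_hat, mu_hat = est$mu_hat,
      regime = est$regime, objective = est$objective,
      n_passengers_used = est$n_passengers_used,
      flags = paste(est$flags, collapse = ",")
    )
  }
  estimates <- dplyr::bind_rows(rows)
  readr::write_tsv(estimates, file.path(out_dir, "selection.tsv"), progress = FALSE)
  .write_manifest(out_dir, "sweep_fit",
                  list(ccf_file = ccf_file, driver_gene = driver_gene,
                       config = unclass(config)[setdiff(names(unclass(config)), "s_grid")],
                       s_grid_range = range(config$s_grid),
                       s_grid_step = if (length(config$s_grid) > 1)
                         diff(config$s_grid[1:2]) else NA),
                  list(failures = as.list(failures)))
  invisible(estimates)
}

#' Signature stage: expression matrix to signature, scores and association
#'
#' Normalizes the matrix, ranks genes by MAD, prunes the top candidates into
#' an up/down signature, scores every sample, and (when a feature table is
#' given) tests the information-coefficient association between the binary
#' feature and the scores by permutation. Writes `signature.json`,
#' `scores.tsv` and optionally `association.tsv`.
#'
#' @param expression_file TSV with genes in rows.
#' @param out_dir output directory.
#' @param n_candidates number of top-MAD candidate genes (default 50).
#' @param target_size optional fixed signature size.
#' @param feature_file optional TSV with columns `sample` and `feature`
#'   (binary).
#' @param n_perm permutations for the association test (default 999).
#' @param seed seed for the permutation generator.
#' @return Invisibly, a list with `signature`, `scores` and optionally
#'   `association`.
#' @export
run_signature <- function(expression_file, out_dir, n_candidates = 50,
                          target_size = NULL, feature_file = NULL,
                          n_perm = 999, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat <- read_expression_matrix(expression_file)
  norm <- normalize_expression(mat)
  candidates <- select_variable_genes(mat, n_candidates)  # rank on raw scale
  sig <- prune_signature(norm, candidates, target_size = target_size)
  scores <- score_samples(norm, sig)
  write_signature(sig, file.path(out_dir, "signature.json"))
  readr::write_tsv(scores, file.path(out_dir, "scores.tsv"), progress = FALSE)
  out <- list(signature = sig, scores = scores)
  if (!is.null(feature_file)) {
    feat <- readr::read_tsv(feature_file, show_col_types = FALSE, progress = FALSE)
    names(feat) <- tolower(names(feat))
    merged <- merge(scores, feat, by.x = "sample_id", by.y = "sample")
    res <- permutation_pvalue(merged$feature, merged$score, n_perm = n_perm,
                              seed = seed)
    assoc <- tibble::tibble(feature = "feature", ic = res$ic,
                            p_value = res$p_value,
                            n_permutations = res$n_permutations)
    readr::write_tsv(assoc, file.path(out_dir, "association.tsv"), progress = FALSE)
    out$association <- assoc
  }
  .write_manifest(out_dir, "signature",
                  list(expression_file = expression_file,
                       n_candidates = n_candidates,
                       target_size = target_size, feature_file = feature_file,
                       n_perm = n_perm, seed = seed),
                  list(n_up = length(sig$up_genes),
                       n_down = length(sig$down_genes)))
  invisible(out)
}
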