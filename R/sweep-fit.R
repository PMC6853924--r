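# Per-tumor selection-strength estimation from the subclonal (passenger)
# frequency spectrum.
#
# The driver's observed CCF fixes, for each candidate fitness s, the time the
# sweep has been running; the hitch-hiker model then predicts the frequency of
# every passenger rank i at that time. Two objectives are available:
#
# * "censored_binomial" (default): the observed subclonal mutations, ranked by
#   CCF, are matched to passenger ranks and scored with a binomial read-count
#   likelihood; passenger ranks beyond the observed set contribute the
#   probability of falling below the detection threshold. Binning is avoided
#   because, at mutation rates far below the fitness, the entire predicted
#   spectrum lies inside the lowest CCF bin and a binned objective carries no
#   information about s.
# * "multinomial": the 10-bin CCF histogram (shared with the diversity index)
#   scored against the predicted bin mass.

#' Configuration for [estimate_selection()]
#'
#' @param s_grid grid of candidate fitness values (default `seq(1, 5, 0.01)`).
#' @param mu neutral mutation rate on the sweeping clone (default 0.001); used
#'   as-is unless `mu_grid` is given.
#' @param mu_grid optional log-spaced grid over which `mu` is profiled.
#' @param N population size in cells (default 1e6).
#' @param n_model_passengers number of passenger ranks in the model (default
#'   100).
#' @param min_passengers observed subclonal mutations below this count set a
#'   `low_n` diagnostic flag (default 5). The censored objective remains
#'   defined at zero observations (absence of detectable hitch-hikers is
#'   itself informative), so the estimate is still returned.
#' @param mean_depth sequencing depth assumed for undetected passenger ranks;
#'   `NULL` (default) uses the median depth of the input records.
#' @param min_alt detection threshold in alt reads (default 2).
#' @param hard_cut fitted fitness at or above this value is a hard sweep
#'   (default 1.5).
#' @param neutral_tol fitted fitness within this distance of 1 is neutral
#'   (default 0.05).
#' @param clonal_threshold CCF above which records are excluded as clonal
#'   (default 0.95).
#' @param passenger_ccf_max upper CCF bound of the passenger window (default
#'   0.6). Records with CCF in `(passenger_ccf_max, clonal_threshold]` are
#'   ambiguous — under read noise the clonal cluster sheds mass into that
#'   range — and are excluded from the spectrum fit entirely.
#' @param objective `"censored_binomial"` (default) or `"multinomial"`.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(s_grid = seq(1, 5, by = 0.01),
                             mu = 1e-3, mu_grid = NULL, N = 1e6,
                             n_model_passengers = 100, min_passengers = 5,
                             mean_depth = NULL, min_alt = 2,
                             hard_cut = 1.5, neutral_tol = 0.05,
                             clonal_threshold = 0.95, passenger_ccf_max = 0.6,
                             objective = c("censored_binomial", "multinomial")) {
  structure(list(s_grid = s_grid, mu = mu, mu_grid = mu_grid, N = N,
                 n_model_passengers = n_model_passengers,
                 min_passengers = min_passengers, mean_depth = mean_depth,
                 min_alt = min_alt, hard_cut = hard_cut,
                 neutral_tol = neutral_tol,
                 clonal_threshold = clonal_threshold,
                 passenger_ccf_max = passenger_ccf_max,
                 objective = match.arg(objective)),
            class = "selection_config")
}

# log-likelihood of the observed subclonal records under fitness s (mu fixed)
.sweep_loglik <- function(s, mu, cfg, driver_ccf, obs, mean_depth) {
  t_obs <- solve_sweep_time(s, cfg$N, driver_ccf)
  k_model <- max(cfg$n_model_passengers, nrow(obs))
  n_i <- passenger_frequency(seq_len(k_model), t_obs, s, mu)
  ll <- 0
  if (nrow(obs) > 0) {
    idx <- seq_len(nrow(obs))
    vaf_pred <- obs$purity * n_i[idx] /
      (obs$purity * obs$local_cn + 2 * (1 - obs$purity))
    vaf_pred <- pmin(pmax(vaf_pred, 1e-12), 1 - 1e-12)
    ll <- ll + sum(dbinom(obs$alt_count, obs$depth, vaf_pred, log = TRUE))
  }
  if (k_model > nrow(obs)) {
    idx <- (nrow(obs) + 1):k_model
    vaf_cens <- pmin(pmax(n_i[idx] / 2, 1e-12), 1 - 1e-12)  # diploid, m = 1
    ll <- ll + sum(pbinom(cfg$min_alt - 1, mean_depth, vaf_cens, log.p = TRUE))
  }
  ll
}

# multinomial alternative: 10-bin histogram of observed subclonal CCFs vs
# predicted passenger bin mass
.sweep_loglik_multinomial <- function(s, mu, cfg, driver_ccf, obs) {
  t_obs <- solve_sweep_time(s, cfg$N, driver_ccf)
  n_i <- passenger_frequency(seq_len(cfg$n_model_passengers), t_obs, s, mu)
  pred_bins <- tabulate(ccf_bin(n_i), nbins = 10) + 0.5  # smoothed
  pred <- pred_bins / sum(pred_bins)
  obs_bins <- tabulate(ccf_bin(obs$ccf), nbins = 10)
  sum(obs_bins * log(pred))
}

#' Estimate per-tumor selection strength from the passenger spectrum
#'
#' Grid search over fitness `s` (optionally profiling `mu`): for each `s` the
#' observation time is solved from the driver CCF, the hitch-hiker model
#' predicts the passenger frequency at every rank, and the objective in
#' `config` scores the observed subclonal records. The regime is `NEUTRAL`
#' when `s_hat - 1 < neutral_tol`, `HARD` when `s_hat >= hard_cut`, else
#' `SOFT`.
#'
#' @param ccf_records tibble of per-mutation records (as from
#'   [compute_ccf_table()]) with columns `ccf`, `alt_count`, `ref_count`,
#'   `purity`, `local_cn`.
#' @param driver_ccf observed CCF of the driver mutation, in `(0, 1]`.
#' @param config a [selection_config()].
#' @return An object of class `selection_estimate`: list with `s_hat`,
#'   `mu_hat`, `objective` (criterion value at the optimum), `regime`,
#'   `n_passengers_used`, `flags` (character vector; `"low_n"` marks sparse
#'   subclonal spectra).
#' @export
estimate_selection <- function(ccf_records, driver_ccf,
                               config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  stopifnot(driver_ccf > 0, driver_ccf <= 1)
  at_fixation <- driver_ccf >= 1
  if (at_fixation) driver_ccf <- 1 - 1e-9  # observed CCF 1: at/beyond fixation
  sub <- ccf_records[!is.na(ccf_records$ccf) &
                       ccf_records$ccf <= config$passenger_ccf_max, , drop = FALSE]
  sub <- sub[order(-sub$ccf), , drop = FALSE]
  obs <- tibble::tibble(
    ccf = sub$ccf,
    alt_count = as.integer(round(sub$alt_count)),
    depth = as.integer(round(sub$alt_count + sub$ref_count)),
    purity = sub$purity,
    local_cn = sub$local_cn
  )
  flags <- character(0)
  if (at_fixation) flags <- c(flags, "driver_at_fixation")
  if (nrow(obs) < config$min_passengers) flags <- c(flags, "low_n")
  mean_depth <- config$mean_depth
  if (is.null(mean_depth)) {
    mean_depth <- if (nrow(ccf_records) > 0) {
      as.integer(round(median(ccf_records$alt_count + ccf_records$ref_count,
                              na.rm = TRUE)))
    } else 200L
  }
  if (config$objective == "multinomial" && nrow(obs) < config$min_passengers) {
    return(structure(list(s_hat = NA_real_, mu_hat = config$mu,
                          objective = NA_real_, regime = NA_character_,
                          n_passengers_used = nrow(obs), flags = flags),
                     class = "selection_estimate"))
  }
  mu_values <- if (is.null(config$mu_grid)) config$mu else config$mu_grid
  best <- list(ll = -Inf, s = NA_real_, mu = NA_real_)
  for (mu in mu_values) {
    ll <- vapply(config$s_grid, function(s) {
      if (mu > s) return(-Inf)
      if (config$objective == "censored_binomial") {
        .sweep_loglik(s, mu, config, driver_ccf, obs, mean_depth)
      } else {
        .sweep_loglik_multinomial(s, mu, config, driver_ccf, obs)
      }
    }, numeric(1))
    k <- which.max(ll)
    if (ll[k] > best$ll) best <- list(ll = ll[k], s = config$s_grid[k], mu = mu)
  }
  s_hat <- best$s
  regime <- if (is.na(s_hat)) NA_character_
  else if (s_hat - 1 < config$neutral_tol) "NEUTRAL"
  else if (s_hat >= config$hard_cut) "HARD"
  else "SOFT"
  structure(list(s_hat = s_hat, mu_hat = best$mu, objective = best$ll,
                 regime = regime, n_passengers_used = nrow(obs),
                 flags = flags),
            class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf("<selection_estimate> s_hat = %.3f (mu = %.3g), regime %s, %d subclonal mutation(s) used%s\n",
              x$s_hat, x$mu_hat, x$regime, x$n_passengers_used,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}
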