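# Synthetic tumors, cohorts, clone trees and expression matrices with the
# statistical structure the analysis assumes.
#
# Read-count model: per-locus depth is Poisson(mean_depth) and the alt count
# is Binomial(depth, expected VAF) with
#   expected VAF = purity * ccf * m / (purity * cn + 2 * (1 - purity)).
# Only mutations reaching the detection threshold (alt reads >= min_alt) are
# emitted in the mutation table, as a variant caller would; the truth table
# records every generated locus with a `detected` flag.

#' Configuration for [simulate_tumor()]
#'
#' Defaults mirror the study conditions of the sweep model: hard sweeps at
#' fitness 2.0, soft sweeps at 1.1, hitch-hiker mutation rate 0.001 per
#' generation, populations of 1e6 cells, and exome-like sequencing at mean
#' depth 200.
#'
#' @param regime `"HARD"`, `"SOFT"`, `"NEUTRAL"` or `"SUBCLONAL_DRIVER"`.
#' @param s fitness of the driver subclone; defaults to 2.0 (HARD), 1.1
#'   (SOFT), 1.0 otherwise.
#' @param mu neutral mutation rate on the sweeping clone (default 0.001).
#' @param N population size in cells (default 1e6).
#' @param purity tumor purity (default 0.8).
#' @param mean_depth mean sequencing depth (default 200).
#' @param n_background_mutations number of background (hitch-hiker or
#'   neutral subclonal) loci generated (default 150).
#' @param n_clonal_mutations number of truncal clonal loci (CCF 1, one
#'   variant copy, diploid), present in every regime (default 25).
#' @param driver_multiplicity variant copies per cancer cell at the driver
#'   locus (default 1).
#' @param local_cn_at_driver total copy number at the driver locus (default 2).
#' @param stop_at_driver_ccf driver CCF at observation for swept regimes
#'   (default 0.99).
#' @param detection_min_alt minimum alt reads for a locus to be reported in
#'   the mutation table (default 2).
#' @param neutral_ccf_floor,neutral_ccf_max range of the 1/f-shaped neutral
#'   subclonal spectrum (defaults 0.05 and 0.4): the floor mirrors the
#'   practical detection limit of bulk exomes, the cap keeps neutral tails
#'   below the clonal range.
#' @param seed integer seed; the generator is a pure function of the seed.
#' @return A list of class `sim_tumor_config`.
#' @export
sim_tumor_config <- function(regime = c("HARD", "SOFT", "NEUTRAL", "SUBCLONAL_DRIVER"),
                             s = NULL, mu = 1e-3, N = 1e6, purity = 0.8,
                             mean_depth = 200, n_background_mutations = 150,
                             n_clonal_mutations = 25, driver_multiplicity = 1,
                             local_cn_at_driver = 2, stop_at_driver_ccf = 0.99,
                             detection_min_alt = 2, neutral_ccf_floor = 0.05,
                             neutral_ccf_max = 0.4, seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(s)) {
    s <- switch(regime, HARD = 2.0, SOFT = 1.1, NEUTRAL = 1.0, SUBCLONAL_DRIVER = 1.0)
  }
  stopifnot(purity > 0, purity <= 1, mean_depth > 0,
            driver_multiplicity >= 1,
            driver_multiplicity <= local_cn_at_driver)
  structure(list(regime = regime, s = s, mu = mu, N = N, purity = purity,
                 mean_depth = mean_depth,
                 n_background_mutations = n_background_mutations,
                 n_clonal_mutations = n_clonal_mutations,
                 driver_multiplicity = driver_multiplicity,
                 local_cn_at_driver = local_cn_at_driver,
                 stop_at_driver_ccf = stop_at_driver_ccf,
                 detection_min_alt = detection_min_alt,
                 neutral_ccf_floor = neutral_ccf_floor,
                 neutral_ccf_max = neutral_ccf_max,
                 seed = as.integer(seed)),
            class = "sim_tumor_config")
}

#' Simulate one bulk tumor with known truth
#'
#' The driver CCF follows the regime (swept regimes stop at
#' `stop_at_driver_ccf`; `NEUTRAL` carries a truncal driver at CCF 1;
#' `SUBCLONAL_DRIVER` draws the driver CCF uniformly in (0.1, 0.6)).
#' Background loci are hitch-hikers from [simulate_sweep_spectrum()] in the
#' swept regimes and a 1/f-shaped subclonal spectrum (truncated at the
#' detection floor) otherwise. Truncal clonal loci are added in every
#' regime. Read counts follow the Poisson/binomial model above; SEG records
#' are emitted consistent with each locus's copy number, and the driver
#' locus sits on chromosome 7.
#'
#' @param config a [sim_tumor_config()].
#' @param sample_id sample identifier (default derived from the seed).
#' @return A list of class `sim_tumor` with elements `sample` (a
#'   [assemble_tumor_sample()] object) and `truth` (list: `mutations` tibble
#'   of every generated locus with true CCF/multiplicity/copy number and a
#'   `detected` flag, plus `s`, `regime`, `purity`).
#' @export
simulate_tumor <- function(config, sample_id = NULL) {
  stopifnot(inherits(config, "sim_tumor_config"))
  set.seed(config$seed)
  if (is.null(sample_id)) sample_id <- sprintf("SIM%06d", config$seed %% 1000000L)

  # -- true per-locus architecture ------------------------------------------
  driver_ccf <- switch(config$regime,
    HARD = config$stop_at_driver_ccf,
    SOFT = config$stop_at_driver_ccf,
    NEUTRAL = 1.0,
    SUBCLONAL_DRIVER = runif(1, 0.1, 0.6)
  )
  nb <- config$n_background_mutations
  if (config$regime %in% c("HARD", "SOFT")) {
    spec <- simulate_sweep_spectrum(
      sweep_params(s = config$s, N = config$N, mu = config$mu),
      n_passengers = nb, stop_at_driver_ccf = config$stop_at_driver_ccf
    )
    background_ccf <- spec$passenger_freqs
  } else {
    u <- runif(nb)
    background_ccf <- config$neutral_ccf_floor *
      (config$neutral_ccf_max / config$neutral_ccf_floor)^u
  }

  ccf <- c(driver_ccf, rep(1, config$n_clonal_mutations), background_ccf)
  m <- c(config$driver_multiplicity, rep(1L, config$n_clonal_mutations + nb))
  cn <- c(config$local_cn_at_driver, rep(2L, config$n_clonal_mutations + nb))
  is_driver <- c(TRUE, rep(FALSE, config$n_clonal_mutations + nb))
  n <- length(ccf)

  # -- reads ----------------------------------------------------------------
  p <- config$purity
  evaf <- p * ccf * m / (p * cn + 2 * (1 - p))
  if (any(evaf > 1 + 1e-12)) {
    stop("configuration implies an expected VAF above 1 (ccf * multiplicity too large for the locus)")
  }
  depth <- rpois(n, config$mean_depth)
  alt_reads <- rbinom(n, depth, pmin(evaf, 1))
  detected <- alt_reads >= config$detection_min_alt

  # -- genomic layout: driver on chr7, everything else spread over chr1 -----
  chrom <- c("7", rep("1", n - 1))
  pos <- c(140753336L, sort(sample.int(2e8L, n - 1)))
  gene <- c("BRAF", sprintf("G%04d", seq_len(n - 1)))

  mutations <- tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = pos,
    ref = "A", alt = "T", gene = gene,
    alt_count = as.numeric(alt_reads), ref_count = as.numeric(depth - alt_reads),
    vaf = ifelse(depth > 0, alt_reads / depth, NA_real_)
  )[detected, , drop = FALSE]

  segments <- tibble::tibble(
    sample_id = sample_id,
    chrom = c("1", "7"),
    start = c(1L, 140000000L),
    end = c(200000000L, 141000000L),
    num_probes = NA_real_,
    seg_mean = c(0, log2(config$local_cn_at_driver / 2)),
    ccf_cnv = 1.0
  )

  truth <- list(
    mutations = tibble::tibble(
      sample_id = sample_id, chrom = chrom, pos = pos, gene = gene,
      is_driver = is_driver, true_ccf = ccf, true_multiplicity = m,
      true_cn = cn, expected_vaf = evaf, depth = depth,
      alt_count = alt_reads, detected = detected
    ),
    s = config$s, regime = config$regime, purity = p
  )

  structure(
    list(sample = assemble_tumor_sample(mutations, segments, p, sample_id,
                                        cancer_type = "SIM"),
         truth = truth, config = config),
    class = "sim_tumor"
  )
}

# deterministic master-seed -> per-tumor-seed splitting
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) + 99991 * as.numeric(k)) %% 2147483647) + 1L
}

#' Simulate a cohort of tumors
#'
#' Tumors are independent; each draws its own seed from the master seed with
#' a fixed splitting scheme (`(seed + 99991 * k) mod (2^31 - 1) + 1`), so
#' cohorts are reproducible and stable under partial regeneration.
#'
#' @param n_per_regime named integer vector, e.g.
#'   `c(HARD = 50, SOFT = 50)`; names are regimes.
#' @param base_config a [sim_tumor_config()] whose regime-independent fields
#'   are shared by all tumors.
#' @param seed master seed.
#' @param config_overrides optional named list mapping a regime to a list of
#'   `sim_tumor_config()` fields overriding `base_config` for that regime
#'   (e.g. gained driver loci for hard-swept tumors).
#' @return A list of `sim_tumor` objects, with a `regimes` attribute.
#' @export
simulate_cohort <- function(n_per_regime, base_config = sim_tumor_config(),
                            seed = 1L, config_overrides = NULL) {
  stopifnot(!is.null(names(n_per_regime)), all(n_per_regime >= 1))
  out <- list()
  k <- 0L
  for (regime in names(n_per_regime)) {
    fields <- unclass(base_config)
    fields$regime <- regime
    fields$s <- NULL  # regime default unless overridden
    if (!is.null(config_overrides[[regime]])) {
      fields[names(config_overrides[[regime]])] <- config_overrides[[regime]]
    }
    for (j in seq_len(n_per_regime[[regime]])) {
      k <- k + 1L
      fields$seed <- derive_seed(seed, k)
      cfg <- do.call(sim_tumor_config, fields)
      out[[k]] <- simulate_tumor(cfg, sample_id = sprintf("S%04d", k))
    }
  }
  attr(out, "regimes") <- vapply(out, function(t) t$truth$regime, character(1))
  out
}

#' Simulate clone trees
#'
#' Fixture-grade rooted trees with valid prevalences (children never exceed
#' their parent and siblings share the parent's mass).
#'
#' @param topology `"CHAIN"`, `"STAR"` or `"RANDOM"` (uniform parent
#'   assignment).
#' @param n_nodes number of nodes, >= 1.
#' @param mutation_counts per-node mutation counts (recycled); default draws
#'   `rpois(lambda = 5) + 1`.
#' @param n_trees number of trees to generate.
#' @param seed optional seed.
#' @return A list of `clone_tree` objects.
#' @export
simulate_clone_trees <- function(topology = c("CHAIN", "STAR", "RANDOM"),
                                 n_nodes, mutation_counts = NULL, n_trees = 1,
                                 seed = NULL) {
  topology <- match.arg(topology)
  stopifnot(n_nodes >= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_trees), function(b) {
    parent <- rep(NA_integer_, n_nodes)
    if (n_nodes > 1) {
      parent[-1] <- switch(topology,
        CHAIN = seq_len(n_nodes - 1),
        STAR = rep(1L, n_nodes - 1),
        RANDOM = vapply(2:n_nodes, function(i) {
          sample.int(i - 1L, 1)
        }, integer(1))
      )
    }
    muts <- if (is.null(mutation_counts)) rpois(n_nodes, 5) + 1L
            else rep_len(as.integer(mutation_counts), n_nodes)
    prevalence <- numeric(n_nodes)
    prevalence[1] <- 1
    if (n_nodes > 1) {
      for (i in 2:n_nodes) {
        sibs <- sum(parent == parent[i], na.rm = TRUE)
        prevalence[i] <- prevalence[parent[i]] * runif(1, 0.3, 0.9) / sibs
      }
    }
    clone_tree(tibble::tibble(node_id = seq_len(n_nodes), parent_id = parent,
                              n_mutations = muts, prevalence = prevalence))
  })
}

#' Simulate an expression matrix with planted up/down signature structure
#'
#' Gaussian noise genes plus planted signal: in the "high" class the up genes
#' are shifted by `+effect_size` SD and the down genes by `-effect_size` SD.
#'
#' @param n_up,n_down,n_noise gene counts (>= 1).
#' @param n_samples_per_class samples per class.
#' @param effect_size shift in within-gene SD units (default 2).
#' @param seed integer seed.
#' @return A list with `matrix` (genes x samples, log scale) and `truth`
#'   (list: `up_genes`, `down_genes`, `noise_genes`, `high_samples`,
#'   `low_samples`).
#' @export
simulate_expression <- function(n_up = 20, n_down = 20, n_noise = 160,
                                n_samples_per_class = 20, effect_size = 2,
                                seed = 1L) {
  stopifnot(n_up >= 1, n_down >= 1, n_noise >= 1, n_samples_per_class >= 2)
  set.seed(seed)
  genes <- c(sprintf("UP%03d", seq_len(n_up)),
             sprintf("DN%03d", seq_len(n_down)),
             sprintf("NS%03d", seq_len(n_noise)))
  samples <- c(sprintf("HI%03d", seq_len(n_samples_per_class)),
               sprintf("LO%03d", seq_len(n_samples_per_class)))
  mat <- matrix(rnorm(length(genes) * length(samples)),
                nrow = length(genes), dimnames = list(genes, samples))
  hi <- seq_len(n_samples_per_class)
  mat[seq_len(n_up), hi] <- mat[seq_len(n_up), hi] + effect_size
  mat[n_up + seq_len(n_down), hi] <- mat[n_up + seq_len(n_down), hi] - effect_size
  list(matrix = mat,
       truth = list(up_genes = genes[seq_len(n_up)],
                    down_genes = genes[n_up + seq_len(n_down)],
                    noise_genes = genes[n_up + n_down + seq_len(n_noise)],
                    high_samples = samples[hi],
                    low_samples = samples[-hi]))
}
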