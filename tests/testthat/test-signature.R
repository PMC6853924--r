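test_that("normalization centers on the median and scales by the SD", {
  mat <- rbind(g1 = c(0, 1, 2), g2 = c(5, 5, 5))
  norm <- normalize_expression(mat)
  expect_equal(unname(norm["g1", ]), c(-1, 0, 1))
  expect_equal(unname(norm["g2", ]), c(0, 0, 0))
  expect_equal(attr(norm, "zero_sd_genes"), "g2")
  # row medians of non-flagged genes are 0 after normalization
  set.seed(2)
  m <- matrix(rnorm(200), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  expect_lt(max(abs(apply(normalize_expression(m), 1, median))), 1e-12)
  expect_error(normalize_expression(m[, 1:2, drop = FALSE]), "at least 3")
})

test_that("variable-gene ranking finds planted signal and demotes constants", {
  set.seed(3)
  m <- matrix(rnorm(300), nrow = 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  m["g01", ] <- m["g01", ] * 6      # planted high-dispersion gene
  m["g30", ] <- 2                   # constant gene
  ranked <- select_variable_genes(m, 30)
  expect_equal(ranked[1], "g01")
  expect_equal(ranked[30], "g30")
  expect_warning(all_genes <- select_variable_genes(m, 99), "exceeds")
  expect_length(all_genes, 30)
  # on a planted matrix most of the top-20 are signal genes
  sim <- simulate_expression(n_up = 10, n_down = 10, n_noise = 180,
                             n_samples_per_class = 20, effect_size = 2, seed = 41)
  top20 <- select_variable_genes(sim$matrix, 20)
  signal <- c(sim$truth$up_genes, sim$truth$down_genes)
  expect_gte(sum(top20 %in% signal), 18)
})

test_that("pruning recovers planted anticorrelated blocks and drops noise first", {
  sim <- simulate_expression(n_up = 15, n_down = 15, n_noise = 170,
                             n_samples_per_class = 20, effect_size = 2, seed = 27)
  norm <- normalize_expression(sim$matrix)
  cand <- select_variable_genes(sim$matrix, 40)
  sig <- prune_signature(norm, cand)
  expect_gte(partition_accuracy(sig, sim$truth$up_genes, sim$truth$down_genes), 0.9)
  expect_false(any(c(sig$up_genes, sig$down_genes) %in% sim$truth$noise_genes))

  # target size equal to candidate count is the identity on membership
  sig_all <- prune_signature(norm, cand, target_size = length(cand))
  expect_setequal(c(sig_all$up_genes, sig_all$down_genes), cand)

  # with all-signal candidates, an injected pure-noise gene is pruned first
  cand2 <- c(sim$truth$up_genes, sim$truth$down_genes, sim$truth$noise_genes[1])
  sig2 <- prune_signature(norm, cand2, target_size = length(cand2) - 1)
  expect_false(sim$truth$noise_genes[1] %in% c(sig2$up_genes, sig2$down_genes))
})

test_that("scores separate planted classes and are exactly antisymmetric", {
  sim <- simulate_expression(n_up = 20, n_down = 20, n_noise = 160,
                             n_samples_per_class = 20, effect_size = 2, seed = 5)
  norm <- normalize_expression(sim$matrix)
  sig <- structure(list(up_genes = sim$truth$up_genes,
                        down_genes = sim$truth$down_genes),
                   class = "gene_signature")
  sc <- score_samples(norm, sig)
  hi <- sc$score[sc$sample_id %in% sim$truth$high_samples]
  lo <- sc$score[sc$sample_id %in% sim$truth$low_samples]
  expect_gte(mean(outer(hi, lo, ">")), 0.95)

  swapped <- sig
  swapped$up_genes <- sig$down_genes
  swapped$down_genes <- sig$up_genes
  expect_equal(score_samples(norm, swapped)$score, -sc$score)
})

test_that("scores are invariant to a per-sample additive shift", {
  sim <- simulate_expression(seed = 13)
  sig <- structure(list(up_genes = sim$truth$up_genes,
                        down_genes = sim$truth$down_genes),
                   class = "gene_signature")
  shifted <- sweep(sim$matrix, 2, rnorm(ncol(sim$matrix), 0, 5), "+")
  expect_equal(score_samples(shifted, sig)$score,
               score_samples(sim$matrix, sig)$score)
})

test_that("missing signature genes are dropped with a warning", {
  sim <- simulate_expression(seed = 14)
  sig <- structure(list(up_genes = c(sim$truth$up_genes, "ABSENT1"),
                        down_genes = sim$truth$down_genes),
                   class = "gene_signature")
  expect_warning(sc <- score_samples(sim$matrix, sig), "ABSENT1")
  expect_equal(nrow(sc), ncol(sim$matrix))
})

test_that("null effect sizes leave classes statistically indistinguishable", {
  pvals <- vapply(1:20, function(b) {
    sim <- simulate_expression(n_up = 10, n_down = 10, n_noise = 30,
                               n_samples_per_class = 10, effect_size = 0,
                               seed = 500 + b)
    sig <- structure(list(up_genes = sim$truth$up_genes,
                          down_genes = sim$truth$down_genes),
                     class = "gene_signature")
    sc <- score_samples(sim$matrix, sig)
    hi <- sc$score[sc$sample_id %in% sim$truth$high_samples]
    lo <- sc$score[sc$sample_id %in% sim$truth$low_samples]
    wilcox.test(hi, lo)$p.value
  }, numeric(1))
  expect_gt(mean(pvals), 0.01)
})

test_that("signatures round-trip through JSON", {
  sim <- simulate_expression(seed = 15)
  norm <- normalize_expression(sim$matrix)
  sig <- prune_signature(norm, select_variable_genes(sim$matrix, 30))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sig.json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$up_genes, sig$up_genes)
  expect_equal(back$down_genes, sig$down_genes)
  expect_equal(back$per_gene_center, sig$per_gene_center)
})
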