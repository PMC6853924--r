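test_that("diversity index matches closed-form entropies", {
  expect_equal(diversity_index(rep(0.55, 40))$h, 0)
  expect_equal(diversity_index(seq(0.05, 0.95, by = 0.1))$h, log(10))
  d <- diversity_index(c(rep(0.05, 50), rep(0.97, 50)))
  expect_equal(d$h, log(2))
  expect_equal(d$bin_counts, c(50, 0, 0, 0, 0, 0, 0, 0, 0, 50))
  # CCF = 1 occupies the top (closed) bin; 0.1 belongs to bin 2
  expect_equal(diversity_index(c(1, 1))$bin_counts[10], 2)
  expect_equal(diversity_index(0.1)$bin_counts[2], 1)
  expect_error(diversity_index(numeric(0)), "non-empty")
})

test_that("diversity index is permutation-invariant and sample-size free", {
  set.seed(12)
  x <- runif(200)
  expect_equal(diversity_index(sample(x))$h, diversity_index(x)$h)
  expect_equal(diversity_index(rep(x, 5))$h, diversity_index(x)$h)
})

test_that("median CCF follows the even-n convention", {
  expect_equal(median_ccf(c(0.2, 0.5, 0.9)), 0.5)
  expect_equal(median_ccf(c(0.2, 0.4)), 0.3)
  expect_error(median_ccf(numeric(0)), "non-empty")
})

test_that("best tree takes the lowest normalized log likelihood with tie-breaks", {
  trees <- simulate_clone_trees("RANDOM", 4, n_trees = 3, seed = 15)
  trees <- Map(function(tr, ll) { tr$log_likelihood <- ll; tr },
               trees, c(-3, -5, -3))
  expect_equal(best_tree(trees)$log_likelihood, -5)
  expect_equal(best_tree(trees, best = "highest")$log_likelihood, -3)
  # ties break toward fewer nodes
  t3 <- simulate_clone_trees("CHAIN", 3, n_trees = 1, seed = 1)[[1]]
  t5 <- simulate_clone_trees("CHAIN", 5, n_trees = 1, seed = 1)[[1]]
  t3$log_likelihood <- -7; t5$log_likelihood <- -7
  expect_equal(nrow(best_tree(list(t5, t3))$nodes), 3)
  # no likelihoods: first tree, with a warning
  t5$log_likelihood <- NA_real_; t3$log_likelihood <- NA_real_
  expect_warning(bt <- best_tree(list(t5, t3)), "no tree carries")
  expect_equal(nrow(bt$nodes), 5)
})

test_that("tree indices: chain, star and the counted example", {
  chain <- simulate_clone_trees("CHAIN", 3, mutation_counts = c(2, 3, 4))[[1]]
  ci <- tree_indices(chain)
  expect_equal(ci$linearity, 1)
  expect_equal(ci$branching, 0)

  star <- clone_tree(tibble::tibble(node_id = 1:3, parent_id = c(NA, 1, 1),
                                    n_mutations = c(0, 3, 5),
                                    prevalence = c(1, 0.4, 0.4)))
  si <- tree_indices(star)
  expect_equal(si$linearity, 0)
  expect_equal(si$branching, 1)

  # root(2) -> {A(3), B(5)}: linear 2*3 + 2*5 = 16, branched 3*5 = 15
  t <- clone_tree(tibble::tibble(node_id = 1:3, parent_id = c(NA, 1, 1),
                                 n_mutations = c(2, 3, 5),
                                 prevalence = c(1, 0.5, 0.4)))
  ti <- tree_indices(t)
  expect_equal(ti$linearity, 16 / 31)
  expect_equal(ti$branching, 15 / 31)

  # single mutation-bearing node is degenerate
  lone <- clone_tree(tibble::tibble(node_id = 1, parent_id = NA,
                                    n_mutations = 9, prevalence = 1))
  expect_true(tree_indices(lone)$degenerate)
})

test_that("tree indices equal brute-force pair enumeration on random trees", {
  set.seed(33)
  for (b in 1:100) {
    n <- sample(2:8, 1)
    tr <- simulate_clone_trees("RANDOM", n,
                               mutation_counts = sample(0:4, n, replace = TRUE),
                               seed = 1000 + b)[[1]]
    got <- tree_indices(tr)
    want <- oracle_tree_indices(tr)
    expect_equal(got$linearity, want$linearity)
    expect_equal(got$branching, want$branching)
  }
})

test_that("averaged indices reduce correctly", {
  chain <- simulate_clone_trees("CHAIN", 4, mutation_counts = 2)[[1]]
  star <- clone_tree(tibble::tibble(node_id = 1:4, parent_id = c(NA, 1, 1, 1),
                                    n_mutations = c(0, 2, 2, 2),
                                    prevalence = c(1, 0.3, 0.3, 0.3)))
  chain$log_likelihood <- -1; star$log_likelihood <- -2
  avg <- averaged_tree_indices(list(chain, star), top_k = 2)
  expect_equal(avg$linearity, 0.5)
  expect_equal(avg$branching, 0.5)
  expect_equal(averaged_tree_indices(list(chain, chain))$linearity, 1)
  # top_k = 1 equals the best tree's own indices (lowest log likelihood = star)
  expect_equal(averaged_tree_indices(list(chain, star), top_k = 1)$branching, 1)
})

test_that("association fits exact lines and flags degenerate predictors", {
  x <- 1:10
  a <- suppressWarnings(architecture_association(x, 2 * x))  # perfect-fit note
  expect_equal(a$slope, 2)
  expect_equal(a$intercept, 0)
  expect_lt(a$p_value, 1e-10)
  expect_true(architecture_association(rep(1, 5), rnorm(5))$degenerate)
  # permuted pairing has near-zero slope on average
  set.seed(9)
  slopes <- replicate(200, {
    y <- 3 * x + rnorm(10)
    architecture_association(sample(x), y)$slope
  })
  expect_lt(abs(mean(slopes)), 0.3)
})

test_that("hard-swept cohorts collapse diversity relative to neutral cohorts", {
  cohort <- simulate_cohort(c(HARD = 10, NEUTRAL = 10), seed = 19)
  h <- vapply(cohort, function(t) {
    diversity_index(compute_ccf_table(t$sample)$ccf)$h
  }, numeric(1))
  med <- vapply(cohort, function(t) {
    median_ccf(compute_ccf_table(t$sample)$ccf)
  }, numeric(1))
  regime <- attr(cohort, "regimes")
  expect_lt(mean(h[regime == "HARD"]), mean(h[regime == "NEUTRAL"]))
  expect_gt(mean(med[regime == "HARD"]), mean(med[regime == "NEUTRAL"]))
})
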