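test_that("rmse and normalized error follow their definitions", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 50, 100), c(10, 50, 90)), sqrt(200 / 3))
  expect_equal(rmse(3, 7), 4)
  expect_error(rmse(1:3, 1:2), "equal length")
  expect_error(rmse(numeric(0), numeric(0)), "empty")

  expect_equal(normalized_error(10, 0, 100), 0.1)
  expect_equal(normalized_error(0, 0, 100), 0)
  expect_equal(normalized_error(100, 0, 100), 1)
  expect_error(normalized_error(1, 5, 5), "degenerate")
  expect_error(normalized_error(-1, 0, 1))
})

test_that("per-user correlations handle undefined cases as missing", {
  preds <- c(1, 2, 3, 5, 9)
  truth <- c(1, 2, 3, 4, 2)
  users <- c("a", "a", "a", "b", "c")
  r <- per_user_correlation(preds, truth, users)
  expect_equal(r[["a"]], 1.0)
  expect_true(is.na(r[["b"]]))  # single cell
  expect_true(is.na(r[["c"]]))

  const <- per_user_correlation(c(1, 1), c(2, 3), c("a", "a"))
  expect_true(is.na(const[["a"]]))

  # random instance vs a brute-force loop
  set.seed(2)
  p <- rnorm(60); t <- rnorm(60); u <- sample(letters[1:6], 60, TRUE)
  r2 <- per_user_correlation(p, t, u)
  for (uu in unique(u)) expect_equal(r2[[uu]], cor(p[u == uu], t[u == uu]))
})

test_that("a perfect oracle algorithm scores zero error at every sparsity", {
  m <- gen_subgroup_decisions(n_users = 12, n_items = 15, seed = 2)
  ev <- cross_validate(m, list(oracle = make_oracle_algorithm(m)),
                       sparsity_levels = c(0.2, 0.6), n_iterations = 2,
                       base_seed = 3)
  expect_true(all(ev$normalized_error == 0))
  pc <- ev$pred_truth_correlation
  expect_true(all(is.na(pc) | abs(pc - 1) < 1e-12))
})

test_that("a constant matrix gives the mean model zero error", {
  v <- matrix(42, 6, 8) + 0  # constant ratings
  m <- ratings_matrix(v, scale = c(0, 100))
  ev <- cross_validate(m, "mean", sparsity_levels = 0.5, n_iterations = 2,
                       base_seed = 1)
  expect_true(all(ev$normalized_error == 0))
})

test_that("split sizes, pairing and seed discipline hold across the sweep", {
  m <- random_ratings(20, 30, frac_missing = 0, seed = 4, scale = c(0, 100))
  ev <- cross_validate(m, c("mean", "knn"), sparsity_levels = 0.4,
                       n_iterations = 3, base_seed = 5)
  per_run <- tapply(ev$n_test, list(ev$algorithm, ev$iteration), sum)
  expect_true(all(per_run == 240))  # 0.4 * 600 cells, shared by algorithms

  ev2 <- cross_validate(m, c("mean", "knn"), sparsity_levels = 0.4,
                        n_iterations = 3, base_seed = 5)
  expect_identical(as.data.frame(ev), as.data.frame(ev2))
})

test_that("per-user aggregation matches a hand-rolled two-stage average", {
  m <- gen_normed_images(n_users = 10, n_items = 12, seed = 6)
  ev <- cross_validate(m, "mean", sparsity_levels = 0.5, n_iterations = 4,
                       base_seed = 7)
  agg <- aggregate_evaluation(ev, n_boot = 0)
  # oracle: average each user's iterations first, then across users
  by_user <- tapply(ev$normalized_error, ev$user, mean)
  expect_equal(agg$normalized_error, mean(by_user))

  # bootstrap CI brackets the point estimate and is seeded
  a1 <- aggregate_evaluation(ev, n_boot = 200, seed = 1)
  a2 <- aggregate_evaluation(ev, n_boot = 200, seed = 1)
  expect_identical(a1, a2)
  expect_lt(a1$ci_lower, a1$normalized_error)
  expect_gt(a1$ci_upper, a1$normalized_error)
})

test_that("normalized error stays in [0, 1] for the mean model", {
  m <- gen_subgroup_decisions(n_users = 15, n_items = 15, seed = 8)
  ev <- cross_validate(m, "mean", sparsity_levels = c(0.1, 0.9),
                       n_iterations = 2, base_seed = 9)
  expect_true(all(ev$normalized_error >= 0))
  expect_true(all(ev$normalized_error <= 1))
})

test_that("algorithm failures are recorded with diagnostics, not dropped", {
  boom <- function(train, cells, seed) stop("deliberate failure")
  m <- gen_normed_images(n_users = 8, n_items = 8, seed = 10)
  ev <- cross_validate(m, list(mean = list(algorithm = "mean"), boom = boom),
                       sparsity_levels = 0.5, n_iterations = 2, base_seed = 11)
  fails <- attr(ev, "failures")
  expect_equal(nrow(fails), 2L)
  expect_match(fails$message[1], "deliberate failure")
  expect_true(all(ev$failed[ev$algorithm == "boom"]))
  expect_false(any(ev$failed[ev$algorithm == "mean"]))
  agg <- aggregate_evaluation(ev, n_boot = 0)
  expect_equal(agg$n_failed[agg$algorithm == "boom"], 2L)
})

test_that("poisoned test cells never reach any training state in the harness", {
  m <- gen_affect_timeseries(n_users = 6, n_items = 60, seed = 12)
  # recorder hook: captures every train matrix the harness hands to a model,
  # including dilated variants
  run <- function(mat) {
    store <- new.env()
    store$seen <- list()
    hook <- function(train, cells, seed) {
      store$seen <- c(store$seen, list(train$values))
      mean_predict(train, cells)
    }
    cross_validate(mat, list(probe = hook), sparsity_levels = 0.8,
                   n_iterations = 1, dilation_widths_s = c(0, 5),
                   base_seed = 13)
    store$seen
  }
  split <- mask_random(m, 0.8, seed = cfimpute:::derive_seed(13, 1, 1))
  clean_seen <- run(m)
  sentinel <- m
  sentinel$values[split$test] <- 1e9
  sentinel$scale <- NULL
  dirty_seen <- run(sentinel)
  expect_gt(length(clean_seen), 1L)
  expect_identical(clean_seen, dirty_seen)

  # direct model-level contract on the same split
  poisoned <- m
  poisoned$values[split$test] <- 1e9
  poisoned$scale <- NULL
  tr_clean <- train_matrix(m, split)
  tr_dirty <- train_matrix(poisoned, split)
  expect_identical(tr_clean$values, tr_dirty$values)
  d_clean <- dilate(tr_clean, split$train, boxcar_kernel(5))
  d_dirty <- dilate(tr_dirty, split$train, boxcar_kernel(5))
  expect_identical(d_clean$values, d_dirty$values)
  cells <- which(split$test, arr.ind = TRUE)
  for (alg in list(function(tr) mean_predict(tr, cells),
                   function(tr) predict(knn_fit(tr, k = 10), cells),
                   function(tr) predict(nnmf_sgd(tr, max_iter = 30, seed = 1),
                                        cells))) {
    expect_identical(alg(d_clean)$value, alg(d_dirty)$value)
  }
})

test_that("evaluation tables export with a failure sidecar", {
  m <- gen_normed_images(n_users = 8, n_items = 8, seed = 14)
  ev <- cross_validate(m, "mean", sparsity_levels = 0.5, n_iterations = 1,
                       base_seed = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_evaluation_csv(ev, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".meta.json")))
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(ev))
})
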