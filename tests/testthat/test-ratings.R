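test_that("from_long pivots records, averages duplicates, rejects bad input", {
  df <- data.frame(user = c("A", "A", "B"), item = c("i1", "i2", "i1"),
                   rating = c(1, 2, 3))
  m <- from_long(df)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m$values["A", "i1"], 1)
  expect_equal(m$values["A", "i2"], 2)
  expect_equal(m$values["B", "i1"], 3)
  expect_true(is.na(m$values["B", "i2"]))

  dup <- data.frame(user = c("A", "A"), item = c("i1", "i1"), rating = c(1, 3))
  expect_equal(from_long(dup)$values[1, 1], 2)

  expect_error(from_long(data.frame()), "non-empty")
  bad <- data.frame(user = "A", item = "i1", rating = NaN)
  expect_error(from_long(bad), "i1")
})

test_that("to_long emits row-major records and round-trips with from_long", {
  v <- rbind(u0 = c(1, NA), u1 = c(3, 4))
  colnames(v) <- c("i0", "i1")
  out <- to_long(ratings_matrix(v))
  expect_equal(out$user, c("u0", "u1", "u1"))
  expect_equal(out$item, c("i0", "i0", "i1"))
  expect_equal(out$rating, c(1, 3, 4))

  expect_equal(nrow(to_long(ratings_matrix(matrix(1:4 + 0, 2, 2)))), 4L)

  # inverse pair on duplicate-free records
  m <- random_ratings(7, 9, frac_missing = 0.4, seed = 42)
  back <- from_long(to_long(m))
  expect_identical(back$values[rownames(m$values), colnames(m$values)],
                   m$values)
})

test_that("mask_random partitions observed cells at the requested fraction", {
  m <- ratings_matrix(matrix(runif(100), 10, 10))
  s <- mask_random(m, 0.6, seed = 7)
  expect_equal(sum(s$test), 60L)
  expect_equal(sum(s$train), 40L)

  s2 <- mask_random(m, 0.6, seed = 7)
  expect_identical(s$test, s2$test)

  expect_error(mask_random(m, 0, seed = 1), "between 0 and 1")
  expect_error(mask_random(m, 1.2, seed = 1), "between 0 and 1")
})

test_that("masks are disjoint and cover the observed cells for many seeds", {
  m <- random_ratings(8, 13, frac_missing = 0.25, seed = 3)
  obs <- !is.na(m$values)
  for (seed in 0:99) {
    s <- mask_random(m, 0.4, seed = seed)
    expect_false(any(s$train & s$test))
    expect_identical(s$train | s$test, obs)
  }
  # count within rounding of the request
  s <- mask_random(m, 0.37, seed = 5)
  expect_lte(abs(sum(s$test) - 0.37 * sum(obs)), 1)
})

test_that("resample_time averages blocks down and repeats samples up", {
  m <- ratings_matrix(rbind(u1 = c(1, 2, 3, 4)), interval_s = 1)
  down <- resample_time(m, 2, "down")
  expect_equal(unname(down$values[1, ]), c(1.5, 3.5))
  expect_equal(down$interval_s, 2)

  expect_identical(resample_time(m, 1, "down"), m)
  expect_identical(resample_time(m, 1, "up"), m)

  gap <- ratings_matrix(rbind(u1 = c(1, NA, 3, NA)), interval_s = 1)
  expect_equal(unname(resample_time(gap, 2, "down")$values[1, ]), c(1, 3))

  up <- resample_time(m, 3, "up")
  expect_equal(ncol(up$values), 12L)
  expect_equal(up$interval_s, 1 / 3)
  # down-then-up preserves shape and block means
  back <- resample_time(down, 2, "up")
  expect_equal(dim(back$values), dim(m$values))
  expect_equal(unname(back$values[1, ]), c(1.5, 1.5, 3.5, 3.5))

  no_axis <- ratings_matrix(rbind(u1 = c(1, 2)))
  expect_error(resample_time(no_axis, 2, "down"), "time axis")
})

test_that("ratings_matrix validates scale, shape and emptiness", {
  expect_error(ratings_matrix(matrix(NA_real_, 2, 2)), "non-missing")
  expect_error(ratings_matrix(matrix(c(1, 11), 1, 2), scale = c(0, 10)),
               "outside the declared scale")
  expect_error(ratings_matrix(matrix(1:4 + 0, 2, 2), scale = c(5, 5)))
  m <- ratings_matrix(matrix(c(1, NA, 3, 4), 2, 2), scale = c(0, 10))
  expect_equal(rating_range(m), c(0, 10))
  expect_equal(rating_range(ratings_matrix(matrix(c(1, 4), 1, 2))), c(1, 4))
  expect_equal(n_observed(m), 3L)
})

test_that("long and wide CSV round-trips preserve observed cells", {
  m <- random_ratings(5, 6, frac_missing = 0.3, seed = 11)
  long_path <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(m, long_path)
  back <- read_ratings_csv(long_path)
  expect_equal(back$values[rownames(m$values), colnames(m$values)], m$values)

  wide_path <- withr::local_tempfile(fileext = ".csv")
  write_ratings_wide(m, wide_path)
  wide <- read_ratings_wide(wide_path)
  expect_equal(wide$values, m$values)

  ts <- gen_affect_timeseries(n_users = 3, n_items = 10, seed = 1)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(ts, p2)
  back2 <- read_ratings_csv(p2)
  expect_equal(back2$interval_s, 1)
  expect_equal(back2$values, ts$values)
})
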