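#' Construct a user-by-item ratings matrix
#'
#' The central container of the package: a real-valued `users x items` matrix
#' with explicit missingness (`NA`), an optional declared rating scale, and an
#' optional uniform time axis (items are consecutive time points sampled every
#' `interval_s` seconds).
#'
#' @param values Numeric matrix (rows = users, columns = items). `NA` marks a
#'   missing rating. Row and column names are used as user/item ids; defaults
#'   (`u1..`, `i1..` or `t0..` on a time axis) are supplied when absent.
#' @param scale Optional length-2 numeric `c(r_min, r_max)`. When declared,
#'   every non-missing value must lie inside it; it is used by the normalized
#'   error and by chained-equations clipping.
#' @param interval_s Optional positive number of seconds between consecutive
#'   items. Setting it declares the matrix a time-series (items equally spaced
#'   and ordered).
#' @return An object of class `ratings_matrix`.
#' @examples
#' m <- ratings_matrix(rbind(u1 = c(1, 2), u2 = c(3, NA)), scale = c(0, 10))
#' n_observed(m)
#' @export
ratings_matrix <- function(values, scale = NULL, interval_s = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!any(is.finite(values)))
    stop("ratings matrix must contain at least one non-missing entry")
  if (any(is.infinite(values)))
    stop("ratings must be finite or NA")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("u", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- if (is.null(interval_s)) paste0("i", seq_len(ncol(values)))
                        else paste0("t", seq_len(ncol(values)) - 1L)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("user and item ids must be unique")
  if (!is.null(scale)) {
    if (length(scale) != 2L || !is.numeric(scale) || scale[2] <= scale[1])
      stop("`scale` must be c(r_min, r_max) with r_max > r_min")
    obs <- values[!is.na(values)]
    if (any(obs < scale[1] | obs > scale[2]))
      stop("observed ratings fall outside the declared scale")
  }
  if (!is.null(interval_s)) {
    if (!is.numeric(interval_s) || length(interval_s) != 1L || interval_s <= 0)
      stop("`interval_s` must be a positive number of seconds")
  }
  structure(
    list(values = values, scale = scale, interval_s = interval_s),
    class = "ratings_matrix"
  )
}

#' @export
print.ratings_matrix <- function(x, ...) {
  d <- dim(x$values)
  n_obs <- sum(!is.na(x$values))
  cat(sprintf("<ratings_matrix> %d users x %d items, %d/%d observed (%.1f%%)\n",
              d[1], d[2], n_obs, prod(d), 100 * n_obs / prod(d)))
  if (!is.null(x$scale))
    cat(sprintf("  scale: [%g, %g]\n", x$scale[1], x$scale[2]))
  if (!is.null(x$interval_s))
    cat(sprintf("  time axis: %d samples at %g s intervals\n", d[2], x$interval_s))
  invisible(x)
}

#' @export
dim.ratings_matrix <- function(x) dim(x$values)

#' Number of observed (non-missing) cells
#' @param x A `ratings_matrix`.
#' @return Integer count of non-missing cells.
#' @export
n_observed <- function(x) {
  stopifnot(inherits(x, "ratings_matrix"))
  sum(!is.na(x$values))
}

#' Rating range used for error normalization
#'
#' The declared scale when present, otherwise the observed data range.
#' @param x A `ratings_matrix`.
#' @return Numeric `c(r_min, r_max)`.
#' @export
rating_range <- function(x) {
  stopifnot(inherits(x, "ratings_matrix"))
  if (!is.null(x$scale)) x$scale else range(x$values, na.rm = TRUE)
}

#' Pivot long-form rating records into a ratings matrix
#'
#' Accepts one record per user-item rating, the layout used for data
#' collection where every row is a single judgment. Duplicate (user, item)
#' pairs are averaged (the same reduction applied to repeated-condition
#' decisions when trials share a design cell). User and item order follow
#' first appearance unless a `time_s` column orders the items.
#'
#' @param records Data frame with columns `user`, `item`, `rating`, and
#'   optionally `time_s` (seconds; must map 1:1 onto items and be equally
#'   spaced, in which case the result carries a time axis).
#' @param scale Optional declared rating scale, see [ratings_matrix()].
#' @return A `ratings_matrix`.
#' @examples
#' df <- data.frame(user = c("A", "A", "B"), item = c("i1", "i2", "i1"),
#'                  rating = c(1, 2, 3))
#' from_long(df)
#' @seealso [to_long()] for the inverse operation.
#' @export
from_long <- function(records, scale = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data frame")
  need <- c("user", "item", "rating")
  if (!all(need %in% names(records)))
    stop("`records` must have columns user, item, rating")
  bad <- which(!is.finite(records$rating))
  if (length(bad))
    stop(sprintf("non-finite rating for user '%s', item '%s' (row %d)",
                 records$user[bad[1]], records$item[bad[1]], bad[1]))
  users <- unique(as.character(records$user))
  interval_s <- NULL
  if ("time_s" %in% names(records)) {
    key <- unique(records[, c("item", "time_s")])
    key$item <- as.character(key$item)
    if (anyDuplicated(key$item))
      stop("each item must map to a single time_s value")
    key <- key[order(key$time_s), ]
    items <- key$item
    if (nrow(key) > 1L) {
      steps <- diff(key$time_s)
      if (any(abs(steps - steps[1]) > 1e-9 * max(abs(steps))))
        stop("time_s values must be equally spaced")
      interval_s <- steps[1]
    }
  } else {
    items <- unique(as.character(records$item))
  }
  ui <- match(as.character(records$user), users)
  ii <- match(as.character(records$item), items)
  vals <- matrix(NA_real_, length(users), length(items),
                 dimnames = list(users, items))
  # duplicate (user, item) records are averaged
  fu <- factor(ui, seq_along(users))
  fi <- factor(ii, seq_along(items))
  sums <- tapply(records$rating, list(fu, fi), sum)
  n <- tapply(rep(1L, nrow(records)), list(fu, fi), sum)
  vals[] <- sums / n
  ratings_matrix(vals, scale = scale, interval_s = interval_s)
}

#' Flatten a ratings matrix to long-form records
#'
#' One record per non-missing cell, in row-major (user-by-user) order.
#' Inverse of [from_long()] on duplicate-free input.
#'
#' @param matrix A `ratings_matrix`.
#' @return Data frame with columns `user`, `item`, `rating` and, when the
#'   matrix has a time axis, `time_s`.
#' @export
to_long <- function(matrix) {
  stopifnot(inherits(matrix, "ratings_matrix"))
  v <- matrix$values
  keep <- which(!is.na(t(v)))  # row-major order
  it <- t(v)
  ii <- ((keep - 1L) %% ncol(v)) + 1L
  ui <- ((keep - 1L) %/% ncol(v)) + 1L
  out <- data.frame(
    user = rownames(v)[ui],
    item = colnames(v)[ii],
    rating = it[keep],
    stringsAsFactors = FALSE
  )
  if (!is.null(matrix$interval_s))
    out$time_s <- (ii - 1L) * matrix$interval_s
  out
}

#' Randomly mask observed cells into train/test sets
#'
#' Selects `masked_fraction` of the observed cells uniformly at random over
#' the whole matrix (not stratified per user) as a held-out test set; the
#' remaining observed cells form the training set. At high fractions a user
#' can lose every observed rating, in which case downstream models fall back
#' to their degenerate-prediction rules.
#'
#' @param matrix A `ratings_matrix`.
#' @param masked_fraction Fraction of observed cells to mask, in (0, 1).
#' @param seed Integer seed; identical inputs and seed give identical masks.
#' @return An `observation_split`: list with logical matrices `train` and
#'   `test` (disjoint, jointly covering exactly the observed cells),
#'   `masked_fraction` and `seed`.
#' @examples
#' m <- gen_normed_images(n_users = 10, n_items = 10, seed = 1)
#' s <- mask_random(m, 0.6, seed = 2)
#' sum(s$test)  # 60 of the 100 observed cells
#' @export
mask_random <- function(matrix, masked_fraction, seed) {
  stopifnot(inherits(matrix, "ratings_matrix"))
  if (!is.numeric(masked_fraction) || length(masked_fraction) != 1L ||
      masked_fraction <= 0 || masked_fraction >= 1)
    stop("`masked_fraction` must lie strictly between 0 and 1")
  obs <- which(!is.na(matrix$values))
  if (length(obs) == 0L) stop("matrix has no observed cells")
  n_test <- round(masked_fraction * length(obs))
  test_idx <- with_seed(seed, obs[sample.int(length(obs), n_test)])
  train <- !is.na(matrix$values)
  test <- array(FALSE, dim(matrix$values))
  test[test_idx] <- TRUE
  train[test_idx] <- FALSE
  structure(
    list(train = train, test = test,
         masked_fraction = masked_fraction, seed = as.integer(seed)),
    class = "observation_split"
  )
}

#' @export
print.observation_split <- function(x, ...) {
  cat(sprintf("<observation_split> %d train / %d test cells (%.0f%% masked, seed %d)\n",
              sum(x$train), sum(x$test), 100 * x$masked_fraction, x$seed))
  invisible(x)
}

#' Apply a split: keep training cells, blank everything else
#'
#' @param matrix A `ratings_matrix`.
#' @param split An `observation_split` from [mask_random()].
#' @return A `ratings_matrix` whose non-train cells are missing.
#' @export
train_matrix <- function(matrix, split) {
  stopifnot(inherits(matrix, "ratings_matrix"), inherits(split, "observation_split"))
  v <- matrix$values
  v[!split$train] <- NA_real_
  ratings_matrix(v, scale = matrix$scale, interval_s = matrix$interval_s)
}

#' Temporal resampling of a time-series ratings matrix
#'
#' Downsampling reduces non-overlapping blocks of `factor` consecutive time
#' points to the mean of their non-missing values (an all-missing block stays
#' missing; a shorter trailing block is averaged over the points it has).
#' Upsampling repeats each time point `factor` times. The sample interval is
#' rescaled accordingly.
#'
#' @param matrix A `ratings_matrix` with a time axis.
#' @param factor Integer >= 1.
#' @param direction `"down"` or `"up"`.
#' @return A `ratings_matrix` with the new time axis.
#' @export
resample_time <- function(matrix, factor, direction = c("down", "up")) {
  stopifnot(inherits(matrix, "ratings_matrix"))
  direction <- match.arg(direction)
  if (is.null(matrix$interval_s))
    stop("`matrix` has no time axis; set `interval_s` first")
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(matrix)
  v <- matrix$values
  if (direction == "down") {
    blocks <- split(seq_len(ncol(v)), ceiling(seq_len(ncol(v)) / factor))
    out <- vapply(blocks, function(j) {
      x <- v[, j, drop = FALSE]
      rowMeans(x, na.rm = TRUE)
    }, numeric(nrow(v)))
    if (nrow(v) == 1L) out <- base::matrix(out, nrow = 1L)
    out[is.nan(out)] <- NA_real_
    rownames(out) <- rownames(v)
    colnames(out) <- paste0("t", seq_len(ncol(out)) - 1L)
    ratings_matrix(out, scale = matrix$scale,
                   interval_s = matrix$interval_s * factor)
  } else {
    out <- v[, rep(seq_len(ncol(v)), each = factor), drop = FALSE]
    colnames(out) <- paste0("t", seq_len(ncol(out)) - 1L)
    ratings_matrix(out, scale = matrix$scale,
                   interval_s = matrix$interval_s / factor)
  }
}

#' Read/write long-form rating CSV files
#'
#' Long-form files have a header `user,item,rating` with an optional `time_s`
#' column (UTF-8, `.` decimal separator).
#'
#' @param path File path.
#' @param scale Optional declared scale passed to [from_long()].
#' @return `read_ratings_csv()` returns a `ratings_matrix`;
#'   `write_ratings_csv()` invisibly returns `path`.
#' @export
read_ratings_csv <- function(path, scale = NULL) {
  from_long(read.csv(path, stringsAsFactors = FALSE), scale = scale)
}

#' @rdname read_ratings_csv
#' @param matrix A `ratings_matrix` to write.
#' @export
write_ratings_csv <- function(matrix, path) {
  write.csv(to_long(matrix), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a ratings matrix as wide CSV
#'
#' Wide files have users as rows (first column `user`), items as columns and
#' empty cells for missing ratings.
#'
#' @param path File path.
#' @param scale,interval_s Passed to [ratings_matrix()].
#' @return `read_ratings_wide()` returns a `ratings_matrix`.
#' @export
read_ratings_wide <- function(path, scale = NULL, interval_s = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  users <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- users
  ratings_matrix(v, scale = scale, interval_s = interval_s)
}

#' @rdname read_ratings_wide
#' @param matrix A `ratings_matrix` to write.
#' @export
write_ratings_wide <- function(matrix, path) {
  stopifnot(inherits(matrix, "ratings_matrix"))
  df <- data.frame(user = rownames(matrix$values),
                   matrix$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
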