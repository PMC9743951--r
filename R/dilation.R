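#' Boxcar dilation kernel
#'
#' Converts a kernel width in seconds into an odd number of samples given the
#' matrix's sample interval: `width_samples = max(1, round(width_s /
#' interval_s))`, rounded up to the next odd integer so the window is
#' symmetric around each observed sample. At 1 Hz the widths 5, 20 and 60
#' seconds give 5, 21 and 61 samples.
#'
#' @param width_s Positive kernel width in seconds.
#' @param interval_s Positive sample interval in seconds.
#' @return A `dilation_kernel`: list with `shape`, `width_s`, `width_samples`.
#' @export
boxcar_kernel <- function(width_s, interval_s = 1) {
  if (!is.numeric(width_s) || length(width_s) != 1L || width_s <= 0)
    stop("`width_s` must be a positive number of seconds")
  if (!is.numeric(interval_s) || length(interval_s) != 1L || interval_s <= 0)
    stop("`interval_s` must be positive")
  w <- max(1L, as.integer(round(width_s / interval_s)))
  if (w %% 2L == 0L) w <- w + 1L
  structure(list(shape = "boxcar", width_s = width_s, width_samples = w),
            class = "dilation_kernel")
}

#' Dilate sparse time-series ratings prior to model fitting
#'
#' Spreads each training-observed rating of a user to the
#' `floor(width_samples / 2)` time points on either side. A time point
#' receiving contributions from several observed ratings takes their
#' unweighted mean (a boxcar weights all contributions equally). Originally
#' train-observed values are never altered; points outside every window stay
#' missing; windows truncate at the series edges. Only cells flagged in
#' `train_mask` contribute, so held-out test ratings can never leak into the
#' dilated matrix.
#'
#' @param matrix A `ratings_matrix` with a time axis.
#' @param train_mask Logical matrix marking the observed (training) cells;
#'   must be `TRUE` only where `matrix` is non-missing.
#' @param kernel A `dilation_kernel` from [boxcar_kernel()].
#' @return A `ratings_matrix` containing the train-observed values plus the
#'   filled ("pseudo-observed") points; everything else missing. The logical
#'   attribute `"pseudo_observed"` marks the filled cells.
#' @examples
#' v <- rbind(u1 = c(NA, 4, NA, 8, NA))
#' m <- ratings_matrix(v, interval_s = 1)
#' k <- boxcar_kernel(3)
#' dilate(m, !is.na(v), k)$values
#' @export
dilate <- function(matrix, train_mask, kernel) {
  stopifnot(inherits(matrix, "ratings_matrix"), inherits(kernel, "dilation_kernel"))
  if (is.null(matrix$interval_s))
    stop("dilation requires a time axis; set `interval_s`")
  if (!is.logical(train_mask) || !identical(dim(train_mask), dim(matrix$values)))
    stop("`train_mask` must be a logical matrix matching the ratings matrix")
  if (any(train_mask & is.na(matrix$values)))
    stop("`train_mask` marks cells that are missing in `matrix`")
  w <- kernel$width_samples
  n_t <- ncol(matrix$values)
  if (w > n_t)
    stop(sprintf("kernel width (%d samples) exceeds series length (%d)", w, n_t))
  h <- w %/% 2L
  v <- matrix$values
  out <- base::matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  pseudo <- base::matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  for (u in seq_len(nrow(v))) {
    obs_t <- which(train_mask[u, ])
    if (length(obs_t) == 0L) next
    acc <- numeric(n_t)
    cnt <- integer(n_t)
    for (t0 in obs_t) {
      lo <- max(1L, t0 - h); hi <- min(n_t, t0 + h)
      acc[lo:hi] <- acc[lo:hi] + v[u, t0]
      cnt[lo:hi] <- cnt[lo:hi] + 1L
    }
    filled <- cnt > 0L
    out[u, filled] <- acc[filled] / cnt[filled]
    # originally observed values are kept verbatim
    out[u, obs_t] <- v[u, obs_t]
    pseudo[u, ] <- filled
    pseudo[u, obs_t] <- FALSE
  }
  res <- ratings_matrix(out, scale = matrix$scale, interval_s = matrix$interval_s)
  attr(res, "pseudo_observed") <- pseudo
  res
}
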