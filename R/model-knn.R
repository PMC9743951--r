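#' User-based k-nearest-neighbors collaborative filtering
#'
#' `knn_fit()` stores the training matrix together with a user-user
#' similarity matrix; `predict()` implements the similarity-weighted
#' neighborhood average
#' \deqn{\hat r_{u,i} = \sum_v r_{v,i} \, sim(u,v) \; / \; \sum_v sim(u,v)}
#' over the at most `k` most similar users with a *defined, strictly
#' positive* similarity to `u` and an observed training rating for item `i`.
#' `k` is the maximum neighborhood size: fewer (or zero) candidates may exist
#' under high sparsity. With no candidate the prediction falls back to the
#' item mean (`item_mean_fallback`), and to the global training mean
#' (`global_mean_fallback`) when the item has no observed rating at all.
#' Predictions are not clipped to the rating scale.
#'
#' @param train A `ratings_matrix` of training ratings.
#' @param k Maximum number of neighbors (>= 1); ties in similarity are broken
#'   by user order.
#' @param metric,min_overlap Passed to [pairwise_similarity()].
#' @param similarity Optionally a precomputed `similarity_matrix` on `train`.
#' @return A `knn_fit` object.
#' @examples
#' m <- gen_subgroup_decisions(n_users = 12, n_items = 20, seed = 1)
#' s <- mask_random(m, 0.4, seed = 2)
#' fit <- knn_fit(train_matrix(m, s), k = 5)
#' head(predict(fit))
#' @export
knn_fit <- function(train, k = 10L, metric = "pearson", min_overlap = 2L,
                    similarity = NULL) {
  stopifnot(inherits(train, "ratings_matrix"))
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("`k` must be >= 1")
  if (is.null(similarity)) {
    similarity <- pairwise_similarity(train, metric, min_overlap)
  } else {
    stopifnot(inherits(similarity, "similarity_matrix"))
  }
  structure(list(train = train, similarity = similarity, k = as.integer(k)),
            class = "knn_fit")
}

#' @rdname knn_fit
#' @param object A `knn_fit`.
#' @param cells Cells to predict, see [mean_predict()].
#' @param ... Unused.
#' @export
predict.knn_fit <- function(object, cells = NULL, ...) {
  train <- object$train
  idx <- resolve_cells(train, cells)
  v <- train$values
  sim <- object$similarity$values
  col_means <- colMeans(v, na.rm = TRUE)
  global <- mean(v, na.rm = TRUE)
  k <- object$k
  n <- nrow(idx)
  value <- numeric(n)
  method <- character(n)
  for (r in seq_len(n)) {
    u <- idx[r, 1]; i <- idx[r, 2]
    s <- sim[u, ]
    cand <- which(!is.na(s) & s > 0 & !is.na(v[, i]))
    cand <- cand[cand != u]
    if (length(cand) > 0L) {
      # top-k by similarity; order() is stable so ties resolve by user order
      cand <- cand[order(-s[cand])][seq_len(min(k, length(cand)))]
      w <- s[cand]
      value[r] <- sum(v[cand, i] * w) / sum(w)
      method[r] <- "model"
    } else if (!is.nan(col_means[i])) {
      value[r] <- col_means[i]
      method[r] <- "item_mean_fallback"
    } else {
      value[r] <- global
      method[r] <- "global_mean_fallback"
    }
  }
  prediction_frame(train, idx, value, method)
}

#' @export
print.knn_fit <- function(x, ...) {
  cat(sprintf("<knn_fit> k = %d, metric = %s, %d users\n",
              x$k, x$similarity$metric, nrow(x$train$values)))
  invisible(x)
}
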