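#' Mean (baseline) predictions
#'
#' Predicts each requested cell with the mean of all observed training
#' ratings for that item. An item with no observed training rating falls back
#' to the global mean of all observed training ratings, flagged
#' `global_mean_fallback`.
#'
#' @param train A `ratings_matrix` holding the training (observed) ratings.
#' @param cells Data frame with columns `user` and `item` (ids present in
#'   `train`), or a 2-column integer matrix of (user, item) indices. Defaults
#'   to every missing cell of `train`.
#' @return Data frame `user`, `item`, `value`, `method_used`.
#' @examples
#' m <- ratings_matrix(rbind(u1 = c(1, NA), u2 = c(3, 4)))
#' mean_predict(m)
#' @export
mean_predict <- function(train, cells = NULL) {
  stopifnot(inherits(train, "ratings_matrix"))
  idx <- resolve_cells(train, cells)
  v <- train$values
  col_means <- colMeans(v, na.rm = TRUE)
  global <- mean(v, na.rm = TRUE)
  value <- col_means[idx[, 2]]
  method <- rep("model", nrow(idx))
  fb <- is.nan(value)
  value[fb] <- global
  method[fb] <- "global_mean_fallback"
  prediction_frame(train, idx, value, method)
}

# Accept cells as NULL (all missing cells), a data.frame of ids, or an
# integer index matrix; return a 2-column integer index matrix.
resolve_cells <- function(matrix, cells) {
  v <- matrix$values
  if (is.null(cells)) {
    miss <- which(is.na(v), arr.ind = TRUE)
    if (nrow(miss) == 0L) stop("no missing cells to predict; pass `cells`")
    return(unname(miss))
  }
  if (is.matrix(cells) && is.numeric(cells)) {
    stopifnot(ncol(cells) == 2L)
    if (any(cells[, 1] < 1 | cells[, 1] > nrow(v)) ||
        any(cells[, 2] < 1 | cells[, 2] > ncol(v)))
      stop("cell indices out of range")
    return(cbind(as.integer(cells[, 1]), as.integer(cells[, 2])))
  }
  if (is.data.frame(cells)) {
    ui <- match(as.character(cells$user), rownames(v))
    ii <- match(as.character(cells$item), colnames(v))
    if (anyNA(ui)) stop("unknown user label: ", cells$user[which(is.na(ui))[1]])
    if (anyNA(ii)) stop("unknown item label: ", cells$item[which(is.na(ii))[1]])
    return(cbind(ui, ii))
  }
  stop("`cells` must be NULL, a data frame with user/item, or an index matrix")
}

prediction_frame <- function(matrix, idx, value, method) {
  data.frame(
    user = rownames(matrix$values)[idx[, 1]],
    item = colnames(matrix$values)[idx[, 2]],
    value = unname(value),
    method_used = method,
    stringsAsFactors = FALSE
  )
}
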