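#' Chained-equations imputation of a sparse ratings matrix
#'
#' Iterative per-item regression imputation: missing cells start at their
#' item (column) mean; each round visits the items in a fresh seeded random
#' order and regresses every incomplete item on all other items, using only
#' the rows where the target item was originally observed, then re-imputes
#' the originally-missing cells from the fitted regression. After the final
#' round, imputations are clipped to the range of the observed training
#' data. Rank-deficient designs are solved by pivoted least squares with
#' aliased coefficients dropped (set to zero), matching pseudo-inverse
#' behavior.
#'
#' A run fails explicitly - rather than silently dropping columns - when an
#' item has no observed rating (column-mean initialization impossible) or
#' fewer than 2 observed rows (no regression can be fit). Such failures are
#' expected at extreme sparsity and are reported by the cross-validation
#' harness as failed runs.
#'
#' @param train A `ratings_matrix`.
#' @param n_rounds Number of imputation rounds (default 10).
#' @param seed Integer seed for the per-round visitation order.
#' @return A `mice_result`: list with `completed` (numeric matrix or `NULL`),
#'   `failed` (logical) and `message`.
#' @examples
#' m <- gen_normed_images(n_users = 15, n_items = 8, seed = 1)
#' s <- mask_random(m, 0.3, seed = 1)
#' res <- mice_impute(train_matrix(m, s), seed = 1)
#' res$failed
#' @export
mice_impute <- function(train, n_rounds = 10L, seed = 0L) {
  stopifnot(inherits(train, "ratings_matrix"))
  v <- train$values
  obs <- !is.na(v)
  fail <- function(msg) structure(list(completed = NULL, failed = TRUE,
                                       message = msg), class = "mice_result")
  col_obs <- colSums(obs)
  if (any(col_obs == 0L))
    return(fail(sprintf("item '%s' has no observed rating; cannot initialize",
                        colnames(v)[which(col_obs == 0L)[1]])))
  incomplete <- which(colSums(!obs) > 0L)
  if (length(incomplete)) {
    short <- incomplete[col_obs[incomplete] < 2L]
    if (length(short))
      return(fail(sprintf("item '%s' has fewer than 2 observed rows; regression impossible",
                          colnames(v)[short[1]])))
  }
  x <- v
  cm <- colMeans(v, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[!obs[, j], j] <- cm[j]
  if (length(incomplete)) {
    for (round in seq_len(n_rounds)) {
      visit <- if (length(incomplete) == 1L) incomplete
               else with_seed(derive_seed(seed, round), sample(incomplete))
      for (j in visit) {
        rows <- obs[, j]
        design <- cbind(1, x[rows, -j, drop = FALSE])
        fit <- stats::lm.fit(design, v[rows, j])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0  # aliased columns dropped
        if (any(!is.finite(beta)))
          return(fail(sprintf("estimation failed for item '%s'", colnames(v)[j])))
        newx <- cbind(1, x[!rows, -j, drop = FALSE])
        x[!rows, j] <- drop(newx %*% beta)
      }
    }
    lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
    x[!obs] <- pmin(pmax(x[!obs], lo), hi)
  }
  structure(list(completed = x, failed = FALSE, message = ""),
            class = "mice_result")
}

#' @export
print.mice_result <- function(x, ...) {
  if (x$failed) cat("<mice_result> imputation failed:", x$message, "\n")
  else cat("<mice_result> completed", nrow(x$completed), "x",
           ncol(x$completed), "matrix\n")
  invisible(x)
}
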