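#' Biased non-negative matrix factorization trained by SGD
#'
#' Learns the prediction model
#' \deqn{\hat r_{u,i} = \mu + b_u + b_i + q_i^T p_u}
#' from the observed training cells only. \eqn{\mu} is the global mean of the
#' training ratings; user and item biases start at zero; the non-negative
#' factor matrices `W` (users x f, rows \eqn{p_u}) and `H` (f x items,
#' columns \eqn{q_i}) start as absolute random normal draws scaled by `1/f`.
#' Each training iteration shuffles the observed cells and, cell by cell,
#' applies the bias and factor gradient updates sequentially, projecting the
#' factors onto the non-negative orthant after every update. Training stops
#' when the absolute change in mean squared training error is at most `tol`
#' or after `max_iter` iterations.
#'
#' @param train A `ratings_matrix` of training ratings.
#' @param n_factors Number of latent factors `f`; `NULL` (default) uses
#'   `min(n_users, n_items)`.
#' @param learning_rate SGD step size \eqn{\gamma} (default 0.001).
#' @param lambda Named numeric vector of L2 penalties
#'   `c(bu = , bi = , pu = , qi = )`; default all zero.
#' @param tol Convergence tolerance on the change in training MSE
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @param seed Integer seed controlling initialization and shuffling.
#' @param check_nonneg Assert factor non-negativity inside the training loop
#'   (test hook; slows training).
#' @return An `nnmf_fit` with elements `mu`, `b_u`, `b_i`, `W`, `H`,
#'   `history` (training MSE per iteration), `converged`, plus the
#'   hyper-parameters used.
#' @examples
#' m <- gen_normed_images(n_users = 10, n_items = 12, seed = 1)
#' fit <- nnmf_sgd(m, n_factors = 2, max_iter = 50, seed = 1)
#' head(predict(fit, to_long(m)[1:3, c("user", "item")]))
#' @export
nnmf_sgd <- function(train, n_factors = NULL, learning_rate = 0.001,
                     lambda = c(bu = 0, bi = 0, pu = 0, qi = 0),
                     tol = 1e-6, max_iter = 1000L, seed = 0L,
                     check_nonneg = FALSE) {
  stopifnot(inherits(train, "ratings_matrix"))
  if (learning_rate < 0) stop("`learning_rate` must be >= 0")
  lam <- c(bu = 0, bi = 0, pu = 0, qi = 0)
  lam[names(lambda)] <- lambda
  v <- train$values
  nu <- nrow(v); ni <- ncol(v)
  f <- as.integer(n_factors %||% min(nu, ni))
  if (f < 1L) stop("`n_factors` must be >= 1")
  obs <- which(!is.na(v), arr.ind = TRUE)
  if (nrow(obs) == 0L) stop("training matrix has no observed ratings")
  r <- v[obs]
  mu <- mean(r)

  res <- with_seed(seed, {
    W0 <- matrix(abs(rnorm(nu * f)) / f, nu, f)
    H0 <- matrix(abs(rnorm(f * ni)) / f, f, ni)
    nnmf_sgd_core(r, obs[, 1] - 1L, obs[, 2] - 1L, t(W0), H0,
                  numeric(nu), numeric(ni), mu, learning_rate,
                  lam[["bu"]], lam[["bi"]], lam[["pu"]], lam[["qi"]],
                  tol, as.integer(max_iter), isTRUE(check_nonneg))
  })
  res$W <- t(res$Wt)
  rownames(res$W) <- rownames(v); colnames(res$H) <- colnames(v)
  names(res$b_u) <- rownames(v); names(res$b_i) <- colnames(v)
  structure(
    list(mu = mu, b_u = res$b_u, b_i = res$b_i, W = res$W, H = res$H,
         history = res$history, converged = res$converged,
         n_iter = res$n_iter, method = "sgd", f = f,
         gamma = learning_rate, lambda = lam, tol = tol,
         max_iter = as.integer(max_iter), seed = as.integer(seed),
         user_ids = rownames(v), item_ids = colnames(v), shift = 0),
    class = "nnmf_fit"
  )
}

#' Non-negative matrix factorization via multiplicative updates
#'
#' The classic two-factor multiplicative update scheme minimizing squared
#' reconstruction error, applied to a dense matrix: the scheme has no native
#' notion of missing cells, so unobserved ratings are zero-filled before
#' factorization (its documented limitation, and the reason it degrades on
#' sparse data). No bias terms; predictions are `(W H)[u, i]`. Training
#' ratings must be non-negative; with a declared scale reaching below zero
#' the data are shifted by `-r_min` for fitting and predictions are shifted
#' back.
#'
#' @param train A `ratings_matrix`.
#' @param n_factors Number of latent factors (default `min(n_users,
#'   n_items)`).
#' @param tol Stop when the change in reconstruction MSE (over the dense,
#'   zero-filled matrix) is at most `tol`.
#' @param max_iter Iteration cap.
#' @param seed Seed for the random (absolute normal) initialization.
#' @param init_W,init_H Optional explicit non-negative starting factors.
#' @return An `nnmf_fit` (with `mu = 0` and zero biases).
#' @export
nnmf_mult <- function(train, n_factors = NULL, tol = 1e-6, max_iter = 1000L,
                      seed = 0L, init_W = NULL, init_H = NULL) {
  stopifnot(inherits(train, "ratings_matrix"))
  v <- train$values
  shift <- 0
  if (any(v < 0, na.rm = TRUE)) {
    if (is.null(train$scale))
      stop("negative ratings require a declared scale so the data can be shifted")
    shift <- -train$scale[1]
    v <- v + shift
  }
  nu <- nrow(v); ni <- ncol(v)
  f <- as.integer(n_factors %||% min(nu, ni))
  if (f < 1L) stop("`n_factors` must be >= 1")
  V <- v
  V[is.na(V)] <- 0  # dense zero-fill: the scheme cannot skip missing cells
  W <- init_W %||% with_seed(seed, matrix(abs(rnorm(nu * f)) / f, nu, f))
  H <- init_H %||% with_seed(derive_seed(seed, 1L), matrix(abs(rnorm(f * ni)) / f, f, ni))
  if (any(W < 0) || any(H < 0)) stop("initial factors must be non-negative")
  eps <- 1e-12
  prev <- Inf
  history <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    mse <- mean((V - W %*% H)^2)
    history <- c(history, mse)
    if (abs(prev - mse) <= tol) { converged <- TRUE; break }
    prev <- mse
  }
  rownames(W) <- rownames(v); colnames(H) <- colnames(v)
  structure(
    list(mu = 0, b_u = setNames(numeric(nu), rownames(v)),
         b_i = setNames(numeric(ni), colnames(v)),
         W = W, H = H, history = history, converged = converged,
         n_iter = length(history), method = "mult", f = f,
         gamma = NA_real_, lambda = c(bu = 0, bi = 0, pu = 0, qi = 0),
         tol = tol, max_iter = as.integer(max_iter), seed = as.integer(seed),
         user_ids = rownames(v), item_ids = colnames(v), shift = shift),
    class = "nnmf_fit"
  )
}

#' @rdname nnmf_sgd
#' @param object An `nnmf_fit`.
#' @param cells Cells to predict, see [mean_predict()].
#' @param ... Unused.
#' @export
predict.nnmf_fit <- function(object, cells = NULL, ...) {
  fake <- list(values = matrix(NA_real_, length(object$user_ids),
                               length(object$item_ids),
                               dimnames = list(object$user_ids, object$item_ids)))
  if (is.null(cells))
    stop("`cells` must be given: an nnmf_fit does not keep the train matrix")
  idx <- resolve_cells(fake, cells)
  inter <- rowSums(object$W[idx[, 1], , drop = FALSE] *
                   t(object$H)[idx[, 2], , drop = FALSE])
  value <- object$mu + object$b_u[idx[, 1]] + object$b_i[idx[, 2]] + inter -
    object$shift
  prediction_frame(fake, idx, value, rep("model", nrow(idx)))
}

#' @export
print.nnmf_fit <- function(x, ...) {
  cat(sprintf("<nnmf_fit> %s, f = %d, %d iteration(s), %sconverged\n",
              if (x$method == "sgd") "SGD with biases" else "multiplicative updates",
              x$f, x$n_iter, if (x$converged) "" else "not "))
  cat(sprintf("  final training MSE: %.6g\n", tail(x$history, 1)))
  invisible(x)
}

#' @importFrom stats setNames
#' @importFrom utils tail
NULL
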