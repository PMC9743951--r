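#' Root mean squared error
#' @param predictions,truths Equal-length, non-empty finite numeric vectors.
#' @return `sqrt(mean((predictions - truths)^2))`.
#' @export
rmse <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("`predictions` and `truths` must have equal length")
  if (length(predictions) == 0L) stop("empty input")
  if (any(!is.finite(predictions)) || any(!is.finite(truths)))
    stop("inputs must be finite")
  sqrt(mean((predictions - truths)^2))
}

#' Normalized error
#'
#' RMSE divided by the rating-scale range, `rmse / (r_max - r_min)`, bounding
#' scores so that 0 is perfect and values near 1 are maximal error; readable
#' as percentage inaccuracy relative to the scale.
#'
#' @param rmse_value Non-negative RMSE.
#' @param r_min,r_max Scale endpoints, `r_max > r_min`.
#' @return Normalized error.
#' @export
normalized_error <- function(rmse_value, r_min, r_max) {
  if (!is.numeric(rmse_value) || any(rmse_value < 0))
    stop("`rmse_value` must be >= 0")
  if (r_max <= r_min) stop("degenerate range: r_max must exceed r_min")
  rmse_value / (r_max - r_min)
}

#' Per-user prediction-truth correlations
#'
#' Pearson correlation between predictions and true ratings, computed
#' separately for each user. Users with fewer than 2 cells, or a constant
#' prediction or truth vector, get `NA` (excluded from averages).
#'
#' @param predictions,truths Numeric vectors.
#' @param by_user Vector of user labels, same length.
#' @return Named numeric vector, one entry per distinct user (in order of
#'   first appearance).
#' @export
per_user_correlation <- function(predictions, truths, by_user) {
  stopifnot(length(predictions) == length(truths),
            length(by_user) == length(truths))
  users <- unique(by_user)
  out <- vapply(users, function(u) {
    sel <- by_user == u
    p <- predictions[sel]; t <- truths[sel]
    if (length(p) < 2L || sd(p) == 0 || sd(t) == 0) return(NA_real_)
    cor(p, t)
  }, numeric(1))
  names(out) <- as.character(users)
  out
}

builtin_algorithms <- c("mean", "knn", "nnmf_sgd", "nnmf_mult", "mice")

# Dispatch one algorithm on a train matrix; returns data.frame of predictions
# for `cells` (index matrix) or condition-signals an error.
run_algorithm <- function(name, fun, train, cells, seed, control) {
  if (!is.null(fun)) return(fun(train, cells, seed))
  switch(name,
    mean = mean_predict(train, cells),
    knn = predict(knn_fit(train, k = control$k %||% 10L,
                          metric = control$metric %||% "pearson",
                          min_overlap = control$min_overlap %||% 2L),
                  cells),
    nnmf_sgd = predict(nnmf_sgd(train,
                                n_factors = control$n_factors,
                                learning_rate = control$learning_rate %||% 0.001,
                                lambda = control$lambda %||% c(bu = 0, bi = 0, pu = 0, qi = 0),
                                tol = control$tol %||% 1e-6,
                                max_iter = control$max_iter %||% 1000L,
                                seed = seed),
                       cells),
    nnmf_mult = predict(nnmf_mult(train,
                                  n_factors = control$n_factors,
                                  tol = control$tol %||% 1e-6,
                                  max_iter = control$max_iter %||% 1000L,
                                  seed = seed),
                        cells),
    mice = {
      res <- mice_impute(train, n_rounds = control$n_rounds %||% 10L, seed = seed)
      if (res$failed) stop("imputation failed: ", res$message)
      data.frame(user = rownames(train$values)[cells[, 1]],
                 item = colnames(train$values)[cells[, 2]],
                 value = res$completed[cells],
                 method_used = "model", stringsAsFactors = FALSE)
    },
    stop("unknown algorithm: ", name)
  )
}

#' Masking cross-validation across sparsity levels
#'
#' The evaluation harness: for every combination of sparsity level and
#' iteration, one seeded random mask is drawn and *shared by all algorithms
#' and dilation settings* (a paired design). Each algorithm trains on the
#' un-masked cells (optionally dilated, for time-series matrices - dilation
#' is applied after masking and sees only training cells) and predicts every
#' held-out cell. Errors are computed separately per user: RMSE over the
#' user's test cells, normalized by the rating-scale range, plus the
#' prediction-truth correlation. Algorithm failures (e.g. chained-equations
#' runs at extreme sparsity) are recorded as failed runs, not dropped.
#'
#' @param matrix A fully or partially observed `ratings_matrix` (the ground
#'   truth).
#' @param algorithms Character vector of built-ins (`"mean"`, `"knn"`,
#'   `"nnmf_sgd"`, `"nnmf_mult"`, `"mice"`), and/or a named list whose
#'   elements are either a built-in name's control list or a function
#'   `f(train, cells, seed)` returning a prediction data frame (test hook).
#' @param sparsity_levels Fractions of observed cells masked for testing
#'   (default `seq(0.1, 0.9, 0.1)`).
#' @param n_iterations Random masks per sparsity level (default 10).
#' @param dilation_widths_s Numeric vector of boxcar widths in seconds;
#'   0 means no dilation (default). Non-zero widths need a time axis.
#' @param base_seed Integer; all masks and model seeds derive from it.
#' @param control Default control list applied to all built-in algorithms
#'   (e.g. `list(k = 10, max_iter = 1000)`).
#' @return A `cf_evaluation`: data frame with columns `algorithm`,
#'   `dilation_width_s`, `sparsity`, `iteration`, `user`, `n_test`, `rmse`,
#'   `normalized_error`, `pred_truth_correlation`, `failed`, plus a
#'   `"failures"` attribute describing failed runs.
#' @examples
#' m <- gen_subgroup_decisions(n_users = 15, n_items = 20, seed = 1)
#' ev <- cross_validate(m, "mean", sparsity_levels = 0.5,
#'                      n_iterations = 2, base_seed = 1)
#' aggregate_evaluation(ev)
#' @export
cross_validate <- function(matrix, algorithms = c("mean", "knn", "nnmf_sgd"),
                           sparsity_levels = seq(0.1, 0.9, by = 0.1),
                           n_iterations = 10L, dilation_widths_s = 0,
                           base_seed = 0L, control = list()) {
  stopifnot(inherits(matrix, "ratings_matrix"))
  algos <- normalize_algorithms(algorithms)
  if (length(algos) == 0L) stop("at least one algorithm is required")
  if (any(dilation_widths_s > 0) && is.null(matrix$interval_s))
    stop("dilation requires a matrix with a time axis")
  rng <- rating_range(matrix)
  users <- rownames(matrix$values)
  records <- list()
  failures <- list()
  for (si in seq_along(sparsity_levels)) {
    sp <- sparsity_levels[si]
    for (it in seq_len(n_iterations)) {
      split <- mask_random(matrix, sp, seed = derive_seed(base_seed, si, it))
      cells <- which(split$test, arr.ind = TRUE)
      truths <- matrix$values[cells]
      base_train <- train_matrix(matrix, split)
      for (w in dilation_widths_s) {
        train <- if (w > 0) {
          dilate(base_train, split$train, boxcar_kernel(w, matrix$interval_s))
        } else base_train
        for (ai in seq_along(algos)) {
          a <- algos[[ai]]
          model_seed <- derive_seed(base_seed, si, it, ai)
          pred <- tryCatch(
            run_algorithm(a$name, a$fun, train, cells, model_seed,
                          utils::modifyList(control, a$control)),
            error = function(e) e
          )
          if (inherits(pred, "error")) {
            failures[[length(failures) + 1L]] <- data.frame(
              algorithm = a$label, dilation_width_s = w, sparsity = sp,
              iteration = it, message = conditionMessage(pred),
              stringsAsFactors = FALSE)
            records[[length(records) + 1L]] <- data.frame(
              algorithm = a$label, dilation_width_s = w, sparsity = sp,
              iteration = it, user = NA_character_, n_test = NA_integer_,
              rmse = NA_real_, normalized_error = NA_real_,
              pred_truth_correlation = NA_real_, failed = TRUE,
              stringsAsFactors = FALSE)
            next
          }
          by_user <- users[cells[, 1]]
          for (u in unique(by_user)) {
            sel <- by_user == u
            r <- rmse(pred$value[sel], truths[sel])
            p <- pred$value[sel]; t <- truths[sel]
            pc <- if (sum(sel) < 2L || sd(p) == 0 || sd(t) == 0) NA_real_
                  else cor(p, t)
            records[[length(records) + 1L]] <- data.frame(
              algorithm = a$label, dilation_width_s = w, sparsity = sp,
              iteration = it, user = u, n_test = sum(sel), rmse = r,
              normalized_error = normalized_error(r, rng[1], rng[2]),
              pred_truth_correlation = pc, failed = FALSE,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures)
                           else data.frame()
  attr(out, "range") <- rng
  class(out) <- c("cf_evaluation", "data.frame")
  out
}

normalize_algorithms <- function(algorithms) {
  if (is.character(algorithms)) {
    return(lapply(algorithms, function(nm) {
      if (!nm %in% builtin_algorithms) stop("unknown algorithm: ", nm)
      list(name = nm, label = nm, fun = NULL, control = list())
    }))
  }
  if (is.list(algorithms)) {
    nms <- names(algorithms)
    if (is.null(nms) || any(nms == ""))
      stop("algorithm lists must be named")
    return(lapply(seq_along(algorithms), function(k) {
      el <- algorithms[[k]]
      if (is.function(el))
        list(name = nms[k], label = nms[k], fun = el, control = list())
      else if (is.list(el)) {
        base <- el$algorithm %||% nms[k]
        if (!base %in% builtin_algorithms) stop("unknown algorithm: ", base)
        list(name = base, label = nms[k], fun = NULL,
             control = el[setdiff(names(el), "algorithm")])
      } else stop("each algorithm entry must be a function or a control list")
    }))
  }
  stop("`algorithms` must be a character vector or a named list")
}

#' Aggregate an evaluation table
#'
#' Two-stage aggregation matching the harness's reporting convention: for
#' each (algorithm, dilation width, sparsity), errors are first averaged
#' over iterations within each user, then averaged across users, with a
#' seeded bootstrap (resampling users) for 95% confidence intervals.
#'
#' @param evaluation A `cf_evaluation` from [cross_validate()].
#' @param n_boot Bootstrap resamples (default 1000; 0 disables the CI).
#' @param seed Bootstrap seed.
#' @return Data frame with one row per (algorithm, dilation_width_s,
#'   sparsity): `n_users`, `normalized_error` (mean across users),
#'   `ci_lower`, `ci_upper`, `rmse`, `pred_truth_correlation`, `n_failed`.
#' @export
aggregate_evaluation <- function(evaluation, n_boot = 1000L, seed = 0L) {
  stopifnot(inherits(evaluation, "cf_evaluation") || is.data.frame(evaluation))
  ev <- as.data.frame(evaluation)
  key <- interaction(ev$algorithm, ev$dilation_width_s, ev$sparsity, drop = TRUE)
  rows <- lapply(split(ev, key), function(g) {
    ok <- g[!g$failed, , drop = FALSE]
    n_failed <- length(unique(g$iteration[g$failed]))
    if (nrow(ok) == 0L) {
      return(data.frame(algorithm = g$algorithm[1],
                        dilation_width_s = g$dilation_width_s[1],
                        sparsity = g$sparsity[1], n_users = 0L,
                        normalized_error = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, rmse = NA_real_,
                        pred_truth_correlation = NA_real_,
                        n_failed = n_failed, stringsAsFactors = FALSE))
    }
    per_user <- tapply(ok$normalized_error, ok$user, mean)
    per_user_rmse <- tapply(ok$rmse, ok$user, mean)
    pc <- ok$pred_truth_correlation
    per_user_corr <- tapply(pc, ok$user, function(z)
      if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0L && length(per_user) > 1L) {
      boots <- with_seed(seed, {
        vapply(seq_len(n_boot), function(b)
          mean(per_user[sample.int(length(per_user), replace = TRUE)]),
          numeric(1))
      })
      ci <- unname(quantile(boots, c(0.025, 0.975)))
    }
    data.frame(algorithm = g$algorithm[1],
               dilation_width_s = g$dilation_width_s[1],
               sparsity = g$sparsity[1], n_users = length(per_user),
               normalized_error = mean(per_user), ci_lower = ci[1],
               ci_upper = ci[2], rmse = mean(per_user_rmse),
               pred_truth_correlation = mean(per_user_corr, na.rm = TRUE),
               n_failed = n_failed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$algorithm, out$dilation_width_s, out$sparsity), ]
}

#' Minimal error-versus-sparsity summary plot
#'
#' @param x A `cf_evaluation`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the aggregated table that was plotted.
#' @export
plot.cf_evaluation <- function(x, ...) {
  agg <- aggregate_evaluation(x, n_boot = 0L)
  key <- paste(agg$algorithm, agg$dilation_width_s, sep = "/")
  sp <- sort(unique(agg$sparsity))
  mat <- sapply(unique(key), function(k) {
    g <- agg[key == k, ]
    g$normalized_error[match(sp, g$sparsity)]
  })
  graphics::matplot(sp, mat, type = "b", pch = 19, lty = 1,
                    xlab = "fraction of ratings masked",
                    ylab = "normalized error", ...)
  graphics::legend("topleft", legend = unique(key), col = seq_len(ncol(mat)),
                   lty = 1, pch = 19, bty = "n", cex = 0.8)
  invisible(agg)
}

#' Write an evaluation table and its run metadata
#'
#' The long-form CSV is shaped for downstream mixed-model analysis; the JSON
#' sidecar records failures.
#'
#' @param evaluation A `cf_evaluation`.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.meta.json` using a minimal serializer (no extra dependencies).
#' @export
write_evaluation_csv <- function(evaluation, path) {
  write.csv(as.data.frame(evaluation), path, row.names = FALSE, quote = FALSE)
  fails <- attr(evaluation, "failures")
  meta <- sprintf(
    '{"n_records": %d, "n_failures": %d, "failures": [%s]}',
    nrow(evaluation), nrow(fails),
    paste(vapply(seq_len(nrow(fails)), function(k) {
      sprintf('{"algorithm": "%s", "sparsity": %g, "iteration": %d, "message": "%s"}',
              fails$algorithm[k], fails$sparsity[k], fails$iteration[k],
              gsub('"', "'", fails$message[k]))
    }, character(1)), collapse = ", ")
  )
  writeLines(meta, paste0(path, ".meta.json"))
  invisible(path)
}

#' @importFrom graphics matplot legend
NULL
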