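#' Pairwise user-user similarity on a sparse ratings matrix
#'
#' Computes a symmetric user-by-user similarity matrix over pairwise-complete
#' items only. Pairs sharing fewer than `min_overlap` observed items, and
#' pairs where either vector has zero variance over the overlap (for
#' correlation metrics), are left undefined (`NA`). Undefined similarities
#' mean "no neighbor relation" downstream; they are never treated as 0.
#'
#' Spearman is a rank transform of the overlap followed by Pearson; Kendall
#' is tau-b; cosine is computed on the raw (uncentered) vectors.
#'
#' @param matrix A `ratings_matrix`.
#' @param metric One of `"pearson"`, `"spearman"`, `"kendall"`, `"cosine"`.
#' @param min_overlap Minimum number of shared observed items for a pair to
#'   be defined; at least 2 for correlation metrics.
#' @return A `similarity_matrix`: list with `values` (symmetric numeric
#'   matrix, diagonal 1 where defined), `metric`, `min_overlap`.
#' @examples
#' m <- from_long(data.frame(user = rep(c("a", "b"), each = 3),
#'                           item = rep(c("x", "y", "z"), 2),
#'                           rating = c(1, 2, 3, 2, 4, 6)))
#' pairwise_similarity(m)$values
#' @export
pairwise_similarity <- function(matrix,
                                metric = c("pearson", "spearman", "kendall", "cosine"),
                                min_overlap = 2L) {
  stopifnot(inherits(matrix, "ratings_matrix"))
  metric <- match.arg(metric)
  if (metric != "cosine" && min_overlap < 2L)
    stop("`min_overlap` must be >= 2 for correlation metrics")
  if (min_overlap < 1L) stop("`min_overlap` must be >= 1")
  v <- matrix$values
  n <- nrow(v)
  s <- base::matrix(NA_real_, n, n, dimnames = list(rownames(v), rownames(v)))
  for (a in seq_len(n)) {
    for (b in a:n) {
      s[a, b] <- s[b, a] <- pair_similarity(v[a, ], v[b, ], metric, min_overlap)
    }
  }
  structure(list(user_ids = rownames(v), values = s, metric = metric,
                 min_overlap = as.integer(min_overlap)),
            class = "similarity_matrix")
}

pair_similarity <- function(x, y, metric, min_overlap) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_overlap) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (metric == "cosine") {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(NA_real_)
    return(sum(x * y) / (nx * ny))
  }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  if (metric == "spearman") return(cor(rank(x), rank(y)))
  cor(x, y, method = metric)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  n <- nrow(x$values)
  nd <- sum(is.na(x$values[lower.tri(x$values)]))
  cat(sprintf("<similarity_matrix> %d users, metric %s, %d undefined pair(s)\n",
              n, x$metric, nd))
  invisible(x)
}

#' Write a similarity matrix as wide CSV
#' @param sim A `similarity_matrix`.
#' @param path File path.
#' @export
write_similarity_csv <- function(sim, path) {
  stopifnot(inherits(sim, "similarity_matrix"))
  df <- data.frame(user = rownames(sim$values), sim$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Intersubject correlation summary
#'
#' Mean and standard deviation of the pairwise intersubject Pearson
#' correlations (the strictly-lower-triangle defined entries of the Pearson
#' similarity matrix). High mean / low SD indicates rating consensus; values
#' near zero indicate idiosyncratic responses.
#'
#' @param matrix A `ratings_matrix`.
#' @param min_overlap Passed to [pairwise_similarity()].
#' @return Named list `isc_mean`, `isc_sd`, `n_pairs`.
#' @examples
#' m <- gen_normed_images(n_users = 12, n_items = 40, seed = 0)
#' isc_summary(m)
#' @export
isc_summary <- function(matrix, min_overlap = 2L) {
  sim <- pairwise_similarity(matrix, "pearson", min_overlap = min_overlap)
  lt <- sim$values[lower.tri(sim$values)]
  lt <- lt[!is.na(lt)]
  if (length(lt) == 0L) stop("no user pair has a defined correlation")
  list(isc_mean = mean(lt), isc_sd = if (length(lt) > 1L) sd(lt) else 0,
       n_pairs = length(lt))
}
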