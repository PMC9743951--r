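# Independent brute-force oracles, deliberately naive and separate from the
# package implementations they cross-check.

# Pairwise-complete correlation between two users, straight from the
# definition.
oracle_pair_cor <- function(x, y, min_overlap = 2L) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_overlap) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  mx <- mean(x); my <- mean(y)
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(NA_real_)
  sum((x - mx) * (y - my)) / den
}

# Neighborhood prediction: similarity-weighted average over at most k users
# with positive similarity and an observed rating for the item, with the
# item-mean and global-mean fallbacks.
oracle_knn_cell <- function(values, sim, u, i, k) {
  cand <- setdiff(which(!is.na(values[, i])), u)
  cand <- cand[!is.na(sim[u, cand]) & sim[u, cand] > 0]
  if (length(cand) > 0L) {
    ord <- cand[order(-sim[u, cand])]
    use <- ord[seq_len(min(k, length(ord)))]
    return(sum(values[use, i] * sim[u, use]) / sum(sim[u, use]))
  }
  col <- values[, i]
  if (any(!is.na(col))) return(mean(col, na.rm = TRUE))
  mean(values, na.rm = TRUE)
}

# A random partially observed ratings matrix for property tests.
random_ratings <- function(n_users, n_items, frac_missing = 0.3, seed = 1,
                           scale = NULL) {
  set.seed(seed)
  v <- matrix(runif(n_users * n_items, 0, 100), n_users, n_items)
  v[sample(length(v), round(frac_missing * length(v)))] <- NA
  if (all(is.na(v))) v[1] <- 50
  ratings_matrix(v, scale = scale)
}

# Test-hook algorithm for the harness: returns the true held-out values.
make_oracle_algorithm <- function(truth) {
  force(truth)
  function(train, cells, seed) {
    data.frame(user = rownames(train$values)[cells[, 1]],
               item = colnames(train$values)[cells[, 2]],
               value = truth$values[cells],
               method_used = "model", stringsAsFactors = FALSE)
  }
}
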