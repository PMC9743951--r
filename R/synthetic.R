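#' Synthetic rating-data archetypes
#'
#' Seeded generators producing dense user-by-item matrices with the
#' statistical structure of three prototypical experimental contexts in
#' affective science: normed static-stimulus ratings with high consensus
#' (intersubject correlation around 0.72), autocorrelated 1 Hz bipolar
#' valence time-series with low consensus (ISC around 0.20), and decision
#' profiles with latent user sub-groups (ISC around 0.34). Matrices are
#' dense; sparsity is always induced afterwards with [mask_random()], so the
#' full ground truth is available for evaluation.
#'
#' @name synthetic_archetypes
NULL

clip_scale <- function(v, scale) {
  v[v < scale[1]] <- scale[1]
  v[v > scale[2]] <- scale[2]
  v
}

#' @describeIn synthetic_archetypes High-consensus ratings of normed static
#'   stimuli: `r_ui = item_signal_i + b_u + noise`, with the item signal
#'   dominating so users largely agree. The default variance decomposition
#'   (signal SD 8, noise SD 5, bias SD 3 on a 0-100 scale) targets a mean
#'   pairwise ISC of `8^2 / (8^2 + 5^2) = 0.72`.
#' @param n_users,n_items Matrix dimensions (>= 2 each).
#' @param seed Integer seed; identical configuration and seed give an
#'   identical matrix.
#' @param scale Rating scale; generated values are clipped into it.
#' @param item_signal_sd SD of the per-item mean signal (rating units).
#' @param user_bias_sd SD of additive per-user offsets.
#' @param noise_sd SD of cell-level noise.
#' @return A dense `ratings_matrix` (for the sub-group generator, with a
#'   `"groups"` attribute naming each user's latent group).
#' @examples
#' m <- gen_normed_images(n_users = 20, n_items = 40, seed = 0)
#' isc_summary(m)$isc_mean
#' @export
gen_normed_images <- function(n_users = 40, n_items = 80, seed = 0L,
                              scale = c(0, 100), item_signal_sd = 8,
                              user_bias_sd = 3, noise_sd = 5) {
  check_archetype_config(n_users, n_items, scale,
                         c(item_signal_sd, user_bias_sd, noise_sd))
  mid <- mean(scale)
  if (noise_sd + item_signal_sd > diff(scale))
    warning("noise/signal SDs are large relative to the scale; ",
            "clipping will distort the calibration")
  v <- with_seed(seed, {
    signal <- rnorm(n_items, mid, item_signal_sd)
    bias <- rnorm(n_users, 0, user_bias_sd)
    noise <- matrix(rnorm(n_users * n_items, 0, noise_sd), n_users, n_items)
    outer(bias, signal, `+`) + noise
  })
  dimnames(v) <- list(paste0("u", seq_len(n_users)), paste0("i", seq_len(n_items)))
  ratings_matrix(clip_scale(v, scale), scale = scale)
}

# AR(1) series with unit stationary variance.
ar1_series <- function(n, phi) {
  innov <- rnorm(n, 0, sqrt(1 - phi^2))
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t]
  x
}

# Rescale a draw to exact sample mean/sd so the configured variance
# decomposition (and hence the ISC calibration) holds in-sample rather than
# only in expectation.
standardize_to <- function(x, mean_target = 0, sd_target = 1) {
  s <- sd(x)
  if (s == 0) return(rep(mean_target, length(x)))
  mean_target + sd_target * (x - mean(x)) / s
}

#' @describeIn synthetic_archetypes Low-consensus continuous bipolar valence
#'   time-series at 1 Hz: each user's series is a personal loading on one
#'   shared autocorrelated story signal, plus an idiosyncratic
#'   autocorrelated process and a bias, mapped onto the rating scale. The
#'   loadings are spread around a positive mean wide enough that some users
#'   carry the opposite sign - disagreement about the valence of the same
#'   moment - which is what pushes the mean ISC down to about 0.2 while
#'   leaving every series strongly autocorrelated (lag-1 correlation near
#'   `ar_coefficient`).
#' @param ar_coefficient AR(1) coefficient of both latent processes, in
#'   `[0, 1)`.
#' @param sample_interval_s Seconds between consecutive time points.
#' @param loading_mean,loading_sd Mean and SD of the per-user loadings on
#'   the shared signal.
#' @param idio_sd SD of the idiosyncratic process (shared signal has SD 1).
#' @param gain Rating units per latent unit when mapping onto the scale.
#' @export
gen_affect_timeseries <- function(n_users = 30, n_items = 400, seed = 0L,
                                  scale = c(0, 100), ar_coefficient = 0.9,
                                  sample_interval_s = 1,
                                  loading_mean = 0.8, loading_sd = 1.2,
                                  idio_sd = 0.5, user_bias_sd = 0.7,
                                  gain = 12) {
  check_archetype_config(n_users, n_items, scale,
                         c(loading_sd, idio_sd, user_bias_sd))
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("`ar_coefficient` must lie in [0, 1)")
  mid <- mean(scale)
  v <- with_seed(seed, {
    shared <- standardize_to(ar1_series(n_items, ar_coefficient))
    loading <- standardize_to(rnorm(n_users), loading_mean, loading_sd)
    bias <- rnorm(n_users, 0, user_bias_sd)
    t(vapply(seq_len(n_users), function(u) {
      idio <- standardize_to(ar1_series(n_items, ar_coefficient))
      raw <- loading[u] * shared + idio_sd * idio + bias[u]
      mid + gain * raw
    }, numeric(n_items)))
  })
  dimnames(v) <- list(paste0("u", seq_len(n_users)),
                      paste0("t", seq_len(n_items) - 1L))
  ratings_matrix(clip_scale(v, scale), scale = scale,
                 interval_s = sample_interval_s)
}

#' @describeIn synthetic_archetypes Decision profiles with latent user
#'   sub-groups (by default four, with unequal sizes echoing moral
#'   phenotypes such as guilt aversion, inequity aversion, greed and moral
#'   opportunism): each group has its own item-response profile that shares
#'   a common component across groups, and users add a bias and noise. The
#'   default decomposition targets within-group correlations around 0.8,
#'   between-group around 0.15, and a mean ISC around 0.34. The true group
#'   label of each user is attached as attribute `"groups"` (a sidecar for
#'   stratified evaluation; it is never given to any algorithm).
#' @param n_groups Number of latent sub-groups (>= 1).
#' @param group_proportions Group size proportions, summing to 1.
#' @param profile_sd SD of the group item-profiles around the scale
#'   midpoint.
#' @param common_frac Fraction of profile variance shared by all groups, in
#'   `[0, 1]`.
#' @param profiles Optional explicit `n_items x n_groups` matrix of group
#'   item-profiles, overriding the random construction.
#' @export
gen_subgroup_decisions <- function(n_users = 60, n_items = 76, seed = 0L,
                                   scale = c(0, 100), n_groups = 4,
                                   group_proportions = c(0.1, 0.15, 0.35, 0.4),
                                   profile_sd = 16, common_frac = 0.19,
                                   user_bias_sd = 8, noise_sd = 8,
                                   profiles = NULL) {
  check_archetype_config(n_users, n_items, scale,
                         c(profile_sd, user_bias_sd, noise_sd))
  if (n_groups < 1) stop("`n_groups` must be >= 1")
  if (length(group_proportions) != n_groups)
    stop("`group_proportions` must have one entry per group")
  if (abs(sum(group_proportions) - 1) > 1e-8)
    stop("`group_proportions` must sum to 1")
  if (common_frac < 0 || common_frac > 1)
    stop("`common_frac` must lie in [0, 1]")
  sizes <- round(group_proportions * n_users)
  sizes[n_groups] <- n_users - sum(sizes[-n_groups])
  if (any(sizes < 1))
    stop("group proportions leave at least one group empty after rounding")
  mid <- mean(scale)
  group_of <- rep(seq_len(n_groups), sizes)
  if (!is.null(profiles) &&
      (!is.matrix(profiles) || !all(dim(profiles) == c(n_items, n_groups))))
    stop("`profiles` must be an n_items x n_groups matrix")
  v <- with_seed(seed, {
    if (is.null(profiles)) {
      base <- rnorm(n_items)
      profiles <- vapply(seq_len(n_groups), function(g) {
        mid + profile_sd * (sqrt(common_frac) * base +
                            sqrt(1 - common_frac) * rnorm(n_items))
      }, numeric(n_items))  # items x groups
    }
    bias <- rnorm(n_users, 0, user_bias_sd)
    noise <- matrix(rnorm(n_users * n_items, 0, noise_sd), n_users, n_items)
    t(profiles[, group_of]) + bias + noise
  })
  dimnames(v) <- list(paste0("u", seq_len(n_users)), paste0("i", seq_len(n_items)))
  out <- ratings_matrix(clip_scale(v, scale), scale = scale)
  attr(out, "groups") <- setNames(paste0("g", group_of), rownames(v))
  out
}

#' Latent group labels of a sub-group archetype matrix
#' @param matrix A matrix from [gen_subgroup_decisions()].
#' @return Named character vector of group labels per user.
#' @export
user_groups <- function(matrix) {
  g <- attr(matrix, "groups")
  if (is.null(g)) stop("matrix carries no group labels")
  g
}

check_archetype_config <- function(n_users, n_items, scale, sds) {
  if (n_users < 2 || n_items < 2)
    stop("archetypes need at least 2 users and 2 items")
  if (length(scale) != 2L || scale[2] <= scale[1])
    stop("`scale` must be c(r_min, r_max) with r_max > r_min")
  if (any(sds < 0)) stop("standard deviations must be >= 0")
}
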