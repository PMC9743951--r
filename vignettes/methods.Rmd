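---
title: "Collaborative filtering for sparse subjective ratings: models, harness and synthetic archetypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative filtering for sparse subjective ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfimpute)
```

## The problem

Dense measurement of subjective states — asking every participant to rate
every image, every second of a film, or every decision scenario — is
expensive and itself distorts the experience being measured. `cfimpute`
treats the alternative as a matrix-completion problem: collect ratings
*sparsely*, arrange them in a users × items matrix $V$ with explicit
missingness, and infer the unobserved cells from the similarity structure
among users. The package provides the predictive models, a masking
cross-validation harness that quantifies how well each model recovers
held-out ratings at any sparsity level, and seeded generators for three
synthetic data archetypes against which everything is tested.

"Items" is deliberately generic: static stimuli (one rating each),
time points of a continuous annotation (the matrix then carries a time
axis with a fixed sample interval), or experimental trials.

## Models

Four predictors consume a training matrix and emit predictions for
requested cells; none of them ever sees a held-out value.

**Mean baseline.** The prediction for cell $(u,i)$ is the mean of the
observed training ratings for item $i$. If the item has no observed rating,
the global training mean is used and the prediction is flagged
`global_mean_fallback`. Any model must beat this to justify its complexity.

**User-based k-nearest neighbors** (`knn_fit()`). User–user similarities are
computed over pairwise-complete items (Pearson by default; Spearman,
Kendall's tau-b and cosine are available). The prediction is the
similarity-weighted average

$$\hat r_{u,i} = \frac{\sum_{v} r_{v,i}\,\mathrm{sim}(u,v)}
                      {\sum_{v}\mathrm{sim}(u,v)}$$

over at most $k$ neighbors with *defined, strictly positive* similarity and
an observed rating for item $i$. Three details matter under sparsity:

* similarities computed from fewer than `min_overlap` shared items (default
  2) are *undefined*, and undefined is never conflated with zero — a user
  with an undefined similarity is simply not a candidate neighbor;
* $k$ is a maximum: when fewer candidates exist, whatever remains is used,
  and the weights renormalize over the used neighbors;
* with no candidate at all the model falls back to the item mean, then to
  the global mean, and the fallback is recorded per prediction.

Ties in neighbor selection break by user order, making predictions
deterministic. Predictions are not clipped to the rating scale.

**Biased non-negative matrix factorization trained by SGD**
(`nnmf_sgd()`). The model is

$$\hat r_{u,i} = \mu + b_u + b_i + q_i^\top p_u,$$

with $\mu$ the global training mean, user/item biases $b_u, b_i$, and
non-negative factor vectors $p_u$ (rows of $W$) and $q_i$ (columns of $H$).
Biases start at zero; $W$ and $H$ start as $|N(0,1)|/f$ draws, which keeps
the initial interaction term at $O(1/f)$ so early predictions are close to
$\mu$. Each iteration shuffles the observed cells (seeded) and for each
cell applies, in sequence,

$$b_i \leftarrow b_i + \gamma(e_{u,i} - \lambda_{bi} b_i), \quad
  b_u \leftarrow b_u + \gamma(e_{u,i} - \lambda_{bu} b_u),$$
$$q_i \leftarrow q_i + \gamma(e_{u,i} p_u - \lambda_{qi} q_i), \quad
  p_u \leftarrow p_u + \gamma(e_{u,i} q_i - \lambda_{pu} p_u),$$

with $e_{u,i} = r_{u,i} - \hat r_{u,i}$, projecting the touched factor
vectors onto the non-negative orthant after each update. Defaults follow
the standard protocol for this model family: $\gamma = 0.001$, $f =
\min(n_\mathrm{users}, n_\mathrm{items})$, all $\lambda = 0$, stopping when
the training MSE changes by at most $10^{-6}$ or after 1000 iterations.
Because the sequential per-cell updates are the hot loop, they are
implemented in C++ (via Rcpp), driven by R's RNG so a seed fixes the run
bit-for-bit. Predictions are unbounded; they are deliberately never clipped
to the scale.

Numerical choices worth stating: the convergence criterion is the absolute
change in mean squared training error between consecutive epochs;
non-negativity is enforced by projection (clipping at zero) rather than
reparameterization; a non-finite training error aborts with a diagnostic
pointing at the learning rate. With $\gamma = 0$ the parameters provably
stay at initialization — a useful degenerate case for testing.

**Multiplicative-update factorization** (`nnmf_mult()`). The classic
two-factor scheme $H \leftarrow H \odot (W^\top V)/(W^\top W H)$,
$W \leftarrow W \odot (V H^\top)/(W H H^\top)$ has no notion of a missing
cell, so unobserved ratings are zero-filled into a dense matrix before
factorization. That zero-filling is the point of including the model: on
sparse data it learns the zeros and its held-out error falls at or below
the mean baseline, a documented negative control. An exact factorization
$V = WH$ supplied as initialization is a fixed point of the updates.

**Chained-equations imputation** (`mice_impute()`), the comparator from the
missing-data literature: initialize missing cells at their item mean, then
for ten rounds visit the incomplete items in a fresh seeded random order
and regress each on all other items over the rows where the target was
originally observed, re-imputing the originally-missing cells. Final
imputations are clipped to the observed data range. Rank-deficient designs
(common when fewer observed rows than items remain) are solved by pivoted
least squares with aliased coefficients dropped, matching pseudo-inverse
behavior; a run *fails explicitly* when an item has no observed rating or
fewer than two observed rows. Failures are a finding, not a bug: the
harness records them per run, and at 10% observed data most runs fail,
which is exactly the behavior this comparator is known for at extreme
sparsity.

## Dilation of sparse time-series

Continuous annotations are strongly autocorrelated: a rating at $t$ says a
lot about $t \pm 2$ s. `dilate()` exploits this by spreading each
*training-observed* rating over a boxcar window of `width_s` seconds
(converted to an odd number of samples; 5/20/60 s at 1 Hz give 5/21/61
samples) before model fitting. Overlapping windows average with equal
weights — a boxcar's weighted average degenerates to the unweighted mean —
observed values are never altered, and windows truncate at the series
edges. The filled cells are flagged "pseudo-observed": models may train on
them, but they are never evaluated against and never enter consensus
summaries. Because dilation runs strictly after masking and reads only
training cells, held-out ratings cannot leak into training; the test suite
proves this by poisoning all held-out cells with a sentinel and verifying
bit-identical training state.

Dilation trades bias for coverage: too wide a kernel (60 s) smears genuine
dynamics and can hurt when data are already dense, which is why the width
is exposed as a harness dimension rather than fixed.

## The evaluation harness

`cross_validate()` masks a given fraction of the observed cells uniformly
at random (not stratified per user — a user can lose everything at high
sparsity, which is precisely when the fallback rules matter), trains every
requested algorithm on the identical training mask (a paired design), and
scores predictions for the held-out cells:

* RMSE is computed per user over that user's held-out cells, normalized by
  the rating-scale range $(r_{\max} - r_{\min})$ — the declared scale when
  present, the observed data range otherwise — giving a score in $[0,1]$
  readable as percent inaccuracy;
* per-user scores are averaged over iterations first, then across users.
  This two-stage aggregation weights every participant equally instead of
  every rating, which penalizes models that are accurate only for
  well-sampled or typical users;
* the aggregated view adds a seeded bootstrap over users (1000 resamples)
  for 95% confidence intervals;
* algorithm failures are retained as failed runs with their diagnostics.

Every mask and model seed derives deterministically from `base_seed`, so a
whole sweep is reproducible from one integer. The long-form output table
(algorithm × dilation × sparsity × iteration × user) is shaped for
downstream mixed-model analysis, which is out of this package's scope.

`isc_summary()` reports the mean and SD of pairwise intersubject Pearson
correlations — the package's one-number description of how much consensus
a dataset has, and the axis along which the three archetypes differ.

## Synthetic archetypes

The generators produce *dense* matrices (sparsity is always induced by
`mask_random()`), are deterministic in configuration and seed, and are
calibrated so their measured intersubject correlation lands in a declared
band; the calibration is checked over seeds 0–9 in the test suite.

**Normed static stimuli** (`gen_normed_images()`, 40 users × 80 items,
target ISC band 0.62–0.82): $r_{u,i} = s_i + b_u + \varepsilon_{u,i}$ with
item signal SD 8, user bias SD 3, noise SD 5 on a 0–100 scale, clipped into
the scale. The signal-to-noise ratio $8^2/(8^2+5^2) = 0.72$ pins the
expected pairwise correlation; consensus is high by construction, so
factorization and mean imputation should be — and are — nearly
interchangeable on these data. The amplitudes are deliberately modest:
high-capacity factorization overfits cell noise on dense data, and the
archetype is meant to sit in the regime where that overfit stays within a
few percent of the scale, as it does for real normed stimuli.

**Continuous bipolar affect** (`gen_affect_timeseries()`, 30 users × 400
time points at 1 Hz, target ISC band 0.10–0.30): each user's series is
$\ell_u z_t + 0.5\,\eta_{u,t} + b_u$ mapped onto 0–100 with gain 12, where
$z_t$ and $\eta_{u,t}$ are AR(1) processes with coefficient 0.9 and the
loadings are drawn from $N(0.8, 1.2^2)$. The wide loading distribution is
the scientific point: a sizable minority of users loads *negatively* on
the shared story signal — people genuinely disagree about the valence of
the same moment — which drives mean consensus down to about 0.2 with a
large spread while keeping every individual series smooth (lag-1
autocorrelation near 0.9). That combination is what makes this archetype
interesting: user-level structure (loadings, biases) is learnable by a
factorization model but invisible to mean imputation, and temporal
smoothness is exploitable by dilation. Latent draws are standardized to
their configured sample moments, so the variance decomposition — and hence
the consensus calibration — holds exactly in every realization rather than
only in expectation.

**Sub-group decisions** (`gen_subgroup_decisions()`, 60 users × 76 items,
target ISC band 0.24–0.44): four latent groups with unequal sizes
(proportions 0.1/0.15/0.35/0.4, echoing moral-strategy phenotypes such as
guilt aversion, inequity aversion, greed and opportunism) each get an
item-response profile sharing 19% of its variance with a common component
(profile SD 16, user bias SD 8, noise SD 8). Within-group correlations
(~0.8) exceed between-group ones (~0.15), and the size-weighted mixture
lands near 0.34. True group labels are attached as a sidecar attribute for
stratified evaluation and are never given to any algorithm.

What the generators do *not* emulate: anchored response styles (pile-ups
at 0, 50, 100 on a visual-analogue scale), non-stationary dynamics,
missingness that is informative rather than random, and item-content
structure. Passing tests on these archetypes therefore demonstrate that
the algorithms and harness behave as specified under controlled consensus,
autocorrelation and group structure — not that any particular error level
will be attained on real data.

## Design choices that were genuinely open

* **Duplicate long-form records are averaged** in `from_long()`: repeated
  measurements of the same user–item cell are treated as noisy reads of one
  value, the same reduction a repeated-conditions design applies to trials.
* **Bias regularization symmetry.** The two bias updates use their own
  penalties ($\lambda_{bu}$ for $b_u$, $\lambda_{bi}$ for $b_i$). Writing
  them with a shared penalty would be an easy transcription slip; symmetry
  with the loss function decides it. Defaults are zero either way.
* **Normalization range.** When no scale is declared the observed range of
  the full matrix is used. A declared scale is preferred because the
  observed range shrinks under heavy masking, which would silently inflate
  normalized errors.
* **Minimum overlap of 2** for correlation-based similarity: a correlation
  over fewer points is undefined by construction. Whether an overlap rule
  should be stricter is left to the `min_overlap` argument.
* **Window truncation at series edges** for dilation (no padding, no window
  shrinking): filled values remain plain means of genuinely observed
  ratings, so they always lie within the user's observed range.
* **Per-update projection** for non-negativity (rather than per-epoch):
  the constraint then holds at every observable moment of training, which
  is also what the in-loop test asserts.
* **Sizes used in the shipped checks.** The acceptance-style tests run the
  archetypes at their default sizes with 5 cross-validation iterations over
  sparsity levels {0.1, 0.5, 0.9} and seeds 0–4; the generator calibration
  sweeps seeds 0–9. These sizes keep the full factorization protocol
  (f = min of the dimensions, up to 1000 epochs) intact while the whole
  suite runs in about a minute.

## Limitations

* The KNN similarity matrix is recomputed per training mask; for thousands
  of users this becomes the dominant cost and would want blocking or
  approximate neighbor search.
* The factorization's default $f = \min(n_\mathrm{users}, n_\mathrm{items})$
  with no regularization is faithful to the reference protocol but is a
  poor default for production use on dense data, where it overfits; tune
  `n_factors` and `lambda` for real deployments.
* `mice_impute()` implements one specific chained-equations variant
  (linear-regression column models, ten rounds, range clipping). It is a
  comparator, not a general imputation engine.
* Normalized error compares models across datasets with different scales
  but says nothing about calibration of individual predictions; the
  per-user prediction–truth correlations in the evaluation table are the
  complementary view.
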