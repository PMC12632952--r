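---
title: "Dimensions of similarity, interference, and pattern transformation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimensions of similarity, interference, and pattern transformation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimshift)
```

# The scientific problem

Memory interference between similar stimuli depends on *which* aspects of
similarity matter, and that can change with learning. `dimshift` implements
an inference chain that (i) estimates visual similarity from behavior and
image-computable metrics, (ii) extracts orthogonal *dimensions* of
similarity from many metrics at once, (iii) quantifies how those dimensions
drive trial-level interference errors at different training levels, and
(iv) asks whether neural (fMRI) pattern similarity preserves or *inverts*
each dimension depending on its current behavioral relevance. Because real
participant data are not bundled, every step is exercised end to end on
synthetic data with planted structure, and the tests quantify how reliably
the pipeline recovers what was planted.

# Similarity estimators

**Memory confusability.** In a cued association test with same-category
foils, choosing the object associated with scene *j* when probed with scene
*i* counts as a confusion of the unordered pair (*i*, *j*), once per test
round. A participant's matrix entry is the fraction of rounds with a
confusion (a pair confused in 2 of 3 rounds scores 0.667); the group matrix
is the participant mean. Confusions are directional events but the matrix
is symmetric: either direction increments the pair.

**Odd-one-out triplet similarity.** For a triplet \{a, b, c\}, choosing c
as "odd" is evidence that a and b are similar: s(a, b) is estimated as the
proportion of trials containing both a and b on which the third item was
chosen. Pairs never co-presented for a participant are missing for that
participant and simply omitted from the group mean (participants are
weighted equally, not by trial count).

**Log transform.** Confusability and triplet proportions are left-skewed
(many rarely-confused pairs), so an optional `log(x + eps)` transform is
provided. The offset is data-adaptive — half the smallest nonzero group
entry — preserving order, defined at zero, and recorded as an attribute.
The natural log is used.

**Exclusions.** Participants are retained when post-test accuracy is at
least 28% and catch-trial accuracy at least 80% (the design's thresholds,
both configurable). The boundary is inclusive: "below 28%" excludes, 28.0%
retains.

**Reliability.** Split-half reliability draws, for each participant count,
random permutations (50 by default) that split the sampled participants
into halves, average matrices within each half, and correlate the
upper-triangle vectors. Per-count summaries average on the Fisher-z scale
and transform back; correlations are clipped at |r| = 1 − 1e−7 before
atanh so degenerate (identical-half) permutations stay finite.

**Recognition d′** uses the equal-variance signal-detection formula
`qnorm(hit) − qnorm(fa)` with rates clipped to [1/(2N), 1 − 1/(2N)], so
perfect performance yields a finite value; the clipping rule is the
standard 1/(2N) correction.

# Image-computable metrics

**SSIM** compares luminance, contrast, and structure in local patches: an
11×11 Gaussian window (σ = 1.5), stabilizers C1 = (0.01·L)², C2 =
(0.03·L)² with dynamic range L = 1 for [0, 1] images, population
(Gaussian-weighted) moments, symmetric boundary handling, and the
window-radius border excluded from the mean — choices that match the widely
used reference implementations, verified against one on frozen fixtures to
1e−6.

**GIST** captures coarse scene layout: intensities are min–max rescaled to
[0, 255] (making the descriptor exactly invariant to global intensity
scaling), log-transformed, whitened and contrast-normalized with a
prefiltering coefficient of 4, passed through a frequency-domain Gabor bank
of 4 scales × 8 orientations, and each filter's output magnitude is
averaged on a 4×4 grid — a 512-dimensional descriptor. The bank follows
the published GIST defaults (amplitude 0.35; radial centers 0.3/1.85^(s−1)
cycles/pixel; angular width term 16·o²/32²). One numerical deviation: the
unpaired Nyquist row/column and the DC bin of the transfer functions are
zeroed. Neither carries oriented energy, and this makes the spectral
support exactly symmetric under 90° rotation, so the rotation-covariance
property (orientation indices shift by 4, grid blocks rotate) holds to
machine precision instead of ~2e−4.

**Embeddings.** Deep-network and text embeddings are *inputs*, not
computations: `read_feature_vectors()` reads an `id, v1..vn` CSV and
`metric_similarity_matrix()` converts vectors to cosine or Pearson
similarity (cosine for unit-normalized embeddings such as CLIP/sentence
embeddings/AlexNet fc7/GIST; Pearson for convolutional layer activations).
Resizing for SSIM/GIST uses plain bilinear interpolation; SSIM is computed
after resizing to a common size.

# Dimension extraction

The per-metric, per-category matrices are vectorized (upper triangle,
canonical category-then-lexicographic order) into a pair × metric table —
552 × 10 in the reference design — and PCA (SVD on the column-standardized
table) extracts orthogonal components. Two open choices were fixed as
follows:

* **Standardization.** Metric columns are z-scored by default
  (correlation-matrix PCA) because the metrics live on incommensurate
  scales (log-confusability vs. cosine similarity); covariance-PCA is
  available via `standardize = FALSE`.
* **Pooling.** The PCA is fit on both categories jointly (all 552 pairs),
  with global (not per-category) standardization.
* **Sign convention.** PCA signs are arbitrary, so each component is
  flipped, deterministically, to load non-negatively on the memory
  confusability metric (falling back to the largest-|loading| metric when
  that loading is numerically zero). This makes extraction reproducible
  and orients both leading components "toward interference".

Degree centrality on a dimension is the signed sum of a scene's pair
scores within its category — signed because PC scores are the similarity
currency, with negative values meaning "less similar than typical". For
use as GLMM predictors, centralities are z-scored within category ×
dimension so slopes are comparable across dimensions; the raw sums are
retained alongside.

# Pattern-similarity scores

For each within-category scene pair, Pearson correlations over voxels are
computed for every ordered pair of distinct runs (56 for 8 runs; same-run
correlations are never used), Fisher z-transformed, and averaged. Each
pair's value is then baselined by subtracting the participant-level mean
over all cross-category pairs (576 for 24+24 scenes), computed the same
way. Both the averaging and the subtraction are done on the z scale
(variance-stabilized arithmetic throughout); a raw-r mode is available
since the scale of the subtraction is an open choice. |r| is clipped at
1 − 1e−7 before atanh — relevant only for noise-free synthetic data.

The *normative alignment* analysis regresses each participant's
high-training pair scores on the mean low-training score of the same pairs
across the participants with the opposite (counterbalanced) assignment —
at least two donors per category are required.

# Mixed-effects models

All drivers use `lme4`; every model with similarity-dimension predictors
includes per-participant random intercepts and random slopes for those
predictors. Linear models use REML with Satterthwaite degrees of freedom
(`lmerTest`); a large-sample z mode (`df_method = "normal"`) is provided
for replicate loops where only signs and error rates matter. Logistic
models use `glmer`; the default `nAGQ = 0` penalized-least-squares
approximation is fast and adequate for slope signs and calibrated
rejection rates, with `nAGQ = 1` (Laplace) available; inference is Wald z.
Singular random-effects fits are refit down a documented ladder
(slopes + intercept → intercept only) and flagged, never silently
accepted. Two-level factors (training level, high-training category) are
coded ±0.5 so main effects are evaluated at the average. Rows with missing
model variables are dropped listwise and counted. Linear contrasts are
1-df Wald F tests on the fitted fixed-effect covariance; for
Satterthwaite fits the denominator df comes from the same approximation,
so a single-term contrast reproduces that term's t².

Interactions with the high-training-category identity are exposed via a
flag (`include_high_cat_interaction`, default off) rather than selected
automatically, since data-driven inclusion is a model-selection step the
drivers surface instead of guessing. When a driver loops over all 10 PCs,
a Bonferroni-adjusted threshold of α = 0.05/10 = 0.005 is applied.

For visualization-faithful summaries, `residualize_and_bin()` regresses
one dimension's scores on the other (OLS with intercept, within category)
and bins the residuals into equal-count quantile bins, mirroring how
binned effects should be displayed when both dimensions are in the model.

# The synthetic-data generator

The generator is first-class, tested code. Its defaults encode the study
design: 2 categories × 24 scenes; 52 participants with the high-training
category alternating across participants; 3 training rounds; 8 exposure
runs; 10 metrics; 2 planted dimensions.

* **Latent structure.** Scene coordinates are drawn per dimension; pair
  scores (negative coordinate distance) are centered, Gram–Schmidt
  orthogonalized across dimensions, and standardized *within category*,
  which also makes the pooled pair-score vectors exactly orthogonal.
* **Metrics** are linear combinations of the planted dimension scores
  (weights in `default_metric_loadings()`, qualitatively mirroring the
  empirical loading pattern: low-level image metrics on dimension 1,
  behavioral/semantic metrics on dimension 2, memory confusability on
  both) plus Gaussian pair-level noise, SD 0.3.
* **Choice models.** Triplet and post-test responses use Luce/softmax
  rules — the simplest generative models whose maximum-likelihood targets
  are the estimators above. The post-test target carries a utility bonus
  (default 4), giving realistic well-above-chance accuracy; with the
  bonus at 0 and flat similarity, accuracy is 1/24 ≈ 4.17%.
* **Training trials** are Bernoulli interference errors with logit =
  intercept + Σ_k slope[k, level]·centrality_k(probe). Defaults plant the
  double dissociation (dimension 1 slope 0.5 only at low training,
  dimension 2 only at high training; intercept −1.7 ≈ a 15% error rate),
  plus a 2% non-competitor rate to exercise the exclusion rule.
* **Voxel patterns.** A scene × scene target correlation matrix combines
  a within-category baseline (0.12), an across-category baseline (0.05),
  and dimension couplings ±0.05 (correlation scale) whose signs invert
  between training levels (negative when the dimension is behaviorally
  relevant). The matrix is repaired to the nearest PSD correlation matrix
  (eigenvalue clipping, diagonal rescale; distortions above a tolerance
  are reported), scene patterns are drawn via the eigendecomposition
  square root over 160 voxels (a realistic high-resolution subfield ROI
  size), and each run adds independent Gaussian noise (SD 0.5, i.e. an
  attenuation of 1/(1+0.25) = 0.8 on observed correlations).
* **Exposure responses** follow an equal-variance signal-detection model
  with true d′ of 0.9 (low) and 1.2 (high training) and a neutral
  criterion.
* **Reproducibility.** One dataset seed; each component generator derives
  a fixed sub-seed from it, so components are independently reproducible
  and the whole dataset is byte-identical across runs.
* Participant-level slope heterogeneity is exposed
  (`participant_slope_sd`) but defaults to 0; the design gives no value.

What the generator does *not* emulate: hemodynamics, image geometry,
motion or physiological confounds, reaction times, session effects, or
inter-participant heterogeneity in the similarity structure itself.
Passing recovery tests therefore shows the *inference chain* is correct
and calibrated under the assumed generative structure — not that real
data satisfy those assumptions.

# Validation strategy and problem sizes

The test suite checks three layers, with problem sizes chosen to keep the
full run comfortably under half an hour on one core:

1. **Exact identities** — design arithmetic (276/552 pairs, 2,024
   triplets, 56 run combinations, 576 baseline pairs, 48 lures), worked
   examples (0.667), and oracle equivalences against independent
   brute-force implementations (centrality, cross-run z, OLS residuals,
   contrast F = t²) at tolerances of 1e−10 to 1e−12.
2. **Distributional checks** — softmax odds ratios, chance-level accuracy,
   binomial bands at 3 SD.
3. **Recovery suites** — with the planted defaults: PCA recovery
   (|r| ≥ 0.9 / 0.8 for the two dimensions at noise 0.3), the behavioral
   double dissociation (sign pattern + contrast rejection in ≥ 90% of 100
   replicates at 50 participants, and ≤ 5% + 3 SD rejection under null
   slopes), and the four-cell neural inversion (≥ 90% of 50 replicates at
   40 participants).

# Known limitations

* GLMM inference is Wald-z on a penalized-least-squares fit by default;
  p-values very close to a decision boundary warrant `nAGQ = 1` or a
  likelihood-ratio test.
* The triplet estimator is consistent for the Luce model but the group
  average ignores trial-count differences across participants (by design,
  matching equal-participant weighting).
* PSD repair slightly distorts extreme target correlation structures; the
  distortion is measured and reported rather than hidden.
* The PCA sign convention assumes the memory-confusability metric is
  present; otherwise the largest-loading rule applies.
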