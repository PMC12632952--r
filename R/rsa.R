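# Cross-run pattern-similarity scoring with a category baseline, and the
# cross-participant normative alignment of low- and high-training structure.

#' Mean cross-run Fisher-z similarity of two scenes
#'
#' Pearson-correlates the two scenes' voxel patterns over every ordered pair
#' of distinct runs (R(R-1) correlations for R runs; 56 for 8 runs), Fisher
#' z-transforms each (clipping |r| at 1 - 1e-7), and returns the mean z.
#' Correlations are never computed within a run. The ordered enumeration
#' covers both directions, so the result is symmetric in scene order.
#'
#' @param patterns A `pattern_set` (see [simulate_voxel_patterns()]) or a
#'   scene x run x voxel array with scene-id dimnames.
#' @param scene_a,scene_b Distinct scene ids.
#' @return Mean Fisher z (NA if every correlation was undefined).
#' @export
cross_run_pair_similarity <- function(patterns, scene_a, scene_b) {
  arr <- if (inherits(patterns, "pattern_set")) patterns$patterns else patterns
  stopifnot(scene_a != scene_b, dim(arr)[2] >= 2)
  R <- dim(arr)[2]
  zs <- c()
  for (ra in seq_len(R)) {
    for (rb in seq_len(R)) {
      if (ra == rb) next
      va <- arr[scene_a, ra, ]
      vb <- arr[scene_b, rb, ]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
        warning("zero-variance pattern vector; correlation skipped")
        next
      }
      zs <- c(zs, fisher_z(stats::cor(va, vb)))
    }
  }
  if (length(zs) == 0) return(NA_real_)
  mean(zs)
}

# All-pairs mean cross-run Fisher-z matrix for one pattern set, computed via
# one scene-run x scene-run correlation matrix and block averaging.
cross_run_z_matrix <- function(arr) {
  n_scene <- dim(arr)[1]; R <- dim(arr)[2]; V <- dim(arr)[3]
  flat <- matrix(aperm(arr, c(3, 2, 1)), nrow = V)  # cols: run fastest, scene
  cors <- stats::cor(flat)
  Z <- fisher_z(cors)
  run_of <- rep(seq_len(R), times = n_scene)
  Z[outer(run_of, run_of, `==`)] <- 0  # same-run combinations excluded
  agg <- kronecker(diag(n_scene), rep(1, R))  # (scene*run) x scene indicator
  block_sum <- t(agg) %*% Z %*% agg
  out <- block_sum / (R * (R - 1))
  dimnames(out) <- list(dimnames(arr)[[1]], dimnames(arr)[[1]])
  diag(out) <- NA
  out
}

#' Pair-level fMRI similarity scores with across-category baseline
#'
#' For one participant x ROI, computes the mean cross-run Fisher-z
#' similarity of every within-category scene pair and subtracts the
#' participant-level baseline: the mean similarity over all cross-category
#' scene pairs (576 pairs for 24+24 scenes). Subtraction is done on the
#' Fisher-z scale by default (`scale = "z"`); `scale = "r"` converts pair
#' values and baseline back to r before subtracting.
#'
#' @param patterns A `pattern_set` with exactly two categories.
#' @param scale `"z"` (default) or `"r"`.
#' @return data.frame of class `similarity_score_table`: `participant`,
#'   `roi`, `category`, `scene_i`, `scene_j`, `training_level`,
#'   `pair_similarity`, `baseline`, `score` (pair minus baseline); 276 rows
#'   per category for the 24-scene design. Attribute `"n_baseline_pairs"`
#'   records the baseline pair count.
#' @export
similarity_scores <- function(patterns, scale = c("z", "r")) {
  scale <- match.arg(scale)
  stopifnot(inherits(patterns, "pattern_set"))
  cats <- unique(patterns$categories)
  if (length(cats) != 2) stop("similarity scores require exactly two categories")
  Z <- cross_run_z_matrix(patterns$patterns)
  ids <- patterns$scene_ids
  cat_of <- stats::setNames(patterns$categories, ids)
  lev_of <- stats::setNames(patterns$training_levels, ids)

  across <- outer(cat_of[ids], cat_of[ids], `!=`)
  vals <- Z[across & upper.tri(Z)]
  n_baseline <- sum(across & upper.tri(Z))
  baseline <- if (scale == "z") mean(vals) else mean(fisher_z_inv(vals))

  stim <- data.frame(scene_id = ids, category = unname(cat_of[ids]),
                     stringsAsFactors = FALSE)
  pairs <- enumerate_pairs(stim)
  pair_sim <- pair_lookup(Z, pairs$scene_i, pairs$scene_j)
  if (scale == "r") pair_sim <- fisher_z_inv(pair_sim)
  if (anyNA(pair_sim)) {
    warning(sum(is.na(pair_sim)), " pair(s) with undefined similarity")
  }
  out <- data.frame(
    participant = patterns$participant, roi = patterns$roi,
    category = pairs$category, scene_i = pairs$scene_i,
    scene_j = pairs$scene_j,
    training_level = unname(lev_of[pairs$scene_i]),
    pair_similarity = pair_sim, baseline = baseline,
    score = pair_sim - baseline, stringsAsFactors = FALSE
  )
  attr(out, "n_baseline_pairs") <- n_baseline
  class(out) <- c("similarity_score_table", "data.frame")
  out
}

#' Cross-participant normative alignment of low- and high-training structure
#'
#' For each participant, the dependent measure is their within-category
#' similarity scores for their high-training category; the predictor for
#' each pair is the mean score for that pair over all participants whose
#' low-training category matches (the counterbalanced assignment guarantees
#' these are other participants).
#'
#' @param score_tables List of [similarity_scores()] tables, one per
#'   participant, with consistent scene ids.
#' @return Long data.frame: `participant`, `category` (the participant's
#'   high-training category), `scene_i`, `scene_j`, `high_score` (DV),
#'   `normative_low_score` (predictor), `n_donors`.
#' @export
normative_alignment <- function(score_tables) {
  all_scores <- do.call(rbind, score_tables)
  all_scores$pair_key <- paste(all_scores$scene_i, all_scores$scene_j)
  low <- all_scores[all_scores$training_level == "low", ]
  norm_tab <- stats::aggregate(score ~ category + pair_key, data = low, mean)
  names(norm_tab)[names(norm_tab) == "score"] <- "normative_low_score"
  donors <- stats::aggregate(participant ~ category, data = low,
                             function(p) length(unique(p)))
  names(donors)[2] <- "n_donors"
  out <- do.call(rbind, lapply(score_tables, function(tab) {
    high <- tab[tab$training_level == "high", ]
    if (nrow(high) == 0) return(NULL)
    cat <- unique(high$category)
    stopifnot(length(cat) == 1)
    nd <- donors$n_donors[donors$category == cat]
    if (length(nd) == 0 || nd < 2) {
      stop("need at least two low-training donors for category ", cat)
    }
    key <- paste(high$scene_i, high$scene_j)
    pred <- norm_tab$normative_low_score[
      match(paste(cat, key), paste(norm_tab$category, norm_tab$pair_key))]
    data.frame(participant = high$participant, category = cat,
               scene_i = high$scene_i, scene_j = high$scene_j,
               high_score = high$score, normative_low_score = pred,
               n_donors = nd, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
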