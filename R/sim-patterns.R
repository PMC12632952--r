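#' Project a symmetric matrix to the nearest positive-semidefinite
#' correlation matrix
#'
#' Eigenvalue clipping at zero followed by rescaling of the diagonal to 1.
#' If the repair moves any entry by more than `tol`, a warning reports the
#' maximum distortion.
#'
#' @param C Symmetric matrix with unit diagonal (the target correlations).
#' @param tol Distortion tolerance for the warning.
#' @return List with `C` (the repaired matrix), `max_distortion`, and
#'   `repaired` (logical: was any eigenvalue clipped).
#' @export
nearest_psd_corr <- function(C, tol = 0.05) {
  check_symmetric(C, tol = 1e-10, what = "target correlation matrix")
  e <- eigen(C, symmetric = TRUE)
  repaired <- any(e$values < 0)
  if (repaired) {
    v <- pmax(e$values, 0)
    C2 <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(pmax(diag(C2), .Machine$double.eps))
    C2 <- C2 / tcrossprod(d)
    diag(C2) <- 1
  } else {
    C2 <- C
  }
  max_distortion <- max(abs(C2 - C))
  if (max_distortion > tol) {
    warning(sprintf(
      "PSD repair distorted the target correlations by up to %.4f (tol %.4f)",
      max_distortion, tol))
  }
  dimnames(C2) <- dimnames(C)
  list(C = C2, max_distortion = max_distortion, repaired = repaired)
}

# Build one participant's scene x scene target correlation matrix from the
# planted structure. Within-category entries couple to the planted pair
# scores with training-level-specific signs; across-category entries are a
# constant baseline.
target_correlation_matrix <- function(latent, config, high_category) {
  stim <- latent$stim
  ids <- stim$scene_id
  C <- matrix(config$baseline_across_corr, length(ids), length(ids),
              dimnames = list(ids, ids))
  dims <- rownames(config$neural_coupling)
  for (cat in unique(stim$category)) {
    level <- if (cat == high_category) "high" else "low"
    cat_ids <- sort(stim$scene_id[stim$category == cat])
    block <- matrix(config$baseline_within_corr, length(cat_ids),
                    length(cat_ids), dimnames = list(cat_ids, cat_ids))
    for (k in seq_along(dims)) {
      D <- latent$dim_scores[[cat]][[paste0("dim", k)]]
      D[is.na(D)] <- 0
      block <- block + config$neural_coupling[dims[k], level] * D
    }
    C[cat_ids, cat_ids] <- block
  }
  diag(C) <- 1
  C
}

#' Simulate multi-run voxel activity patterns with planted correlation
#' structure
#'
#' Builds a scene x scene target correlation matrix whose within-category
#' entries couple to the planted dimension scores (sign and magnitude set by
#' `config$neural_coupling` and the participant's training assignment),
#' repairs it to the nearest PSD correlation matrix, draws scene-level
#' latent patterns with that correlation via an eigendecomposition square
#' root, and adds independent Gaussian run noise to each run's copy.
#'
#' @param latent A [sample_latent_structure()] result.
#' @param config A [sim_config()].
#' @param high_category The participant's high-training category.
#' @param participant Participant id stored in the result.
#' @param roi ROI label stored in the result.
#' @param seed Integer RNG seed.
#' @return A `pattern_set`: list with `patterns` (scene x run x voxel
#'   array, scene-id dimnames), `scene_ids`, `categories`, `run_ids`,
#'   `training_levels` (per scene), `high_category`, `participant`, `roi`,
#'   `target_corr`, and `psd_distortion`.
#' @export
simulate_voxel_patterns <- function(latent, config = sim_config(),
                                    high_category, participant = "p001",
                                    roi = "ROI", seed = 1) {
  stim <- latent$stim
  V <- config$n_voxels
  if (V < nrow(stim)) stop("n_voxels must be >= number of scenes")
  C <- target_correlation_matrix(latent, config, high_category)
  rep_ <- nearest_psd_corr(C, tol = config$psd_tol)

  e <- eigen(rep_$C, symmetric = TRUE)
  M <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))

  n_scene <- nrow(stim)
  with_seed(seed, {
    G <- matrix(stats::rnorm(n_scene * V), n_scene, V)
    P <- M %*% G  # scene x voxel latent patterns, correlation ~ C
    arr <- array(NA_real_, dim = c(n_scene, config$n_runs, V),
                 dimnames = list(stim$scene_id, paste0("run", seq_len(config$n_runs)),
                                 NULL))
    for (r in seq_len(config$n_runs)) {
      noise <- if (config$run_noise_sd > 0) {
        matrix(stats::rnorm(n_scene * V, sd = config$run_noise_sd), n_scene, V)
      } else 0
      arr[, r, ] <- P + noise
    }
    structure(
      list(patterns = arr, scene_ids = stim$scene_id,
           categories = stim$category,
           run_ids = paste0("run", seq_len(config$n_runs)),
           training_levels = ifelse(stim$category == high_category,
                                    "high", "low"),
           high_category = high_category, participant = participant,
           roi = roi, target_corr = rep_$C,
           psd_distortion = rep_$max_distortion),
      class = "pattern_set"
    )
  })
}
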