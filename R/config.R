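#' Default metric-on-dimension loading matrix
#'
#' Ten similarity metrics loading on two orthogonal latent dimensions. The
#' pattern mirrors the study's empirical structure: one dimension is carried
#' mostly by low-level image metrics (VGG max-pooling layers, AlexNet, SSIM)
#' and the other mostly by human behavior and semantic metrics (memory
#' confusability, perceptual judgments, NLP captions, GIST); memory
#' confusability loads positively on both.
#'
#' @return 10 x 2 numeric matrix, rows named by metric, columns `dim1`,
#'   `dim2`.
#' @export
default_metric_loadings <- function() {
  m <- rbind(
    memory    = c(0.50, 0.50),
    percept   = c(0.20, 0.80),
    clip      = c(0.60, 0.40),
    nlp       = c(-0.10, 0.70),
    vgg_mp1   = c(0.80, -0.10),
    vgg_mp3   = c(0.80, -0.15),
    vgg_mp5   = c(0.60, 0.10),
    alexnet   = c(0.80, 0.00),
    gist      = c(-0.20, 0.60),
    ssim      = c(0.70, -0.30)
  )
  colnames(m) <- c("dim1", "dim2")
  m
}

#' Simulation configuration for the synthetic study
#'
#' Bundles every tunable of the synthetic-data generator. Defaults encode the
#' study design: 2 categories x 24 scenes, 3 training rounds, 8 scan runs,
#' two planted orthogonal dimensions, a behavioral double dissociation
#' (dimension 1 drives interference errors under low training only,
#' dimension 2 under high training only) and a mirrored neural inversion
#' (coupling of pattern correlations to dimension 1 is negative under low
#' training and positive under high training; opposite for dimension 2).
#'
#' @param n_participants Number of synthetic participants (52, the fMRI
#'   cohort size).
#' @param n_rounds_training Study-test rounds in the training phase (3).
#' @param n_posttest_rounds Post-test rounds (3 in the behavioral memory
#'   design; 1 in the scanner design).
#' @param n_runs Scan runs in the exposure phase (8).
#' @param n_voxels Voxels per simulated ROI pattern (160, a typical
#'   hippocampal-subfield ROI size at high resolution).
#' @param metric_loadings metrics x dimensions weight matrix; see
#'   [default_metric_loadings()].
#' @param metric_noise_sd SD of the Gaussian pair-level noise added to each
#'   metric (0.3).
#' @param choice_temperature Softmax temperature of the triplet and
#'   confusion choice models (1).
#' @param catch_rate Proportion of triplet catch trials (0.05).
#' @param catch_accuracy Probability a catch trial is answered correctly.
#' @param target_advantage Utility bonus of the target in the post-test
#'   choice model; 4 yields realistic (well-above-chance) accuracy.
#' @param behavior_effects dimensions x training-level matrix of log-odds
#'   slopes of interference errors on standardized degree centrality.
#' @param behavior_intercept Log-odds intercept of the interference-error
#'   model (-1.7, about a 15% error rate).
#' @param noncompetitor_rate Probability a training trial ends in a
#'   non-competitor choice (rare; exercises the exclusion rule).
#' @param neural_coupling dimensions x training-level matrix of signed
#'   coefficients linking planted pair scores to target pattern
#'   correlations (correlation scale).
#' @param baseline_within_corr Baseline within-category target correlation.
#' @param baseline_across_corr Across-category target correlation.
#' @param run_noise_sd SD of independent per-run pattern noise (patterns
#'   have unit signal variance, so 0.5 gives an attenuation of 0.8).
#' @param dprime True exposure-phase discriminability per training level.
#' @param psd_tol Warn if the positive-semidefinite repair of the target
#'   correlation matrix moves any entry by more than this.
#' @param participant_slope_sd SD of participant-level random deviations of
#'   the behavioral slopes (0 by default; the design gives no value).
#' @param n_dims Number of planted latent dimensions (2).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 52,
                       n_rounds_training = 3,
                       n_posttest_rounds = 3,
                       n_runs = 8,
                       n_voxels = 160,
                       metric_loadings = default_metric_loadings(),
                       metric_noise_sd = 0.3,
                       choice_temperature = 1,
                       catch_rate = 0.05,
                       catch_accuracy = 0.95,
                       target_advantage = 4,
                       behavior_effects = NULL,
                       behavior_intercept = -1.7,
                       noncompetitor_rate = 0.02,
                       neural_coupling = NULL,
                       baseline_within_corr = 0.12,
                       baseline_across_corr = 0.05,
                       run_noise_sd = 0.5,
                       dprime = c(low = 0.9, high = 1.2),
                       psd_tol = 0.05,
                       participant_slope_sd = 0,
                       n_dims = 2) {
  dim_names <- paste0("dim", seq_len(n_dims))
  if (is.null(behavior_effects)) {
    # double dissociation: dim1 drives errors under low training only,
    # dim2 under high training only; further dimensions are inert
    behavior_effects <- matrix(0, n_dims, 2,
                               dimnames = list(dim_names, c("low", "high")))
    behavior_effects["dim1", "low"] <- 0.5
    if (n_dims >= 2) behavior_effects["dim2", "high"] <- 0.5
  }
  if (is.null(neural_coupling)) {
    # mirrored inversion: dim1 coupling flips from -c (low) to +c (high),
    # dim2 the reverse
    neural_coupling <- matrix(0, n_dims, 2,
                              dimnames = list(dim_names, c("low", "high")))
    neural_coupling["dim1", ] <- c(-0.05, 0.05)
    if (n_dims >= 2) neural_coupling["dim2", ] <- c(0.05, -0.05)
  }
  cfg <- list(
    n_participants = n_participants,
    n_rounds_training = n_rounds_training,
    n_posttest_rounds = n_posttest_rounds,
    n_runs = n_runs,
    n_voxels = n_voxels,
    metric_loadings = metric_loadings,
    metric_noise_sd = metric_noise_sd,
    choice_temperature = choice_temperature,
    catch_rate = catch_rate,
    catch_accuracy = catch_accuracy,
    target_advantage = target_advantage,
    behavior_effects = behavior_effects,
    behavior_intercept = behavior_intercept,
    noncompetitor_rate = noncompetitor_rate,
    neural_coupling = neural_coupling,
    baseline_within_corr = baseline_within_corr,
    baseline_across_corr = baseline_across_corr,
    run_noise_sd = run_noise_sd,
    dprime = dprime,
    psd_tol = psd_tol,
    participant_slope_sd = participant_slope_sd,
    n_dims = n_dims
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_participants >= 1, cfg$n_rounds_training >= 1,
    cfg$n_posttest_rounds >= 1, cfg$n_runs >= 2, cfg$n_voxels >= 1,
    is.matrix(cfg$metric_loadings), ncol(cfg$metric_loadings) == cfg$n_dims,
    cfg$n_dims >= 1
  )
  if (!(cfg$metric_noise_sd >= 0)) stop("metric_noise_sd must be >= 0")
  if (!(cfg$choice_temperature > 0)) stop("choice_temperature must be > 0")
  if (!(cfg$run_noise_sd >= 0)) stop("run_noise_sd must be >= 0")
  for (nm in c("behavior_effects", "neural_coupling")) {
    m <- cfg[[nm]]
    if (!is.matrix(m) || nrow(m) != cfg$n_dims ||
        !all(c("low", "high") %in% colnames(m))) {
      stop(nm, " must be an n_dims x {low, high} matrix")
    }
  }
  if (abs(cfg$baseline_within_corr) >= 1 || abs(cfg$baseline_across_corr) >= 1) {
    stop("baseline correlations must lie in (-1, 1)")
  }
  invisible(cfg)
}
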