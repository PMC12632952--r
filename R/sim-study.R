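# End-to-end synthetic study generator: every input the analysis pipeline
# consumes, with planted latent structure and training-dependent effects.

#' Simulate a complete synthetic study
#'
#' Generates, from one seed, all inputs of the inference chain: planted
#' latent structure, the 10 noisy metric matrices, odd-one-out triplet
#' responses, post-test confusion records, training-phase trials (with
#' interference errors driven by planted-dimension degree centrality),
#' exposure-phase old/new responses, and per-participant multi-run voxel
#' patterns whose pair correlations couple to the planted dimensions with
#' training-level-dependent signs. The high-training category alternates
#' across participants.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all component generators derive their streams
#'   from it.
#' @param include_triplets,include_posttest,include_training,
#'   include_exposure,include_patterns Toggles for expensive components.
#' @param triplet_participants,triplet_trials Per-category triplet cohort.
#' @return List of class `sim_study` with elements `config`, `stim`,
#'   `latent`, `metric_matrices`, `assignment` (participant ->
#'   high-training category), and the requested response tables
#'   (`triplets`, `posttest`, `training_trials`, `exposure`,
#'   `pattern_sets`), plus `truth` (planted parameters for recovery
#'   checks).
#' @export
simulate_study <- function(config = sim_config(), seed = 1,
                           include_triplets = FALSE,
                           include_posttest = TRUE,
                           include_training = TRUE,
                           include_exposure = FALSE,
                           include_patterns = TRUE,
                           triplet_participants = 50,
                           triplet_trials = 400) {
  stim <- stimulus_set()
  cats <- sort(unique(stim$category))
  latent <- sample_latent_structure(stim, config, seed = seed)
  metric_matrices <- generate_metric_matrices(latent, config, seed = seed)
  assignment <- data.frame(
    participant = sprintf("p%03d", seq_len(config$n_participants)),
    high_category = cats[1 + (seq_len(config$n_participants) %% 2)],
    stringsAsFactors = FALSE
  )

  # behavioral similarity used by the choice models: equal-weight blend of
  # the planted dimensions
  behav_sim <- lapply(stats::setNames(nm = cats), function(cat) {
    ds <- latent$dim_scores[[cat]]
    Reduce(`+`, ds) / sqrt(length(ds))
  })

  out <- list(config = config, stim = stim, latent = latent,
              metric_matrices = metric_matrices, assignment = assignment)

  if (include_triplets) {
    out$triplets <- do.call(rbind, lapply(seq_along(cats), function(ci) {
      simulate_triplet_responses(
        behav_sim[[cats[ci]]], n_participants = triplet_participants,
        trials_per_participant = triplet_trials,
        catch_rate = config$catch_rate, temperature = config$choice_temperature,
        catch_accuracy = config$catch_accuracy, category = cats[ci],
        seed = derive_seed(seed, 10L + ci))
    }))
  }
  if (include_posttest) {
    out$posttest <- do.call(rbind, lapply(seq_along(cats), function(ci) {
      rec <- simulate_posttest_confusions(
        behav_sim[[cats[ci]]], n_participants = config$n_participants,
        n_rounds = config$n_posttest_rounds,
        temperature = config$choice_temperature,
        target_advantage = config$target_advantage, category = cats[ci],
        seed = derive_seed(seed, 20L + ci))
      rec
    }))
  }
  if (include_training) {
    true_cent <- degree_centrality(
      latent$pairs, dimensions = paste0("dim", seq_len(config$n_dims)),
      standardize = TRUE)
    names(true_cent)[names(true_cent) == "dimension"] <- "dimension"
    true_cent$dimension <- true_cent$dimension
    cent_long <- true_cent
    names(cent_long)[names(cent_long) == "centrality"] <- "centrality"
    out$training_trials <- simulate_training_trials(
      cent_long, config, training_mode = "category",
      seed = derive_seed(seed, 30L))
    out$true_centrality <- true_cent
  }
  if (include_exposure) {
    out$exposure <- simulate_exposure_responses(
      stim, config, seed = derive_seed(seed, 40L))
  }
  if (include_patterns) {
    out$pattern_sets <- lapply(seq_len(config$n_participants), function(p) {
      simulate_voxel_patterns(
        latent, config, high_category = assignment$high_category[p],
        participant = assignment$participant[p], roi = "CA3DG",
        seed = derive_seed(seed, 100L + p))
    })
    names(out$pattern_sets) <- assignment$participant
  }

  out$truth <- list(
    seed = seed,
    behavior_effects = config$behavior_effects,
    neural_coupling = config$neural_coupling,
    metric_loadings = config$metric_loadings,
    planted_pairs = latent$pairs,
    assignment = assignment
  )
  class(out) <- "sim_study"
  out
}
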