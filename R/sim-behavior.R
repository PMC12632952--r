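#' Generate noisy per-metric similarity matrices from a planted structure
#'
#' Metric m's pair value is `sum_k loadings[m, k] * dim_k(i, j)` plus
#' Gaussian noise of SD `metric_noise_sd` (one independent draw per
#' unordered pair, so the output stays exactly symmetric).
#'
#' @param latent A [sample_latent_structure()] result.
#' @param config A [sim_config()] supplying `metric_loadings` and
#'   `metric_noise_sd`.
#' @param seed Integer RNG seed.
#' @return Named list (one element per metric) of per-category lists of
#'   symmetric similarity matrices with scene-id dimnames and `NA` diagonal.
#' @export
generate_metric_matrices <- function(latent, config = sim_config(), seed = 1) {
  L <- config$metric_loadings
  if (ncol(L) != config$n_dims) stop("metric_loadings: one column per dimension")
  pairs <- latent$pairs
  dims <- as.matrix(pairs[, paste0("dim", seq_len(config$n_dims)), drop = FALSE])
  metrics <- rownames(L)
  if (is.null(metrics)) metrics <- paste0("metric", seq_len(nrow(L)))

  noise <- with_seed(derive_seed(seed, 2L), {
    matrix(stats::rnorm(nrow(pairs) * nrow(L), sd = config$metric_noise_sd),
           nrow = nrow(pairs))
  })

  out <- lapply(seq_along(metrics), function(m) {
    vals <- as.numeric(dims %*% L[m, ]) + noise[, m]
    lapply(stats::setNames(nm = unique(pairs$category)), function(cat) {
      rows <- pairs$category == cat
      ids <- sort(unique(c(pairs$scene_i[rows], pairs$scene_j[rows])))
      pairs_to_matrix(pairs[rows, ], vals[rows], ids)
    })
  })
  names(out) <- metrics
  out
}

#' Simulate odd-one-out triplet responses
#'
#' Choice model: for a triplet \{a, b, c\}, the probability that c is chosen
#' as the odd one out is proportional to `exp(s(a, b) / temperature)` (Luce
#' choice on the similarity of the retained pair). Triplets are drawn
#' without replacement within participant from all unordered scene triples
#' of one category. A configurable fraction of catch trials (two identical
#' scenes) is answered correctly with probability `catch_accuracy`.
#'
#' @param similarity Symmetric similarity matrix (scene-id dimnames) for one
#'   category.
#' @param n_participants Number of participants.
#' @param trials_per_participant Non-catch trials per participant; capped
#'   (with a warning) at the number of available triplets.
#' @param catch_rate Proportion of additional catch trials.
#' @param temperature Softmax temperature (> 0).
#' @param catch_accuracy Probability a catch trial is answered correctly.
#' @param category Category label stored on the records.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `participant`, `category`, `scene_1`,
#'   `scene_2`, `scene_3`, `chosen` (scene id picked as odd), `catch`
#'   (logical), `catch_correct` (logical, `NA` off catch trials).
#' @export
simulate_triplet_responses <- function(similarity, n_participants,
                                       trials_per_participant,
                                       catch_rate = 0.05,
                                       temperature = 1,
                                       catch_accuracy = 0.95,
                                       category = "cat1",
                                       seed = 1) {
  stopifnot(temperature > 0)
  check_symmetric(similarity, tol = 1e-9, what = "similarity")
  ids <- rownames(similarity)
  n <- length(ids)
  triples <- utils::combn(n, 3)
  n_avail <- ncol(triples)
  if (trials_per_participant > n_avail) {
    warning("trials_per_participant exceeds available triplets (", n_avail,
            "); capped")
    trials_per_participant <- n_avail
  }

  with_seed(derive_seed(seed, 3L), {
    recs <- lapply(seq_len(n_participants), function(p) {
      take <- sample.int(n_avail, trials_per_participant)
      a <- triples[1, take]; b <- triples[2, take]; c3 <- triples[3, take]
      # utility of "x is odd" = s(other two) / temperature
      u <- cbind(similarity[cbind(b, c3)],   # a odd
                 similarity[cbind(a, c3)],   # b odd
                 similarity[cbind(a, b)]) / temperature
      u <- u - apply(u, 1, max)
      pr <- exp(u) / rowSums(exp(u))
      pick <- apply(pr, 1, function(p3) sample.int(3, 1, prob = p3))
      chosen <- cbind(a, b, c3)[cbind(seq_along(pick), pick)]
      rec <- data.frame(
        participant = sprintf("p%03d", p), category = category,
        scene_1 = ids[a], scene_2 = ids[b], scene_3 = ids[c3],
        chosen = ids[chosen], catch = FALSE, catch_correct = NA,
        stringsAsFactors = FALSE
      )
      n_catch <- stats::rbinom(1, trials_per_participant, catch_rate)
      if (n_catch > 0) {
        dup <- sample.int(n, n_catch, replace = TRUE)
        odd <- vapply(dup, function(d) sample(setdiff(seq_len(n), d), 1), 1L)
        ok <- stats::runif(n_catch) < catch_accuracy
        wrong <- ids[dup]  # picking one of the identical pair is an error
        rec_c <- data.frame(
          participant = sprintf("p%03d", p), category = category,
          scene_1 = ids[dup], scene_2 = ids[dup], scene_3 = ids[odd],
          chosen = ifelse(ok, ids[odd], wrong), catch = TRUE,
          catch_correct = ok, stringsAsFactors = FALSE
        )
        rec <- rbind(rec, rec_c)
      }
      rec
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Simulate post-test object-selection responses
#'
#' Each post-test trial presents a probe scene and the objects of all
#' same-category scenes (1 target + n-1 competitors). The choice follows a
#' softmax over utilities: `target_advantage` for the target and
#' `s(probe, j)` for competitor j.
#'
#' @param similarity Symmetric same-category similarity matrix.
#' @param n_participants Number of participants.
#' @param n_rounds Post-test rounds (each probe tested once per round).
#' @param temperature Softmax temperature (> 0).
#' @param target_advantage Utility bonus of the target; `Inf` gives perfect
#'   accuracy.
#' @param category Category label stored on the records.
#' @param seed Integer RNG seed.
#' @return data.frame of confusion records: `participant`, `category`,
#'   `round`, `probe`, `chosen` (scene whose object was selected),
#'   `correct`.
#' @export
simulate_posttest_confusions <- function(similarity, n_participants,
                                         n_rounds = 3, temperature = 1,
                                         target_advantage = 4,
                                         category = "cat1", seed = 1) {
  stopifnot(temperature > 0, n_rounds >= 1)
  check_symmetric(similarity, tol = 1e-9, what = "similarity")
  ids <- rownames(similarity)
  n <- length(ids)

  with_seed(derive_seed(seed, 4L), {
    grid <- expand.grid(probe = seq_len(n), round = seq_len(n_rounds),
                        participant = seq_len(n_participants))
    chosen <- integer(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      i <- grid$probe[r]
      u <- similarity[i, ] / temperature
      if (is.infinite(target_advantage)) {
        chosen[r] <- i
        next
      }
      u[i] <- target_advantage / temperature
      u <- u - max(u)
      chosen[r] <- sample.int(n, 1, prob = exp(u))
    }
    data.frame(
      participant = sprintf("p%03d", grid$participant), category = category,
      round = grid$round, probe = ids[grid$probe], chosen = ids[chosen],
      correct = chosen == grid$probe, stringsAsFactors = FALSE
    )
  })
}

#' Simulate training-phase test trials
#'
#' Each trial (participant x probe scene x round) produces a three-way
#' choice among target, competitor, and non-competitor objects. The
#' interference-error probability follows a logistic model on the probe's
#' standardized degree centrality on each planted dimension, with
#' training-level-specific slopes; non-competitor choices occur at a small
#' fixed rate.
#'
#' @param centrality data.frame with columns `scene_id`, `category`,
#'   `dimension`, `centrality` (standardized), as returned by
#'   [degree_centrality()] on the planted dimensions.
#' @param config A [sim_config()]; uses `behavior_effects`,
#'   `behavior_intercept`, `noncompetitor_rate`, `n_rounds_training`,
#'   `n_participants`, `participant_slope_sd`.
#' @param training_mode `"category"` (level fixed by each participant's
#'   high-training category, alternating across participants) or `"round"`
#'   (round 1 = low, final round = high, interpolated between).
#' @param seed Integer RNG seed.
#' @return data.frame of trial records: `participant`, `round`, `probe`,
#'   `category`, `training_level`, `high_category`, `choice`
#'   (`"target"`/`"competitor"`/`"non_competitor"`), plus the per-dimension
#'   centrality columns used.
#' @export
simulate_training_trials <- function(centrality, config = sim_config(),
                                     training_mode = c("category", "round"),
                                     seed = 1) {
  training_mode <- match.arg(training_mode)
  eff <- config$behavior_effects
  dims <- rownames(eff)
  cats <- sort(unique(centrality$category))
  stopifnot(length(cats) == 2 || training_mode == "round")

  cent_wide <- stats::reshape(
    centrality[, c("scene_id", "category", "dimension", "centrality")],
    idvar = c("scene_id", "category"), timevar = "dimension",
    direction = "wide")
  names(cent_wide) <- sub("^centrality\\.", "", names(cent_wide))
  stopifnot(all(dims %in% names(cent_wide)))

  with_seed(derive_seed(seed, 5L), {
    recs <- lapply(seq_len(config$n_participants), function(p) {
      high_cat <- if (length(cats) == 2) cats[1 + (p %% 2)] else cats[1]
      slope_dev <- stats::rnorm(length(dims), sd = config$participant_slope_sd)
      grid <- expand.grid(scene = seq_len(nrow(cent_wide)),
                          round = seq_len(config$n_rounds_training))
      scene <- cent_wide[grid$scene, ]
      level <- if (training_mode == "category") {
        ifelse(scene$category == high_cat, "high", "low")
      } else {
        # round-graded training: round 1 counts as low, final round as high
        ifelse(grid$round == 1, "low",
               ifelse(grid$round == config$n_rounds_training, "high", "mid"))
      }
      lp <- config$behavior_intercept
      for (k in seq_along(dims)) {
        sl <- ifelse(level == "high", eff[dims[k], "high"],
                     ifelse(level == "low", eff[dims[k], "low"],
                            (eff[dims[k], "low"] + eff[dims[k], "high"]) / 2))
        lp <- lp + (sl + slope_dev[k]) * scene[[dims[k]]]
      }
      p_err <- stats::plogis(lp)
      u <- stats::runif(nrow(grid))
      choice <- ifelse(u < config$noncompetitor_rate, "non_competitor",
                       ifelse(stats::runif(nrow(grid)) < p_err,
                              "competitor", "target"))
      out <- data.frame(
        participant = sprintf("p%03d", p), round = grid$round,
        probe = scene$scene_id, category = scene$category,
        training_level = level, high_category = high_cat,
        choice = choice, stringsAsFactors = FALSE
      )
      for (d in dims) out[[d]] <- scene[[d]]
      out
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Simulate exposure-phase old/new recognition responses
#'
#' Each scan run shows all studied scenes plus a handful of novel lures;
#' participants respond "new" to detected lures. Responses follow an
#' equal-variance signal detection model with training-level-specific true
#' d-prime (`config$dprime`) and criterion midway between the old and new
#' distributions.
#'
#' @param stim A [stimulus_set()] of the studied scenes.
#' @param config A [sim_config()]; uses `dprime`, `n_runs`,
#'   `n_participants`.
#' @param lures_per_run_per_category Novel lures of each category per run
#'   (3 in the design, so 6 lures/run and 48 in total over 8 runs).
#' @param seed Integer RNG seed.
#' @return data.frame with `participant`, `run`, `scene_id`, `category`,
#'   `training_level`, `is_lure`, `responded_new`.
#' @export
simulate_exposure_responses <- function(stim, config = sim_config(),
                                        lures_per_run_per_category = 3,
                                        seed = 1) {
  cats <- sort(unique(stim$category))
  stopifnot(length(cats) == 2)
  with_seed(derive_seed(seed, 6L), {
    recs <- lapply(seq_len(config$n_participants), function(p) {
      high_cat <- cats[1 + (p %% 2)]
      per_run <- lapply(seq_len(config$n_runs), function(r) {
        lure <- do.call(rbind, lapply(cats, function(cat) {
          data.frame(
            scene_id = sprintf("lure_%s_r%d_%d", cat, r,
                               seq_len(lures_per_run_per_category)),
            category = cat, is_lure = TRUE, stringsAsFactors = FALSE)
        }))
        old <- data.frame(scene_id = stim$scene_id, category = stim$category,
                          is_lure = FALSE, stringsAsFactors = FALSE)
        items <- rbind(old, lure)
        items$run <- r
        items
      })
      items <- do.call(rbind, per_run)
      items$training_level <- ifelse(items$category == high_cat, "high", "low")
      d <- unname(config$dprime[items$training_level])
      # evidence of novelty: lures ~ N(d/2, 1), old ~ N(-d/2, 1); criterion 0
      evid <- stats::rnorm(nrow(items), mean = ifelse(items$is_lure, d / 2, -d / 2))
      items$responded_new <- evid > 0
      items$participant <- sprintf("p%03d", p)
      items
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out[, c("participant", "run", "scene_id", "category", "training_level",
            "is_lure", "responded_new")]
  })
}
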