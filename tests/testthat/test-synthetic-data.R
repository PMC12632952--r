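# Planted latent structure and the response generators.

test_that("latent structure has the design pair counts, normalization and orthogonality", {
  stim <- stimulus_set()
  lat <- sample_latent_structure(stim, sim_config(), seed = 11)
  expect_equal(nrow(lat$pairs), 552)
  expect_equal(sum(lat$pairs$category == "beach"), 276)
  for (cat in c("beach", "gazebo")) {
    rows <- lat$pairs$category == cat
    for (d in c("dim1", "dim2")) {
      expect_equal(mean(lat$pairs[[d]][rows]), 0, tolerance = 1e-12)
      expect_equal(sd(lat$pairs[[d]][rows]), 1, tolerance = 1e-12)
    }
  }
  expect_lt(abs(cor(lat$pairs$dim1, lat$pairs$dim2)), 1e-10)
  # symmetric per-category matrices
  m <- lat$dim_scores$beach$dim1
  expect_identical(m, t(m))
})

test_that("latent structure handles minimal and invalid configurations", {
  tiny <- stimulus_set(categories = "c1", scenes_per_category = 3)
  lat <- sample_latent_structure(tiny, sim_config(n_dims = 1,
                                                  metric_loadings = matrix(1)),
                                 seed = 2)
  expect_equal(nrow(lat$pairs), 3)
  expect_equal(mean(lat$pairs$dim1), 0, tolerance = 1e-12)
  expect_equal(sd(lat$pairs$dim1), 1, tolerance = 1e-12)
  # K greater than pairs - 1 is rejected
  expect_error(
    sample_latent_structure(tiny, sim_config(n_dims = 3,
                                             metric_loadings = matrix(1, 1, 3)),
                            seed = 2),
    "invalid config")
})

test_that("generators are deterministic given (config, seed)", {
  cfg <- sim_config(n_participants = 3, n_voxels = 48)
  s1 <- simulate_study(cfg, seed = 5)
  s2 <- simulate_study(cfg, seed = 5)
  expect_identical(s1$latent$pairs, s2$latent$pairs)
  expect_identical(s1$metric_matrices, s2$metric_matrices)
  expect_identical(s1$posttest, s2$posttest)
  expect_identical(s1$training_trials, s2$training_trials)
  expect_identical(s1$pattern_sets[[1]]$patterns, s2$pattern_sets[[1]]$patterns)
  s3 <- simulate_study(cfg, seed = 6)
  expect_false(identical(s1$posttest, s3$posttest))
})

test_that("metric matrices reproduce their zero-noise closed form and stay symmetric", {
  stim <- small_stim(5)
  cfg0 <- sim_config(
    n_dims = 2, metric_noise_sd = 0,
    metric_loadings = rbind(pure1 = c(1, 0), mix = c(0.3, -0.7)))
  lat <- sample_latent_structure(stim, cfg0, seed = 4)
  mats <- generate_metric_matrices(lat, cfg0, seed = 4)
  d1 <- lat$dim_scores$beach$dim1
  expect_equal(mats$pure1$beach, d1, tolerance = 1e-14)
  mixed <- 0.3 * lat$dim_scores$gazebo$dim1 - 0.7 * lat$dim_scores$gazebo$dim2
  expect_equal(mats$mix$gazebo, mixed, tolerance = 1e-14)
  for (m in mats) for (x in m) expect_identical(x, t(x))
})

test_that("a zero-loading metric is uncorrelated with the planted dimensions", {
  stim <- stimulus_set()
  cfg <- sim_config(n_dims = 2, metric_noise_sd = 1,
                    metric_loadings = rbind(null_metric = c(0, 0)))
  lat <- sample_latent_structure(stim, cfg, seed = 9)
  rs <- sapply(1:100, function(s) {
    mats <- generate_metric_matrices(lat, cfg, seed = s)
    v <- unlist(lapply(c("beach", "gazebo"), function(cat) {
      upper_triangle <- mats$null_metric[[cat]]
      upper_triangle[upper.tri(upper_triangle)]
    }))
    cor(v, lat$pairs$dim1)
  })
  expect_lt(mean(abs(rs)), 0.1)
})

test_that("triplet choices follow the Luce rule on the retained pair", {
  # 24 scenes -> 2,024 available triplets; over-asking caps with a warning
  ids <- sprintf("s%02d", 1:24)
  sim <- toy_similarity(ids, rep(0, choose(24, 2)))
  expect_warning(
    rec <- simulate_triplet_responses(sim, 1, choose(24, 3) + 1,
                                      catch_rate = 0, seed = 3),
    "2024|capped")
  expect_equal(nrow(rec), 2024)

  # dominant retained-pair similarity at tiny temperature: c is always odd
  s3 <- toy_similarity(c("a", "b", "c"), c(10, 0, 0))  # s(a,b) large
  rec <- simulate_triplet_responses(s3, 50, 1, catch_rate = 0,
                                    temperature = 1e-3, seed = 8)
  expect_true(all(rec$chosen == "c"))

  # equal similarities at temperature 1: each triplet member odd with p = 1/3
  ids6 <- sprintf("e%d", 1:6)
  s0 <- toy_similarity(ids6, rep(1, choose(6, 2)))
  rec <- simulate_triplet_responses(s0, 100, 20, catch_rate = 0, seed = 12)
  n <- nrow(rec)
  # position-1 scene of each (unordered) triplet record
  phat <- mean(rec$chosen == rec$scene_1)
  expect_lt(abs(phat - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / n))
})

test_that("post-test confusions follow the softmax with target advantage", {
  ids <- c("a", "b", "c")
  # all similarities equal, infinite advantage: perfect accuracy
  s0 <- toy_similarity(ids, c(0, 0, 0))
  rec <- simulate_posttest_confusions(s0, 5, n_rounds = 3,
                                      target_advantage = Inf, seed = 2)
  expect_true(all(rec$correct))

  # competitor odds ratio e for s = 1 vs s = 0 at temperature 1
  s1 <- toy_similarity(ids, c(1, 0, 0))  # s(a,b)=1, s(a,c)=0
  rec <- simulate_posttest_confusions(s1, 120, n_rounds = 30,
                                      target_advantage = 0, seed = 5)
  probe_a <- rec[rec$probe == "a", ]
  odds <- sum(probe_a$chosen == "b") / sum(probe_a$chosen == "c")
  p_b <- exp(1) / (1 + exp(1))
  n_bc <- sum(probe_a$chosen != "a")
  se <- 3 * sqrt(p_b * (1 - p_b) / n_bc)
  expect_lt(abs(sum(probe_a$chosen == "b") / n_bc - p_b), se)
  expect_gt(odds, 1)
})

test_that("training trials match the logistic generator and the design counts", {
  stim <- stimulus_set()
  cfg <- sim_config(
    n_participants = 40,
    behavior_effects = matrix(0, 2, 2,
                              dimnames = list(c("dim1", "dim2"),
                                              c("low", "high"))),
    noncompetitor_rate = 0)
  lat <- sample_latent_structure(stim, cfg, seed = 21)
  cent <- degree_centrality(lat$pairs, c("dim1", "dim2"))
  names(cent)[names(cent) == "dimension"] <- "dimension"
  trials <- simulate_training_trials(cent, cfg, seed = 21)
  # 3 rounds x 48 scenes per participant
  expect_equal(nrow(trials), 40 * 144)
  expect_equal(sum(trials$participant == "p001"), 144)
  # zero slopes: error rate = plogis(intercept) within 3 binomial sd
  p0 <- plogis(cfg$behavior_intercept)
  phat <- mean(trials$choice == "competitor")
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / nrow(trials)))
})

test_that("PSD repair clips eigenvalues, keeps unit diagonal, and reports distortion", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.9
  C[1, 3] <- C[3, 1] <- 0.9
  C[2, 3] <- C[3, 2] <- -0.9  # not PSD
  expect_warning(rep_ <- nearest_psd_corr(C, tol = 0.01), "distort")
  expect_true(rep_$repaired)
  e <- eigen(rep_$C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(e > -1e-10))
  expect_equal(diag(rep_$C), rep(1, 3))
  # an already-PSD matrix is untouched
  C2 <- diag(2); C2[1, 2] <- C2[2, 1] <- 0.3
  rep2 <- nearest_psd_corr(C2)
  expect_false(rep2$repaired)
  expect_equal(rep2$C, C2)
  expect_equal(rep2$max_distortion, 0)
})

test_that("zero-coupling noise-free patterns reproduce the Fisher-z baseline difference", {
  cfg <- sim_config(
    n_participants = 1, n_voxels = 4000, run_noise_sd = 0,
    neural_coupling = matrix(0, 2, 2,
                             dimnames = list(c("dim1", "dim2"),
                                             c("low", "high"))))
  stim <- stimulus_set(scenes_per_category = 6)
  lat <- sample_latent_structure(stim, cfg, seed = 31)
  ps <- simulate_voxel_patterns(lat, cfg, high_category = "beach", seed = 31)
  tab <- similarity_scores(ps)
  expected <- fisher_z(cfg$baseline_within_corr) -
    fisher_z(cfg$baseline_across_corr)
  # voxel-sampling error only (4000 voxels)
  expect_equal(mean(tab$score), expected, tolerance = 0.05)
})

test_that("negative low-training coupling yields a negative pattern-score slope", {
  cfg <- sim_config(
    n_participants = 1, n_voxels = 2000, run_noise_sd = 0.2, psd_tol = 0.1,
    neural_coupling = matrix(c(-0.08, 0, 0, 0), 2, 2,
                             dimnames = list(c("dim1", "dim2"),
                                             c("low", "high"))))
  stim <- stimulus_set()
  lat <- sample_latent_structure(stim, cfg, seed = 41)
  ps <- simulate_voxel_patterns(lat, cfg, high_category = "beach", seed = 41)
  tab <- similarity_scores(ps)
  low <- tab[tab$training_level == "low", ]
  key <- paste(low$scene_i, low$scene_j)
  pk <- paste(lat$pairs$scene_i, lat$pairs$scene_j)
  slope <- coef(lm(low$score ~ lat$pairs$dim1[match(key, pk)]))[2]
  expect_lt(slope, 0)
})

test_that("exposure phase yields the design lure count and training-graded d-prime", {
  stim <- stimulus_set()
  cfg <- sim_config(n_participants = 30)
  rec <- simulate_exposure_responses(stim, cfg, seed = 13)
  one <- rec[rec$participant == "p001", ]
  expect_equal(sum(one$is_lure), 48)          # 6 lures x 8 runs
  expect_equal(nrow(one), 8 * 54)
  dp <- compute_dprime(rec)
  means <- tapply(dp$dprime, dp$training_level, mean)
  expect_gt(means["high"], means["low"])
  expect_equal(unname(means["high"]), 1.2, tolerance = 0.15)
})
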