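# Confusability and triplet similarity estimators, exclusions, reliability,
# d-prime, and interference-error coding.

conf_rec <- function(participant, round, probe, chosen, category = "beach") {
  data.frame(participant = participant, category = category, round = round,
             probe = probe, chosen = chosen,
             correct = probe == chosen, stringsAsFactors = FALSE)
}

test_that("confusability counts rounds per unordered pair and averages over rounds", {
  # beach3 confused with beach7 in 2 of 3 rounds -> 0.667
  rec <- rbind(
    conf_rec("p1", 1, "b3", "b7"),
    conf_rec("p1", 2, "b7", "b3"),   # either direction counts
    conf_rec("p1", 3, "b3", "b3"),
    conf_rec("p1", 1, "b1", "b1"),
    conf_rec("p1", 2, "b1", "b1"),
    conf_rec("p1", 3, "b1", "b1")
  )
  m <- confusability_matrix(rec, n_rounds = 3,
                            scene_ids = c("b1", "b3", "b7"))
  expect_equal(m["b3", "b7"], 2 / 3, tolerance = 1e-12)
  expect_equal(m["b7", "b3"], 2 / 3, tolerance = 1e-12)
  expect_equal(m["b1", "b3"], 0)
  expect_true(is.na(m["b1", "b1"]))
  expect_identical(m, t(m))
})

test_that("group confusability is the participant mean and all-correct gives zeros", {
  # three participants with entries 0, 1/3, 2/3 -> group 1/3
  recs <- rbind(
    conf_rec("p1", 1, "a", "a"), conf_rec("p1", 2, "a", "a"),
    conf_rec("p1", 3, "a", "a"),
    conf_rec("p2", 1, "a", "b"), conf_rec("p2", 2, "a", "a"),
    conf_rec("p2", 3, "a", "a"),
    conf_rec("p3", 1, "a", "b"), conf_rec("p3", 2, "b", "a"),
    conf_rec("p3", 3, "a", "a")
  )
  g <- confusability_matrix(recs, n_rounds = 3, scene_ids = c("a", "b"))
  expect_equal(g["a", "b"], (0 + 1 / 3 + 2 / 3) / 3, tolerance = 1e-12)
  solo <- confusability_matrix(recs[recs$participant == "p1", ], n_rounds = 3,
                               scene_ids = c("a", "b"))
  expect_equal(solo["a", "b"], 0)
})

test_that("confusability is equivariant under scene relabeling", {
  cfg <- sim_config(n_participants = 6)
  stim <- small_stim(5)
  lat <- sample_latent_structure(stim, cfg, seed = 3)
  sim <- lat$dim_scores$beach$dim1
  rec <- simulate_posttest_confusions(sim, 6, n_rounds = 3, category = "beach",
                                      seed = 3)
  m <- confusability_matrix(rec, n_rounds = 3, scene_ids = rownames(sim))
  # relabel scenes by a fixed permutation
  perm <- c(b1 = "z9", b2 = "z1", b3 = "z5", b4 = "z2", b5 = "z7")
  names(perm) <- rownames(sim)
  rec2 <- rec
  rec2$probe <- unname(perm[rec$probe])
  rec2$chosen <- unname(perm[rec$chosen])
  m2 <- confusability_matrix(rec2, n_rounds = 3,
                             scene_ids = sort(unname(perm)))
  expect_equal(m2[perm[rownames(m)], perm[colnames(m)]],
               `dimnames<-`(m, list(unname(perm[rownames(m)]),
                                    unname(perm[colnames(m)]))),
               tolerance = 1e-14)
})

test_that("roster participants with no post-test records are excluded with a warning", {
  rec <- conf_rec("p1", 1, "a", "b")
  expect_warning(
    m <- confusability_matrix(rec, n_rounds = 1, scene_ids = c("a", "b"),
                              participants = c("p1", "p2")),
    "p2")
  expect_equal(m["a", "b"], 1)  # only p1 contributes
})

test_that("triplet similarity is the proportion of 'other chosen' trials", {
  trip <- function(p, s1, s2, s3, chosen) {
    data.frame(participant = p, category = "c", scene_1 = s1, scene_2 = s2,
               scene_3 = s3, chosen = chosen, catch = FALSE,
               catch_correct = NA, stringsAsFactors = FALSE)
  }
  # {a,b,c} seen 4 times, c chosen odd 3 times -> s(a,b) = 0.75
  rec <- rbind(trip("p1", "a", "b", "c", "c"),
               trip("p1", "a", "b", "c", "c"),
               trip("p1", "a", "b", "c", "c"),
               trip("p1", "a", "b", "c", "a"))
  m <- triplet_similarity_matrix(rec)
  expect_equal(m["a", "b"], 0.75)
  # a was chosen once out of 4 -> s(b,c) = 0.25; s(a,c): b never odd -> 0
  expect_equal(m["b", "c"], 0.25)
  expect_equal(m["a", "c"], 0)

  # chooser always picks a member of the pair -> s = 0
  rec2 <- rbind(trip("p1", "a", "b", "c", "a"),
                trip("p1", "a", "b", "c", "b"))
  m2 <- triplet_similarity_matrix(rec2)
  expect_equal(m2["a", "b"], 0)

  # pairs never co-presented stay missing
  rec3 <- trip("p1", "a", "b", "c", "c")
  m3 <- triplet_similarity_matrix(rec3, scene_ids = c("a", "b", "c", "d"))
  expect_true(is.na(m3["a", "d"]))

  # catch trials are excluded before estimation
  rec4 <- rbind(rec,
                data.frame(participant = "p1", category = "c", scene_1 = "a",
                           scene_2 = "a", scene_3 = "b", chosen = "b",
                           catch = TRUE, catch_correct = TRUE,
                           stringsAsFactors = FALSE))
  expect_equal(triplet_similarity_matrix(rec4)["a", "b"], 0.75)
})

test_that("triplet estimator rank-recovers the planted similarity", {
  cfg <- sim_config()
  stim <- stimulus_set(categories = "beach")
  lat <- sample_latent_structure(stim, cfg, seed = 17)
  truth <- lat$dim_scores$beach$dim1
  rec <- simulate_triplet_responses(truth, n_participants = 50,
                                    trials_per_participant = 400,
                                    catch_rate = 0, temperature = 1, seed = 17)
  est <- triplet_similarity_matrix(rec)
  ok <- upper.tri(est) & !is.na(est)
  expect_gt(cor(est[ok], truth[ok], method = "spearman"), 0.8)
})

test_that("log transform uses half the smallest nonzero entry and records it", {
  m <- toy_similarity(c("a", "b", "c"), c(0, 0.2, 0.5))
  g <- confusability_matrix  # silence lint; direct call below
  lt <- dimshift:::log_offset_transform(m)
  expect_equal(attr(lt, "log_offset"), 0.1)
  expect_equal(lt["a", "b"], log(0 + 0.1))
  expect_equal(lt["b", "c"], log(0.5 + 0.1))
})

test_that("exclusion boundaries are inclusive at the threshold", {
  acc <- c(p1 = 0.27, p2 = 0.28, p3 = 0.90)
  res <- apply_exclusions(acc, threshold = 0.28)
  expect_identical(res$retained, c("p2", "p3"))
  expect_identical(res$report$retained, c(FALSE, TRUE, TRUE))
  # catch accuracy 0.79 at threshold 0.80 is excluded
  res2 <- apply_exclusions(c(q1 = 0.79, q2 = 0.80), threshold = 0.80)
  expect_identical(res2$retained, "q2")
  # all pass -> identity
  res3 <- apply_exclusions(c(a = 1, b = 0.5), threshold = 0.28)
  expect_identical(res3$retained, c("a", "b"))
})

test_that("split-half reliability: trivial identities and input validation", {
  m <- toy_similarity(c("a", "b", "c"), c(0.1, 0.5, 0.9))
  mats <- list(p1 = m, p2 = m, p3 = m, p4 = m)
  rc <- split_half_reliability(mats, counts = c(2, 4), n_permutations = 5,
                               seed = 1)
  # z-clipping at |r| = 1 - 1e-7 keeps the summary finite, so identical
  # halves give 1 up to the clipping margin
  expect_equal(rc$mean_r, c(1, 1), tolerance = 1e-6)
  expect_error(split_half_reliability(mats, counts = 3), "even")
  expect_error(split_half_reliability(mats, counts = 6), "exceeds")
  # Fisher round-trip: mean of {0.5, 0.5} is 0.5
  expect_equal(fisher_z_inv(mean(fisher_z(c(0.5, 0.5)))), 0.5,
               tolerance = 1e-12)
  # summary equals brute-force recomputation from stored per-permutation r
  cfg <- sim_config(n_participants = 8)
  stim <- small_stim(5, categories = "beach")
  lat <- sample_latent_structure(stim, cfg, seed = 23)
  rec <- simulate_posttest_confusions(lat$dim_scores$beach$dim1, 8,
                                      n_rounds = 3, seed = 23)
  pm <- confusability_matrix(rec, n_rounds = 3, aggregate = FALSE,
                             scene_ids = rownames(lat$dim_scores$beach$dim1))
  # tiny halves can be all-zero; dropped permutations warn and yield NA
  rc2 <- suppressWarnings(
    split_half_reliability(pm, counts = c(4, 8), n_permutations = 20,
                           seed = 7))
  brute <- apply(rc2$perm_r, 1, function(r) tanh(mean(atanh(r[!is.na(r)]))))
  expect_equal(rc2$mean_r, unname(brute), tolerance = 1e-12)
})

test_that("d-prime matches the normal-quantile oracle and clips extremes", {
  rec <- function(p, lure, new, n) {
    data.frame(participant = p, run = 1, scene_id = sprintf("s%d", seq_len(n)),
               category = "beach", training_level = "low", is_lure = lure,
               responded_new = new, stringsAsFactors = FALSE)
  }
  # hit 0.69, FA 0.31 -> d' = qnorm(.69) - qnorm(.31) ~ 0.9924
  r <- rbind(rec("p1", TRUE, rep(c(TRUE, FALSE), c(69, 31)), 100),
             rec("p1", FALSE, rep(c(TRUE, FALSE), c(31, 69)), 100))
  dp <- compute_dprime(r)
  expect_equal(dp$dprime, qnorm(0.69) - qnorm(0.31), tolerance = 1e-12)
  expect_equal(dp$dprime, 0.9917, tolerance = 1e-4)
  # hit = FA -> 0
  r2 <- rbind(rec("p1", TRUE, rep(c(TRUE, FALSE), c(50, 50)), 100),
              rec("p1", FALSE, rep(c(TRUE, FALSE), c(50, 50)), 100))
  expect_equal(compute_dprime(r2)$dprime, 0)
  # perfect performance with N = 48 per class stays finite via 1/(2N)
  r3 <- rbind(rec("p1", TRUE, rep(TRUE, 48), 48),
              rec("p1", FALSE, rep(FALSE, 48), 48))
  dp3 <- compute_dprime(r3)
  expect_true(is.finite(dp3$dprime))
  expect_equal(dp3$dprime, qnorm(1 - 1 / 96) - qnorm(1 / 96), tolerance = 1e-12)
})

test_that("interference-error coding drops non-competitor and no-response trials", {
  tr <- data.frame(participant = "p1", round = 1, probe = "s1",
                   category = "beach", training_level = "low",
                   high_category = "gazebo",
                   choice = c("target", "competitor", "non_competitor",
                              "target", NA),
                   stringsAsFactors = FALSE)
  out <- code_interference_errors(tr)
  expect_equal(out$error, c(0, 1, 0))
  expect_equal(attr(out, "n_excluded_noncompetitor"), 1)
  expect_equal(attr(out, "n_excluded_noresponse"), 1)
  # all targets -> all-zero outcome
  tr2 <- tr[c(1, 4), ]
  expect_true(all(code_interference_errors(tr2)$error == 0))
})
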