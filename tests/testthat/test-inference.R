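# Mixed-model fitting, linear contrasts, one-sample tests, and the named
# analysis drivers.

test_that("LMM with zero group variance reduces to OLS", {
  set.seed(10)
  d <- data.frame(x = rnorm(120), g = rep(sprintf("g%d", 1:6), each = 20))
  e <- rnorm(120)
  # remove all group structure from the residuals so the random-intercept
  # variance is estimated at its boundary (zero)
  e <- e - ave(e, d$g)
  x_res <- d$x - ave(d$x, d$g)
  d$y <- 0.4 * x_res + e
  res <- fit_lmm(d, y ~ x + (1 | g), df_method = "normal")
  ols <- coef(lm(y ~ x, data = d))
  expect_equal(res$terms$estimate, unname(ols), tolerance = 1e-6)
})

test_that("balanced two-group LMM estimate equals the group mean difference", {
  set.seed(11)
  g <- rep(sprintf("p%d", 1:8), each = 10)
  cond <- rep(c(-0.5, 0.5), times = 40)
  y <- 0.3 * cond + rnorm(80, sd = 0.2) +
    rep(rnorm(8, sd = 0.3), each = 10)
  d <- data.frame(y = y, cond = cond, g = g)
  res <- fit_lmm(d, y ~ cond + (1 | g), df_method = "satterthwaite")
  # balanced design: fixed effect = difference of condition means
  diff_means <- mean(y[cond == 0.5]) - mean(y[cond == -0.5])
  est <- res$terms$estimate[res$terms$term == "cond"]
  expect_equal(est, diff_means, tolerance = 1e-8)
  expect_true(all(res$terms$df > 0))
  expect_identical(res$df_method, "satterthwaite")
})

test_that("singular random-effects fits fall back to intercept-only and are flagged", {
  set.seed(12)
  d <- data.frame(y = rnorm(200), x = rnorm(200),
                  g = rep(sprintf("p%d", 1:10), each = 20))
  res <- fit_lmm(d, y ~ x + (1 + x | g), df_method = "normal")
  expect_true(is.logical(res$fallback_applied))
  if (res$fallback_applied) {
    expect_false(length(lme4::findbars(formula(res$fit))) > 1)
  }
})

test_that("intercept-only logistic GLMM recovers logit of the error rate", {
  set.seed(13)
  n <- 4000
  d <- data.frame(error = rbinom(n, 1, 0.25),
                  g = rep(sprintf("p%d", 1:40), each = 100))
  res <- fit_glmm_logistic(d, error ~ 1 + (1 | g))
  expect_equal(res$terms$estimate[1], qlogis(0.25), tolerance = 0.15)
  expect_identical(res$df_method, "normal")
})

test_that("constant binary outcomes are rejected", {
  d <- data.frame(error = rep(0, 50), g = rep(c("a", "b"), 25))
  expect_error(fit_glmm_logistic(d, error ~ 1 + (1 | g)), "separation")
  d2 <- data.frame(error = rnorm(50), g = rep(c("a", "b"), 25))
  expect_error(fit_glmm_logistic(d2, error ~ 1 + (1 | g)), "binary")
})

test_that("linear contrast reduces to squared t for a single term and matches hand algebra", {
  set.seed(14)
  d <- data.frame(y = rnorm(300), x1 = rnorm(300), x2 = rnorm(300),
                  g = rep(sprintf("p%d", 1:15), each = 20))
  res <- fit_lmm(d, y ~ x1 + x2 + (1 | g), df_method = "satterthwaite")
  ct <- linear_contrast(res, c(x1 = 1))
  t_x1 <- res$terms$statistic[res$terms$term == "x1"]
  expect_equal(ct$F, t_x1^2, tolerance = 1e-10)
  expect_equal(ct$p, res$terms$p[res$terms$term == "x1"], tolerance = 1e-8)
  # hand computation from the coefficient covariance
  w <- c(0, 1, -1)
  V <- as.matrix(vcov(res$fit))
  beta <- lme4::fixef(res$fit)
  F_hand <- (sum(w * beta))^2 / drop(t(w) %*% V %*% w)
  ct2 <- linear_contrast(res, c(x1 = 1, x2 = -1))
  expect_equal(ct2$F, F_hand, tolerance = 1e-10)
  # weight on an absent term errors
  expect_error(linear_contrast(res, c(nope = 1)), "not in the model")
})

test_that("contrast of two identical-estimate terms is approximately zero", {
  set.seed(15)
  # mirror-symmetric design: every row appears with x1 and x2 swapped, so
  # the two fixed-effect estimates are identical by construction
  x1 <- rnorm(200); x2 <- rnorm(200); y <- x1 + x2 + rnorm(200)
  d <- data.frame(x1 = c(x1, x2), x2 = c(x2, x1), y = c(y, y),
                  g = rep(rep(sprintf("p%d", 1:10), each = 20), 2))
  res <- fit_lmm(d, y ~ x1 + x2 + (1 | g), df_method = "normal")
  est <- res$terms$estimate
  expect_equal(est[2], est[3], tolerance = 1e-8)
  ct <- linear_contrast(res, c(x1 = 1, x2 = -1))
  expect_lt(ct$F, 1e-10)
})

test_that("one-sample test matches the textbook formula and handles degenerate input", {
  v <- c(0.12, -0.05, 0.31, 0.07, 0.22)
  res <- one_sample_test(v)
  t_hand <- mean(v) / (sd(v) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # symmetric values about 0
  res2 <- one_sample_test(c(-1, 1, -2, 2))
  expect_equal(res2$t, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-12)
  expect_error(one_sample_test(c(1, 1, 1)), "zero variance")
  expect_error(one_sample_test(1), "two values")
})

test_that("drivers reject datasets missing their required tables", {
  cfg <- sim_config(n_participants = 4, n_voxels = 48)
  study <- simulate_study(cfg, seed = 20, include_patterns = FALSE,
                          include_training = FALSE)
  ds <- build_analysis_dataset(study)
  expect_error(run_analysis(ds, "training_behavior"), "trials")
  expect_error(run_analysis(ds, "fmri_dimensions"), "scores")
  expect_error(run_analysis(ds, "normative"), "normative")
})

test_that("trial exclusion counts propagate from the generator to the driver", {
  cfg <- sim_config(n_participants = 6, noncompetitor_rate = 0.1)
  study <- simulate_study(cfg, seed = 33, include_patterns = FALSE,
                          include_posttest = FALSE)
  ds <- build_analysis_dataset(study)
  truth_nc <- sum(study$training_trials$choice == "non_competitor")
  expect_gt(truth_nc, 0)
  expect_equal(attr(ds$trials, "n_excluded_noncompetitor"), truth_nc)
  expect_equal(nrow(ds$trials), nrow(study$training_trials) - truth_nc)
})

test_that("the confusability driver uses the 552-row layout and Bonferroni family", {
  cfg <- sim_config(n_participants = 4, n_voxels = 48)
  study <- simulate_study(cfg, seed = 21, include_patterns = FALSE,
                          include_training = FALSE)
  ds <- build_analysis_dataset(study)
  rep_ <- run_analysis(ds, "pc_confusability", df_method = "normal")
  expect_equal(rep_$n_rows_per_participant, 552)
  expect_equal(rep_$bonferroni$family_size, 10)
  expect_equal(rep_$bonferroni$alpha_adjusted, 0.005)
  expect_equal(nrow(rep_$pc_effects), 10)
  expect_true(all(c("estimate", "p", "significant") %in% names(rep_$pc_effects)))
})
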