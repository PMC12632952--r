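# Named analysis drivers: each assembles its model-ready table
# from a dataset, fits the specified mixed-effects model(s), and reports
# term tables, contrasts, and correction decisions.

# centered +/- 0.5 coding for two-level factors
code_pm_half <- function(x, high_value) ifelse(x == high_value, 0.5, -0.5)

#' Build the model-ready dataset from a synthetic study
#'
#' Runs the estimation side of the pipeline: assembles the pair-by-metric
#' table, extracts PCA dimensions, computes degree-centrality predictors on
#' the leading components, codes training-trial interference errors, scores
#' the voxel patterns (cross-run Fisher z, category baseline), and builds
#' the normative-alignment table.
#'
#' @param study A [simulate_study()] result.
#' @param n_pcs Number of leading components used as predictors (2).
#' @return List of class `analysis_dataset` with `pair_table` (with PC
#'   scores), `dimensions` (the [extract_dimensions()] result),
#'   `centrality`, `trials` (coded), `scores` (pair-level similarity score
#'   table across participants), `score_summary` (participant x level
#'   means), `normative`, `assignment`, `posttest`, `config`.
#' @export
build_analysis_dataset <- function(study, n_pcs = 2) {
  pair_table <- assemble_pair_table(study$metric_matrices)
  dims <- extract_dimensions(pair_table, anchor_metric = "memory")
  pcs <- paste0("PC", seq_len(n_pcs))
  cent <- degree_centrality(dims$pair_table, dimensions = pcs)
  out <- list(pair_table = dims$pair_table, dimensions = dims,
              centrality = cent, assignment = study$assignment,
              posttest = study$posttest, config = study$config,
              n_pcs = n_pcs)

  if (!is.null(study$training_trials)) {
    trials <- code_interference_errors(study$training_trials)
    cent_wide <- stats::reshape(
      cent[, c("scene_id", "category", "dimension", "centrality")],
      idvar = c("scene_id", "category"), timevar = "dimension",
      direction = "wide")
    names(cent_wide) <- sub("^centrality\\.", "cent_", names(cent_wide))
    n_nc <- attr(trials, "n_excluded_noncompetitor")
    n_nr <- attr(trials, "n_excluded_noresponse")
    trials <- merge(trials, cent_wide,
                    by.x = c("probe", "category"),
                    by.y = c("scene_id", "category"), sort = FALSE)
    attr(trials, "n_excluded_noncompetitor") <- n_nc
    attr(trials, "n_excluded_noresponse") <- n_nr
    out$trials <- trials
  }
  if (!is.null(study$pattern_sets)) {
    tabs <- lapply(study$pattern_sets, similarity_scores)
    scores <- do.call(rbind, tabs)
    key <- paste(scores$category, scores$scene_i, scores$scene_j)
    pt <- dims$pair_table
    pkey <- paste(pt$category, pt$scene_i, pt$scene_j)
    for (pc in pcs) scores[[pc]] <- pt[[pc]][match(key, pkey)]
    for (m in c("memory", "percept")) {
      if (m %in% names(pt)) scores[[m]] <- pt[[m]][match(key, pkey)]
    }
    scores$high_category <- study$assignment$high_category[
      match(scores$participant, study$assignment$participant)]
    rownames(scores) <- NULL
    out$scores <- scores
    out$score_tables <- tabs
    agg <- stats::aggregate(score ~ participant + training_level,
                            data = scores, mean)
    agg$high_category <- study$assignment$high_category[
      match(agg$participant, study$assignment$participant)]
    out$score_summary <- agg
    out$normative <- normative_alignment(tabs)
  }
  class(out) <- c("analysis_dataset", "list")
  out
}

# Per-participant 552-row confusability layout: 0/1 per within-category
# pair (1 if the pair was confused in any post-test round), joined with PC
# scores and training coding.
confusability_pair_layout <- function(dataset) {
  if (is.null(dataset$posttest)) stop("missing required table: posttest")
  pt <- dataset$pair_table
  pcs <- paste0("PC", seq_len(dataset$n_pcs))
  conf <- dataset$posttest[dataset$posttest$probe != dataset$posttest$chosen, ]
  conf_key <- unique(paste(conf$participant,
                           pmin(conf$probe, conf$chosen),
                           pmax(conf$probe, conf$chosen)))
  out <- do.call(rbind, lapply(unique(dataset$posttest$participant), function(p) {
    tab <- pt[, c("category", "scene_i", "scene_j",
                  grep("^PC", names(pt), value = TRUE))]
    tab$participant <- p
    tab$confused <- as.integer(
      paste(p, tab$scene_i, tab$scene_j) %in% conf_key)
    tab
  }))
  out$high_category <- dataset$assignment$high_category[
    match(out$participant, dataset$assignment$participant)]
  out$training <- code_pm_half(
    ifelse(out$category == out$high_category, "high", "low"), "high")
  out$high_cat_code <- code_pm_half(out$high_category,
                                    sort(unique(out$high_category))[2])
  rownames(out) <- NULL
  out
}

#' Run a named analysis of the study
#'
#' Drivers for the study's model specifications:
#' \describe{
#'   \item{pc_confusability}{Per-participant 552-row pair layout with 0/1
#'     post-test confusability as DV; a separate linear mixed model per PC
#'     (PC score + training level + high-training category, random
#'     intercept and PC slope per participant), with a Bonferroni-adjusted
#'     threshold of alpha = 0.005 over the 10 components.}
#'   \item{training_behavior}{Trial-level logistic mixed model of
#'     interference errors on PC1/PC2 degree centrality, training level,
#'     their interactions, and round; linear contrast on the difference of
#'     the two centrality-by-training interactions; per-level follow-up
#'     fits.}
#'   \item{fmri_training}{Participant x training-level mean similarity
#'     scores: linear mixed model with training level and high-training
#'     category, plus per-level one-sample t-tests against zero.}
#'   \item{fmri_dimensions}{Pair-level similarity scores on PC1, PC2,
#'     training level and their interactions (random intercept + PC slopes
#'     per participant); per-level follow-up fits.}
#'   \item{memory_vs_perceptual}{As fmri_dimensions but with the raw memory
#'     confusability and perceptual similarity metrics (z-scored) as the
#'     continuous predictors.}
#'   \item{normative}{Participant high-training pair scores on the
#'     normative low-training scores from counterbalanced other
#'     participants.}
#' }
#'
#' @param dataset A [build_analysis_dataset()] result.
#' @param analysis One of the names above.
#' @param df_method Passed to [fit_lmm()] (`"satterthwaite"` or the faster
#'   `"normal"`).
#' @param alpha Nominal significance level (0.05).
#' @param n_pcs_loop For `pc_confusability`: number of PCs to loop over
#'   (family size for Bonferroni; 10 in the design).
#' @param include_high_cat_interaction Interact the high-training-category
#'   identity with the other fixed effects (off by default; surfaced in
#'   the report rather than guessed).
#' @param include_subsets For `training_behavior` and `fmri_dimensions`:
#'   also fit the per-training-level follow-up models (default TRUE; turn
#'   off in replicate loops that only use the full model).
#' @return A structured report list; contents vary by analysis but always
#'   include `models` (named `model_result`s or term tables) and
#'   `analysis`.
#' @export
run_analysis <- function(dataset,
                         analysis = c("pc_confusability", "training_behavior",
                                      "fmri_training", "fmri_dimensions",
                                      "memory_vs_perceptual", "normative"),
                         df_method = "satterthwaite", alpha = 0.05,
                         n_pcs_loop = NULL,
                         include_high_cat_interaction = FALSE,
                         include_subsets = TRUE) {
  analysis <- match.arg(analysis)
  switch(analysis,
    pc_confusability = {
      layout <- confusability_pair_layout(dataset)
      pcs <- grep("^PC", names(layout), value = TRUE)
      if (!is.null(n_pcs_loop)) pcs <- pcs[seq_len(n_pcs_loop)]
      m <- length(pcs)
      thr <- alpha / m
      models <- lapply(stats::setNames(nm = pcs), function(pc) {
        f <- stats::as.formula(paste(
          "confused ~", pc, "+ training + high_cat_code + (1 +", pc,
          "| participant)"))
        fit_lmm(layout, f, df_method = df_method)
      })
      term_tab <- do.call(rbind, lapply(pcs, function(pc) {
        tt <- models[[pc]]$terms
        row <- tt[tt$term == pc, ]
        row$pc <- pc
        row$significant <- row$p < thr
        row
      }))
      list(analysis = analysis, models = models, pc_effects = term_tab,
           bonferroni = list(family_size = m, alpha_adjusted = thr),
           n_rows_per_participant = sum(layout$participant ==
                                          layout$participant[1]))
    },
    training_behavior = {
      if (is.null(dataset$trials)) stop("missing required table: trials")
      tr <- dataset$trials
      tr$training <- code_pm_half(tr$training_level, "high")
      tr$high_cat_code <- code_pm_half(tr$high_category,
                                       sort(unique(tr$high_category))[2])
      tr$round_c <- tr$round - mean(tr$round)
      f <- error ~ (cent_PC1 + cent_PC2) * training + round_c +
        high_cat_code + (1 + cent_PC1 + cent_PC2 | participant)
      if (include_high_cat_interaction) {
        f <- error ~ (cent_PC1 + cent_PC2) * training * high_cat_code +
          round_c + (1 + cent_PC1 + cent_PC2 | participant)
      }
      full <- fit_glmm_logistic(tr, f)
      contrast <- linear_contrast(
        full, c("cent_PC1:training" = 1, "cent_PC2:training" = -1))
      subsets <- if (!include_subsets) NULL else
        lapply(stats::setNames(nm = c("low", "high")), function(lev) {
          fit_glmm_logistic(
            tr[tr$training_level == lev, ],
            error ~ cent_PC1 + cent_PC2 + round_c + high_cat_code +
              (1 + cent_PC1 + cent_PC2 | participant))
        })
      list(analysis = analysis, models = list(full = full), contrast = contrast,
           subsets = subsets,
           n_excluded_noncompetitor = attr(dataset$trials,
                                           "n_excluded_noncompetitor"))
    },
    fmri_training = {
      if (is.null(dataset$score_summary)) stop("missing required table: scores")
      ss <- dataset$score_summary
      ss$training <- code_pm_half(ss$training_level, "high")
      ss$high_cat_code <- code_pm_half(ss$high_category,
                                       sort(unique(ss$high_category))[2])
      full <- fit_lmm(ss, score ~ training + high_cat_code + (1 | participant),
                      df_method = df_method)
      by_level <- lapply(stats::setNames(nm = c("low", "high")), function(lev) {
        one_sample_test(ss$score[ss$training_level == lev])
      })
      list(analysis = analysis, models = list(full = full),
           one_sample = by_level)
    },
    fmri_dimensions = {
      if (is.null(dataset$scores)) stop("missing required table: scores")
      sc <- dataset$scores
      sc$training <- code_pm_half(sc$training_level, "high")
      sc$high_cat_code <- code_pm_half(sc$high_category,
                                       sort(unique(sc$high_category))[2])
      f <- score ~ (PC1 + PC2) * training + high_cat_code +
        (1 + PC1 + PC2 | participant)
      if (include_high_cat_interaction) {
        f <- score ~ (PC1 + PC2) * training * high_cat_code +
          (1 + PC1 + PC2 | participant)
      }
      full <- fit_lmm(sc, f, df_method = df_method)
      subsets <- if (!include_subsets) NULL else
        lapply(stats::setNames(nm = c("low", "high")), function(lev) {
          fit_lmm(sc[sc$training_level == lev, ],
                  score ~ PC1 + PC2 + high_cat_code +
                    (1 + PC1 + PC2 | participant),
                  df_method = df_method)
        })
      list(analysis = analysis, models = list(full = full), subsets = subsets)
    },
    memory_vs_perceptual = {
      if (is.null(dataset$scores)) stop("missing required table: scores")
      sc <- dataset$scores
      if (!all(c("memory", "percept") %in% names(sc))) {
        stop("missing required columns: memory, percept")
      }
      sc$memory_z <- as.numeric(scale(sc$memory))
      sc$percept_z <- as.numeric(scale(sc$percept))
      sc$training <- code_pm_half(sc$training_level, "high")
      sc$high_cat_code <- code_pm_half(sc$high_category,
                                       sort(unique(sc$high_category))[2])
      full <- fit_lmm(
        sc, score ~ (memory_z + percept_z) * training + high_cat_code +
          (1 + memory_z + percept_z | participant),
        df_method = df_method)
      list(analysis = analysis, models = list(full = full))
    },
    normative = {
      if (is.null(dataset$normative)) stop("missing required table: normative")
      nt <- dataset$normative
      nt$high_cat_code <- code_pm_half(nt$category,
                                       sort(unique(nt$category))[2])
      full <- fit_lmm(
        nt, high_score ~ normative_low_score + high_cat_code +
          (1 + normative_low_score | participant),
        df_method = df_method)
      list(analysis = analysis, models = list(full = full))
    }
  )
}
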