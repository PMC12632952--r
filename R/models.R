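# Mixed-effects model fitting, linear contrasts, and one-sample tests.

# Strip random-effect terms down the documented fallback ladder:
# slopes + intercept -> intercept only.
simplify_random_formula <- function(formula) {
  bars <- lme4::findbars(formula)
  if (length(bars) == 0) return(NULL)
  groups <- vapply(bars, function(b) deparse(b[[3]]), character(1))
  fixed <- lme4::nobars(formula)
  re <- paste(sprintf("(1 | %s)", unique(groups)), collapse = " + ")
  stats::as.formula(paste(deparse(fixed, width.cutoff = 500), "+", re),
                    env = environment(formula))
}

result_terms <- function(coefs, df_method) {
  data.frame(
    term = rownames(coefs),
    estimate = coefs[, "Estimate"],
    se = coefs[, "Std. Error"],
    df = if ("df" %in% colnames(coefs)) coefs[, "df"] else Inf,
    statistic = coefs[, grep("value", colnames(coefs))[1]],
    p = coefs[, grep("^Pr", colnames(coefs))[1]],
    df_method = df_method,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fit a linear mixed-effects model
#'
#' REML fit via `lmerTest::lmer` with Satterthwaite degrees of freedom by
#' default (`df_method = "normal"` uses plain `lme4::lmer` and a
#' large-sample z reference, which is much faster in replicate loops).
#' Singular random-effects fits are refit down the fallback ladder
#' (slopes + intercept -> intercept only) and flagged.
#'
#' @param data Model data (complete cases; rows with missing values in the
#'   model variables are dropped listwise and counted).
#' @param formula `lme4`-style formula with random-effect terms.
#' @param df_method `"satterthwaite"` (default) or `"normal"`.
#' @param allow_fallback Refit with intercept-only random effects on a
#'   singular fit (default TRUE).
#' @return List of class `model_result`: `terms` (term table with estimate,
#'   se, df, statistic, p), `fit`, `singular`, `fallback_applied`,
#'   `converged`, `df_method`, `n_obs`, `n_dropped`, `logLik`.
#' @export
fit_lmm <- function(data, formula, df_method = c("satterthwaite", "normal"),
                    allow_fallback = TRUE) {
  df_method <- match.arg(df_method)
  vars <- all.vars(formula)
  cc <- stats::complete.cases(data[, intersect(vars, names(data)), drop = FALSE])
  n_dropped <- sum(!cc)
  data <- data[cc, , drop = FALSE]

  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = (df_method == "satterthwaite"))
  fit_one <- function(f) {
    if (df_method == "satterthwaite") {
      lmerTest::lmer(f, data = data, REML = TRUE, control = ctrl)
    } else {
      lme4::lmer(f, data = data, REML = TRUE, control = ctrl)
    }
  }
  fit <- suppressMessages(fit_one(formula))
  singular <- lme4::isSingular(fit)
  fallback <- FALSE
  if (singular && allow_fallback) {
    f2 <- simplify_random_formula(formula)
    if (!is.null(f2) && !identical(deparse(f2), deparse(formula))) {
      fit2 <- suppressMessages(fit_one(f2))
      fit <- fit2
      fallback <- TRUE
      singular <- lme4::isSingular(fit)
    }
  }
  coefs <- stats::coef(summary(fit))
  if (df_method == "normal") {
    # z reference on the t values
    p <- 2 * stats::pnorm(-abs(coefs[, "t value"]))
    coefs <- cbind(coefs, df = Inf, `Pr(>|t|)` = p)
  }
  structure(
    list(terms = result_terms(coefs, df_method), fit = fit,
         singular = singular, fallback_applied = fallback,
         converged = length(fit@optinfo$conv$lme4$messages) == 0,
         df_method = df_method, n_obs = nrow(data), n_dropped = n_dropped,
         logLik = as.numeric(stats::logLik(fit))),
    class = "model_result"
  )
}

#' Fit a logistic mixed-effects model
#'
#' Logit-link GLMM via `lme4::glmer`. The default `nAGQ = 0` uses the fast
#' penalized-least-squares approximation, appropriate for the
#' replicate-based recovery and calibration suites; `nAGQ = 1` gives the
#' Laplace approximation. Inference is Wald z. The same singular-fit
#' fallback ladder as [fit_lmm()] applies.
#'
#' @param data Model data (listwise-deleted, counted).
#' @param formula `lme4`-style formula; the outcome must be binary 0/1.
#' @param nAGQ Integration setting passed to `glmer` (0 default).
#' @param allow_fallback Refit intercept-only random effects on singularity.
#' @return A `model_result` (see [fit_lmm()]); `df_method` is `"normal"`
#'   and the approximation is recorded in `method`.
#' @export
fit_glmm_logistic <- function(data, formula, nAGQ = 0L, allow_fallback = TRUE) {
  vars <- all.vars(formula)
  cc <- stats::complete.cases(data[, intersect(vars, names(data)), drop = FALSE])
  n_dropped <- sum(!cc)
  data <- data[cc, , drop = FALSE]
  y <- stats::model.response(stats::model.frame(lme4::nobars(formula), data))
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (stats::var(y) == 0) {
    stop("complete separation: outcome is constant")
  }

  ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                             calc.derivs = FALSE)
  fit_one <- function(f) {
    lme4::glmer(f, data = data, family = stats::binomial(), nAGQ = nAGQ,
                control = ctrl)
  }
  fit <- suppressMessages(fit_one(formula))
  singular <- lme4::isSingular(fit)
  fallback <- FALSE
  if (singular && allow_fallback) {
    f2 <- simplify_random_formula(formula)
    if (!is.null(f2) && !identical(deparse(f2), deparse(formula))) {
      fit <- suppressMessages(fit_one(f2))
      fallback <- TRUE
      singular <- lme4::isSingular(fit)
    }
  }
  coefs <- stats::coef(summary(fit))
  if (any(coefs[, "Std. Error"] > 50)) {
    stop("possible complete separation: huge standard error for ",
         paste(rownames(coefs)[coefs[, "Std. Error"] > 50], collapse = ", "))
  }
  structure(
    list(terms = result_terms(coefs, "normal"), fit = fit,
         singular = singular, fallback_applied = fallback,
         converged = length(fit@optinfo$conv$lme4$messages) == 0,
         df_method = "normal",
         method = if (nAGQ == 0) "PLS (nAGQ = 0)" else
           sprintf("Laplace-type (nAGQ = %d)", nAGQ),
         n_obs = nrow(data), n_dropped = n_dropped,
         logLik = as.numeric(stats::logLik(fit))),
    class = "model_result"
  )
}

#' Wald linear contrast on fixed effects
#'
#' Tests `H0: w' beta = 0` with a 1-numerator-df Wald F on the fitted
#' fixed-effect covariance. For Satterthwaite-fitted linear models the
#' denominator df comes from `lmerTest::contest1D`; otherwise a large-sample
#' chi-square reference is used (F with infinite denominator df). With a
#' weight vector selecting a single term, F equals that term's squared t.
#'
#' @param result A `model_result`.
#' @param weights Named numeric vector of contrast weights; names must match
#'   fitted fixed-effect terms (unnamed terms get weight 0).
#' @return List with `estimate` (w' beta), `se`, `F`, `df1`, `df2`, `p`.
#' @export
linear_contrast <- function(result, weights) {
  fit <- result$fit
  beta <- lme4::fixef(fit)
  if (is.null(names(weights))) {
    stop("weights must be named after fixed-effect terms")
  }
  missing_terms <- setdiff(names(weights), names(beta))
  if (length(missing_terms) > 0) {
    stop("weight on a term not in the model: ",
         paste(missing_terms, collapse = ", "))
  }
  w <- stats::setNames(numeric(length(beta)), names(beta))
  w[names(weights)] <- weights
  V <- as.matrix(stats::vcov(fit))
  est <- sum(w * beta)
  se <- sqrt(drop(t(w) %*% V %*% w))
  Fval <- (est / se)^2
  if (result$df_method == "satterthwaite" && inherits(fit, "lmerModLmerTest")) {
    ct <- lmerTest::contest1D(fit, w)
    df2 <- ct$df
    p <- ct$`Pr(>|t|)`
  } else {
    df2 <- Inf
    p <- stats::pchisq(Fval, df = 1, lower.tail = FALSE)
  }
  list(estimate = est, se = se, F = Fval, df1 = 1, df2 = df2, p = p)
}

#' Two-tailed one-sample t-test
#'
#' @param values Numeric vector (n >= 2, nonzero variance).
#' @param null Null value (default 0).
#' @return List with `t`, `df`, `p`, `mean`, `n`.
#' @export
one_sample_test <- function(values, null = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least two values")
  if (stats::sd(values) == 0) stop("zero variance: t undefined")
  tt <- stats::t.test(values, mu = null)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(values), n = length(values))
}
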