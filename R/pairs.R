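# Pair x metric table assembly and PCA extraction of similarity dimensions.

#' Assemble the within-category pair-by-metric table
#'
#' Vectorizes each metric's per-category similarity matrix (upper triangle)
#' and stacks them into one table with a deterministic row order: category,
#' then lexicographic scene-id pairs. With 2 categories x 24 scenes and 10
#' metrics this yields the canonical 552 x 10 layout.
#'
#' @param metric_matrices Named list, one element per metric, each a named
#'   per-category list of symmetric matrices (as produced by
#'   [generate_metric_matrices()] or [metric_similarity_matrix()]).
#' @return data.frame of class `pair_table`: `category`, `scene_i`,
#'   `scene_j`, then one numeric column per metric.
#' @export
assemble_pair_table <- function(metric_matrices) {
  metrics <- names(metric_matrices)
  stopifnot(length(metrics) >= 1)
  cats <- names(metric_matrices[[1]])
  for (m in metrics) {
    if (!setequal(names(metric_matrices[[m]]), cats)) {
      stop("metric '", m, "' is missing a category")
    }
  }
  cats <- sort(cats)
  base <- do.call(rbind, lapply(cats, function(cat) {
    ids <- sort(rownames(metric_matrices[[1]][[cat]]))
    idx <- utils::combn(length(ids), 2)
    data.frame(category = cat, scene_i = ids[idx[1, ]], scene_j = ids[idx[2, ]],
               stringsAsFactors = FALSE)
  }))
  for (m in metrics) {
    vals <- unlist(lapply(cats, function(cat) {
      mat <- metric_matrices[[m]][[cat]]
      check_symmetric(mat, tol = 1e-12, what = paste0("metric '", m, "'"))
      ids <- sort(rownames(mat))
      mat <- mat[ids, ids]
      rows <- base$category == cat
      pair_lookup(mat, base$scene_i[rows], base$scene_j[rows])
    }), use.names = FALSE)
    if (anyNA(vals)) stop("metric '", m, "' has missing pair entries")
    base[[m]] <- vals
  }
  rownames(base) <- NULL
  class(base) <- c("pair_table", "data.frame")
  base
}

#' Extract orthogonal similarity dimensions by PCA
#'
#' SVD-based PCA of the pair-by-metric table. Columns are centered and (by
#' default) z-scored, since the metrics live on incommensurate scales.
#' Component signs are fixed deterministically: each component's loading on
#' `anchor_metric` (the memory-confusability metric in the study design) is
#' made non-negative; if that loading is (numerically) zero, the metric
#' with the largest absolute loading is made positive instead.
#'
#' @param pair_table A [assemble_pair_table()] result.
#' @param n_components Number of components to retain (default: all).
#' @param standardize z-score each metric column before PCA (default TRUE).
#' @param anchor_metric Metric name used for the sign convention.
#' @return List of class `dimension_scores`: `loadings` (metrics x
#'   components, unit-norm columns), `explained_variance_pct`, `scores`
#'   (pairs x components), `pair_table` (input with `PC<k>` columns
#'   appended), `center`, `scale`.
#' @export
extract_dimensions <- function(pair_table, n_components = NULL,
                               standardize = TRUE, anchor_metric = "memory") {
  meta_cols <- c("category", "scene_i", "scene_j")
  metrics <- setdiff(names(pair_table), c(meta_cols, grep("^PC", names(pair_table),
                                                          value = TRUE)))
  X <- as.matrix(pair_table[, metrics, drop = FALSE])
  if (anyNA(X)) stop("pair table has missing values")
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance metric under standardization: ",
           paste(metrics[sds == 0], collapse = ", "))
    }
  }
  n_max <- min(nrow(X) - 1, ncol(X))
  if (is.null(n_components)) n_components <- min(ncol(X), n_max)
  stopifnot(n_components >= 1, n_components <= n_max)

  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  total_var <- sum(pc$sdev^2)
  expl <- 100 * pc$sdev^2 / total_var

  loadings <- pc$rotation
  scores <- pc$x
  # deterministic sign convention
  for (k in seq_len(ncol(loadings))) {
    l <- loadings[, k]
    flip <- if (anchor_metric %in% metrics && abs(l[anchor_metric]) > 1e-10) {
      l[anchor_metric] < 0
    } else {
      l[which.max(abs(l))] < 0
    }
    if (flip) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  keep <- seq_len(n_components)
  out_tab <- pair_table
  for (k in keep) out_tab[[paste0("PC", k)]] <- scores[, k]
  structure(
    list(loadings = loadings[, keep, drop = FALSE],
         explained_variance_pct = expl,
         scores = scores[, keep, drop = FALSE],
         pair_table = out_tab,
         center = pc$center,
         scale = if (standardize) pc$scale else NULL,
         standardize = standardize,
         anchor_metric = anchor_metric),
    class = "dimension_scores"
  )
}

#' Residualize one score on another and bin for visualization
#'
#' Computes the ordinary-least-squares residual (with intercept) of `x` on
#' `y` within each category, then assigns equal-count quantile bins of the
#' residualized scores. This mirrors the visualization rule of plotting one
#' dimension's effect while controlling for the other.
#'
#' @param x Numeric scores to residualize and bin.
#' @param y Numeric covariate regressed out of `x`.
#' @param category Category labels (recycled `"all"` if NULL).
#' @param n_bins Number of equal-count bins (>= 2).
#' @return List with `residual`, `bin` (integer assignments, per category),
#'   `bin_means` (data.frame category, bin, mean_residual, n).
#' @export
residualize_and_bin <- function(x, y, n_bins = 5, category = NULL) {
  stopifnot(length(x) == length(y), n_bins >= 2)
  if (is.null(category)) category <- rep("all", length(x))
  stopifnot(length(category) == length(x))
  residual <- numeric(length(x))
  bin <- integer(length(x))
  for (cat in unique(category)) {
    rows <- category == cat
    if (sum(rows) < n_bins) stop("n_bins exceeds points in category ", cat)
    r <- stats::lm.fit(cbind(1, y[rows]), x[rows])$residuals
    qs <- stats::quantile(r, probs = seq(0, 1, length.out = n_bins + 1))
    if (anyDuplicated(qs) || diff(range(r)) < 1e-10) {
      stop("degenerate bins: residuals lack spread")
    }
    b <- cut(r, qs, include.lowest = TRUE, labels = FALSE)
    residual[rows] <- r
    bin[rows] <- b
  }
  bm <- stats::aggregate(residual, list(category = category, bin = bin),
                         function(v) c(mean = mean(v), n = length(v)))
  bin_means <- data.frame(category = bm$category, bin = bm$bin,
                          mean_residual = bm$x[, "mean"], n = bm$x[, "n"])
  list(residual = residual, bin = bin,
       bin_means = bin_means[order(bin_means$category, bin_means$bin), ])
}
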