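# Degree centrality and thresholded edge graphs over pair-level scores.

#' Per-scene degree centrality on a similarity dimension
#'
#' `centrality(i) = sum_{j != i} score(i, j)` over all within-category
#' pairs, computed separately per category. Scores may be signed (PC scores
#' are the similarity currency here), so centrality is a signed sum; by
#' default it is additionally z-standardized within category x dimension so
#' slopes are comparable across dimensions.
#'
#' @param pair_scores data.frame with `category`, `scene_i`, `scene_j` and
#'   the score columns named in `dimensions`.
#' @param dimensions Character vector of score column names (e.g.
#'   `c("PC1", "PC2")`).
#' @param standardize z-score within category x dimension (default TRUE).
#' @return data.frame with `scene_id`, `category`, `dimension`,
#'   `centrality` (and `centrality_raw` when standardized).
#' @export
degree_centrality <- function(pair_scores, dimensions, standardize = TRUE) {
  stopifnot(all(dimensions %in% names(pair_scores)))
  out <- do.call(rbind, lapply(unique(pair_scores$category), function(cat) {
    rows <- pair_scores[pair_scores$category == cat, ]
    ids <- sort(unique(c(rows$scene_i, rows$scene_j)))
    n <- length(ids)
    if (nrow(rows) != n * (n - 1) / 2 ||
        anyDuplicated(paste(rows$scene_i, rows$scene_j))) {
      stop("pair scores must cover every pair of category ", cat,
           " exactly once")
    }
    do.call(rbind, lapply(dimensions, function(d) {
      v <- rows[[d]]
      if (anyNA(v)) stop("missing pair score in dimension ", d)
      cent <- vapply(ids, function(id) {
        sum(v[rows$scene_i == id | rows$scene_j == id])
      }, numeric(1))
      df <- data.frame(scene_id = ids, category = cat, dimension = d,
                       centrality_raw = unname(cent),
                       stringsAsFactors = FALSE)
      df$centrality <- if (standardize) {
        as.numeric(scale(df$centrality_raw))
      } else df$centrality_raw
      df
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Threshold pair scores into an edge list
#'
#' Returns the edges with score strictly above `cutoff`, sorted by
#' descending score, together with a top-k report of scenes by degree
#' centrality (computed on the full, unthresholded scores).
#'
#' @param pair_scores data.frame with `category`, `scene_i`, `scene_j` and
#'   the column named in `dimension`.
#' @param dimension Score column to threshold.
#' @param cutoff Finite threshold; edges require `score > cutoff`.
#' @param top_k Number of highest-centrality scenes to report per category.
#' @return List with `edges` (data.frame, possibly empty) and `top_nodes`.
#' @export
threshold_edges <- function(pair_scores, dimension, cutoff, top_k = 4) {
  stopifnot(is.finite(cutoff) || cutoff == -Inf)
  stopifnot(dimension %in% names(pair_scores))
  keep <- pair_scores[[dimension]] > cutoff
  edges <- pair_scores[keep, c("category", "scene_i", "scene_j", dimension)]
  names(edges)[4] <- "score"
  edges <- edges[order(-edges$score), ]
  rownames(edges) <- NULL
  cent <- degree_centrality(pair_scores, dimension, standardize = FALSE)
  top_nodes <- do.call(rbind, lapply(split(cent, cent$category), function(g) {
    utils::head(g[order(-g$centrality_raw), ], top_k)
  }))
  rownames(top_nodes) <- NULL
  list(edges = edges, top_nodes = top_nodes)
}
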