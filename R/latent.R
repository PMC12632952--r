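#' Sample a planted latent similarity structure
#'
#' Draws per-scene embedding coordinates and derives per-pair similarity
#' scores on each of `n_dims` latent dimensions. Pair scores are centered to
#' mean 0 and unit variance within each category and Gram-Schmidt
#' orthogonalized across dimensions; because orthogonalization and
#' standardization are both applied within category, the pooled pair-score
#' vectors of different dimensions are exactly orthogonal as well.
#'
#' @param stim A [stimulus_set()].
#' @param config A [sim_config()]; only `n_dims` is used.
#' @param seed Integer RNG seed.
#' @return List of class `latent_structure` with elements:
#'   \describe{
#'     \item{pairs}{canonical pair table (category, scene_i, scene_j) with
#'       one `dim<k>` score column per dimension}
#'     \item{dim_scores}{per-category list of per-dimension symmetric
#'       matrices (diagonal `NA`)}
#'     \item{scene_embeddings}{scene x dimension coordinate matrix}
#'   }
#' @export
sample_latent_structure <- function(stim, config = sim_config(), seed = 1) {
  K <- config$n_dims
  stopifnot(K >= 1)
  counts <- table(stim$category)
  if (any(counts < 3)) stop("each category needs at least 3 scenes")
  n_pairs_min <- min(choose(counts, 2))
  if (K > n_pairs_min - 1) {
    stop("invalid config: n_dims exceeds number of pairs - 1")
  }

  pairs <- enumerate_pairs(stim)
  emb <- with_seed(derive_seed(seed, 1L), {
    matrix(stats::rnorm(nrow(stim) * K), nrow = nrow(stim),
           dimnames = list(stim$scene_id, paste0("dim", seq_len(K))))
  })

  # raw pair score on dimension k: proximity of the two scenes' coordinates
  raw <- sapply(seq_len(K), function(k) {
    -abs(emb[pairs$scene_i, k] - emb[pairs$scene_j, k])
  })
  raw <- matrix(raw, ncol = K)

  # per category: center, Gram-Schmidt across dimensions, standardize
  score <- raw
  for (cat in unique(pairs$category)) {
    rows <- pairs$category == cat
    x <- raw[rows, , drop = FALSE]
    x <- scale(x, center = TRUE, scale = FALSE)
    for (k in seq_len(K)) {
      if (k > 1) {
        for (j in seq_len(k - 1)) {
          x[, k] <- x[, k] - sum(x[, k] * x[, j]) / sum(x[, j]^2) * x[, j]
        }
      }
      x[, k] <- x[, k] - mean(x[, k])
      s <- stats::sd(x[, k])
      if (s < 1e-12) stop("degenerate latent dimension (zero variance)")
      x[, k] <- x[, k] / s
    }
    score[rows, ] <- x
  }
  colnames(score) <- paste0("dim", seq_len(K))
  pairs <- cbind(pairs, as.data.frame(score))

  dim_scores <- lapply(stats::setNames(nm = unique(stim$category)), function(cat) {
    ids <- sort(stim$scene_id[stim$category == cat])
    rows <- pairs$category == cat
    lapply(stats::setNames(nm = paste0("dim", seq_len(K))), function(d) {
      pairs_to_matrix(pairs[rows, ], pairs[[d]][rows], ids)
    })
  })

  structure(
    list(pairs = pairs, dim_scores = dim_scores, scene_embeddings = emb,
         stim = stim),
    class = "latent_structure"
  )
}
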