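#' Define a categorized scene stimulus set
#'
#' The study design uses two visual categories (beaches, gazebos) with 24
#' scenes each; both counts are configurable.
#'
#' @param categories Character vector of category labels.
#' @param scenes_per_category Number of scenes in each category.
#' @return An object of class `stimulus_set`: a data.frame with columns
#'   `scene_id` and `category`, one row per scene. Scene ids are unique and
#'   carry category membership (e.g. `"beach03"`).
#' @examples
#' stim <- stimulus_set()
#' nrow(stim)  # 48
#' @export
stimulus_set <- function(categories = c("beach", "gazebo"),
                         scenes_per_category = 24) {
  stopifnot(length(categories) >= 1, !anyDuplicated(categories),
            scenes_per_category >= 1)
  scenes <- do.call(rbind, lapply(categories, function(cat) {
    data.frame(
      scene_id = sprintf("%s%02d", cat, seq_len(scenes_per_category)),
      category = cat,
      stringsAsFactors = FALSE
    )
  }))
  stopifnot(!anyDuplicated(scenes$scene_id))
  class(scenes) <- c("stimulus_set", "data.frame")
  scenes
}

#' Enumerate unordered within-category scene pairs
#'
#' For a category of n scenes this yields n(n-1)/2 pairs, in canonical order
#' (category, then lexicographic scene-id pairs with `scene_i < scene_j`).
#'
#' @param stim A `stimulus_set` (or data.frame with `scene_id`, `category`).
#' @return data.frame with columns `category`, `scene_i`, `scene_j`.
#' @export
enumerate_pairs <- function(stim) {
  out <- do.call(rbind, lapply(unique(stim$category), function(cat) {
    ids <- sort(stim$scene_id[stim$category == cat])
    if (length(ids) < 2) {
      return(data.frame(category = character(), scene_i = character(),
                        scene_j = character(), stringsAsFactors = FALSE))
    }
    idx <- utils::combn(length(ids), 2)
    data.frame(category = cat, scene_i = ids[idx[1, ]], scene_j = ids[idx[2, ]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Look up pair values for (i, j) rows in a named symmetric matrix.
pair_lookup <- function(mat, scene_i, scene_j) {
  mat[cbind(match(scene_i, rownames(mat)), match(scene_j, colnames(mat)))]
}

# Build a symmetric matrix from canonical pair rows.
pairs_to_matrix <- function(pairs, values, ids) {
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(match(pairs$scene_i, ids), match(pairs$scene_j, ids))] <- values
  m[cbind(match(pairs$scene_j, ids), match(pairs$scene_i, ids))] <- values
  m
}
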