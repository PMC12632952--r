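# Shared fixtures, built in code.

small_stim <- function(n = 4, categories = c("beach", "gazebo")) {
  stimulus_set(categories = categories, scenes_per_category = n)
}

# A tiny deterministic similarity matrix for k scenes.
toy_similarity <- function(ids, values) {
  n <- length(ids)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Small pattern array (scene x run x voxel) from a named list of per-scene
# base vectors; each run adds the given per-run offsets (default none).
toy_patterns <- function(base, n_runs = 3, run_noise = NULL) {
  ids <- names(base)
  V <- length(base[[1]])
  arr <- array(NA_real_, dim = c(length(ids), n_runs, V),
               dimnames = list(ids, paste0("run", seq_len(n_runs)), NULL))
  for (s in seq_along(ids)) {
    for (r in seq_len(n_runs)) {
      arr[s, r, ] <- base[[s]] + if (is.null(run_noise)) 0 else run_noise[[r]]
    }
  }
  arr
}

# Deterministic 16x16 checkerboard pair used for the frozen SSIM oracle.
checkerboard_pair <- function() {
  a <- outer(0:15, 0:15, function(i, j) (i + j) %% 2) * 1.0
  b <- a
  b[1:8, 1:8] <- 1 - b[1:8, 1:8]
  list(a = a, b = b)
}
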