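# Behavioral similarity estimators: memory confusability and odd-one-out
# triplet similarity, plus exclusions, reliability, and auxiliary measures.

# log(x + eps) with eps = half the smallest nonzero entry; eps recorded as
# an attribute so downstream consumers can report it.
log_offset_transform <- function(m) {
  vals <- m[upper.tri(m)]
  nz <- vals[!is.na(vals) & vals > 0]
  if (length(nz) == 0) stop("log transform undefined: all entries zero")
  eps <- min(nz) / 2
  out <- log(m + eps)
  attr(out, "log_offset") <- eps
  out
}

#' Memory confusability matrix from post-test confusion records
#'
#' A confusion between probe i and chosen scene j (either direction)
#' increments the unordered pair (i, j). A participant's entry is the number
#' of rounds with an i-j confusion divided by `n_rounds`; the group matrix
#' is the mean over participants. E.g. a pair confused in 2 of 3 rounds
#' gives a participant-level entry of 0.667.
#'
#' @param records Confusion records for one category (columns `participant`,
#'   `round`, `probe`, `chosen`; see [simulate_posttest_confusions()]).
#'   Correct trials (`probe == chosen`) contribute no confusion.
#' @param n_rounds Number of post-test rounds.
#' @param scene_ids Scene ids of the category (defaults to ids present in
#'   the records).
#' @param participants Participant roster (defaults to ids present in the
#'   records); roster members with zero records are excluded with a
#'   warning.
#' @param aggregate If `TRUE` (default) return the group mean matrix; else a
#'   named list of participant matrices.
#' @param log_transform Apply `log(x + eps)` to the group matrix, with eps =
#'   half the smallest nonzero entry (recorded as attribute
#'   `"log_offset"`).
#' @return Symmetric matrix (or list of matrices) with `NA` diagonal.
#' @export
confusability_matrix <- function(records, n_rounds, scene_ids = NULL,
                                 participants = NULL, aggregate = TRUE,
                                 log_transform = FALSE) {
  stopifnot(n_rounds >= 1)
  if (is.null(scene_ids)) {
    scene_ids <- sort(unique(c(records$probe, records$chosen)))
  }
  n <- length(scene_ids)
  if (is.null(participants)) participants <- unique(records$participant)
  mats <- lapply(participants, function(p) {
    rec <- records[records$participant == p, ]
    if (nrow(rec) == 0) return(NULL)
    counts <- matrix(0, n, n, dimnames = list(scene_ids, scene_ids))
    # count each round at most once per unordered pair
    conf <- rec[rec$probe != rec$chosen, c("round", "probe", "chosen")]
    if (nrow(conf) > 0) {
      a <- pmin(conf$probe, conf$chosen)
      b <- pmax(conf$probe, conf$chosen)
      round_pair <- unique(paste(conf$round, a, b))  # one count per round
      tab <- table(sub("^[^ ]+ ", "", round_pair))   # rounds per pair
      parts <- do.call(rbind, strsplit(names(tab), " "))
      counts[cbind(match(parts[, 1], scene_ids), match(parts[, 2], scene_ids))] <-
        as.numeric(tab)
      counts <- counts + t(counts)
    }
    m <- counts / n_rounds
    diag(m) <- NA
    m
  })
  empty <- vapply(mats, is.null, TRUE)
  if (any(empty)) {
    warning("excluding participants with zero post-test records: ",
            paste(participants[empty], collapse = ", "))
    mats <- mats[!empty]
    participants <- participants[!empty]
  }
  names(mats) <- participants
  if (!aggregate) return(mats)
  g <- Reduce(`+`, mats) / length(mats)
  if (log_transform) g <- log_offset_transform(g)
  g
}

#' Triplet similarity matrix from odd-one-out records
#'
#' A participant's entry (i, j) is the proportion of their non-catch trials
#' containing both i and j on which the third scene was chosen as odd.
#' Pairs never co-presented to a participant are missing for that
#' participant and omitted from their contribution to the group mean (the
#' group value is the simple mean over participants with data).
#'
#' @param records Triplet records (see [simulate_triplet_responses()]);
#'   catch trials are excluded before estimation.
#' @param scene_ids Scene ids (defaults to ids present in the records).
#' @param aggregate If `TRUE` (default) return the group matrix, else a list
#'   of participant matrices (with `NA` for pairs lacking data).
#' @param log_transform Apply the `log(x + eps)` rule to the group matrix.
#' @return Symmetric matrix (or list), `NA` diagonal. Group entries with no
#'   data in any participant remain `NA`; downstream consumers reject such
#'   matrices.
#' @export
triplet_similarity_matrix <- function(records, scene_ids = NULL,
                                      aggregate = TRUE,
                                      log_transform = FALSE) {
  records <- records[!records$catch, ]
  if (is.null(scene_ids)) {
    scene_ids <- sort(unique(c(records$scene_1, records$scene_2,
                               records$scene_3)))
  }
  n <- length(scene_ids)
  participants <- unique(records$participant)
  mats <- lapply(participants, function(p) {
    rec <- records[records$participant == p, ]
    seen <- matrix(0, n, n, dimnames = list(scene_ids, scene_ids))
    other <- seen
    i1 <- match(rec$scene_1, scene_ids)
    i2 <- match(rec$scene_2, scene_ids)
    i3 <- match(rec$scene_3, scene_ids)
    ch <- match(rec$chosen, scene_ids)
    for (t in seq_len(nrow(rec))) {
      tri <- c(i1[t], i2[t], i3[t])
      for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
        a <- tri[pr[1]]; b <- tri[pr[2]]
        seen[a, b] <- seen[a, b] + 1
        if (!(ch[t] %in% c(a, b))) other[a, b] <- other[a, b] + 1
      }
    }
    seen <- seen + t(seen); other <- other + t(other)
    m <- other / seen  # NaN where never co-presented
    m[seen == 0] <- NA
    diag(m) <- NA
    m
  })
  names(mats) <- participants
  if (!aggregate) return(mats)
  arr <- simplify2array(mats)
  g <- apply(arr, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  diag(g) <- NA
  if (log_transform) g <- log_offset_transform(g)
  g
}

#' Apply performance-based participant exclusions
#'
#' Participants are retained when their metric value is at or above the
#' threshold; strictly lower values are excluded ("below 28%" post-test
#' accuracy, catch accuracy "lower than 80%").
#'
#' @param accuracy Named numeric vector of per-participant accuracies.
#' @param threshold Retention threshold (default 0.28 for post-test
#'   accuracy; use 0.80 for triplet catch accuracy).
#' @return List with `retained` (ids), `report` (data.frame of id, value,
#'   threshold, retained flag).
#' @export
apply_exclusions <- function(accuracy, threshold = 0.28) {
  keep <- accuracy >= threshold
  list(
    retained = names(accuracy)[keep],
    report = data.frame(participant = names(accuracy), value = unname(accuracy),
                        threshold = threshold, retained = unname(keep),
                        stringsAsFactors = FALSE)
  )
}

#' Split-half reliability curve over participant counts
#'
#' For each count, `n_permutations` random permutations each sample `count`
#' participants, split them into two equal halves, average the matrices
#' within each half, and Pearson-correlate the upper-triangle vectors. The
#' per-count summary is the inverse Fisher z of the mean Fisher z over
#' permutations.
#'
#' @param participant_matrices Named list of per-participant symmetric
#'   matrices (equal dimnames).
#' @param counts Even participant counts, each <= number of participants.
#' @param n_permutations Permutations per count (50 in the study design).
#' @param seed Integer RNG seed.
#' @return List of class `reliability_curve`: `counts`, `mean_r` (per
#'   count), `perm_r` (count x permutation matrix).
#' @export
split_half_reliability <- function(participant_matrices, counts,
                                   n_permutations = 50, seed = 1) {
  stopifnot(n_permutations >= 1)
  if (any(counts %% 2 != 0)) stop("all counts must be even")
  n_avail <- length(participant_matrices)
  if (any(counts > n_avail)) stop("count exceeds available participants")
  vecs <- vapply(participant_matrices, upper_vec,
                 numeric(sum(upper.tri(participant_matrices[[1]]))))
  with_seed(derive_seed(seed, 7L), {
    perm_r <- matrix(NA_real_, length(counts), n_permutations,
                     dimnames = list(as.character(counts), NULL))
    for (ci in seq_along(counts)) {
      cnt <- counts[ci]
      for (p in seq_len(n_permutations)) {
        take <- sample.int(n_avail, cnt)
        h1 <- take[seq_len(cnt / 2)]
        h2 <- take[(cnt / 2 + 1):cnt]
        v1 <- rowMeans(vecs[, h1, drop = FALSE], na.rm = TRUE)
        v2 <- rowMeans(vecs[, h2, drop = FALSE], na.rm = TRUE)
        ok <- stats::complete.cases(v1, v2)
        if (stats::sd(v1[ok]) == 0 || stats::sd(v2[ok]) == 0) {
          warning("zero-variance half; permutation dropped")
          next
        }
        perm_r[ci, p] <- stats::cor(v1[ok], v2[ok])
      }
    }
    mean_r <- apply(perm_r, 1, function(r) {
      fisher_z_inv(mean(fisher_z(r[!is.na(r)])))
    })
    structure(list(counts = counts, mean_r = unname(mean_r), perm_r = perm_r),
              class = "reliability_curve")
  })
}

#' Recognition sensitivity (d-prime) from exposure-phase responses
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`, where a hit is a "new"
#' response to a lure and a false alarm a "new" response to a studied
#' scene. Rates are clipped to `[1/(2N), 1 - 1/(2N)]` so perfect
#' performance yields a finite value.
#'
#' @param records Exposure records (see [simulate_exposure_responses()]).
#' @return data.frame with `participant`, `training_level`, `n_lure`,
#'   `n_old`, `hit_rate`, `fa_rate`, `dprime` (NA when a condition has no
#'   trials).
#' @export
compute_dprime <- function(records) {
  grp <- split(records, list(records$participant, records$training_level),
               drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    n_lure <- sum(g$is_lure); n_old <- sum(!g$is_lure)
    clip <- function(rate, n) pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
    hit <- if (n_lure > 0) clip(mean(g$responded_new[g$is_lure]), n_lure) else NA
    fa <- if (n_old > 0) clip(mean(g$responded_new[!g$is_lure]), n_old) else NA
    data.frame(participant = g$participant[1],
               training_level = g$training_level[1],
               n_lure = n_lure, n_old = n_old,
               hit_rate = hit, fa_rate = fa,
               dprime = stats::qnorm(hit) - stats::qnorm(fa),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$participant, out$training_level), ]
}

#' Code training-phase trials as interference-error outcomes
#'
#' Competitor choices are coded 1, target choices 0, and non-competitor
#' choices are dropped (with the count reported as an attribute), matching
#' the trial-level interference-error models.
#'
#' @param trials Training trial records (see [simulate_training_trials()]);
#'   the `choice` column must be one of `"target"`, `"competitor"`,
#'   `"non_competitor"`, or `NA` (no response, dropped).
#' @return The model-ready data.frame with an `error` column (0/1);
#'   attributes `n_excluded_noncompetitor` and `n_excluded_noresponse`.
#' @export
code_interference_errors <- function(trials) {
  no_resp <- is.na(trials$choice)
  nc <- !no_resp & trials$choice == "non_competitor"
  out <- trials[!no_resp & !nc, , drop = FALSE]
  out$error <- as.integer(out$choice == "competitor")
  attr(out, "n_excluded_noncompetitor") <- sum(nc)
  attr(out, "n_excluded_noresponse") <- sum(no_resp)
  out
}
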