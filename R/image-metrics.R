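# Similarity matrices from images or externally computed feature vectors.

#' Read an image as a grayscale matrix in [0, 1]
#'
#' PNG input via the `png` package; RGB(A) channels are combined with the
#' standard luma weights (0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG images requires the 'png' package")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  }
  img
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm vector under cosine similarity")
  sum(a * b) / (na * nb)
}

#' Pairwise similarity matrix from features or images
#'
#' Computes the within-category pairwise similarity matrix for one metric:
#' cosine similarity or Pearson correlation between feature vectors (the
#' study uses cosine for CLIP/NLP/AlexNet/GIST embeddings and Pearson for
#' VGG layer activations), or SSIM directly between grayscale images.
#'
#' @param x For `measure` `"cosine"`/`"pearson"`: a named list of numeric
#'   feature vectors (one per scene, equal length). For `"ssim"`: a named
#'   list of grayscale image matrices of equal shape.
#' @param measure One of `"cosine"`, `"pearson"`, `"ssim"`.
#' @param ... Passed to [ssim()] for `measure = "ssim"`.
#' @return Symmetric matrix with scene-id dimnames and `NA` diagonal.
#' @export
metric_similarity_matrix <- function(x, measure = c("cosine", "pearson", "ssim"),
                                     ...) {
  measure <- match.arg(measure)
  ids <- names(x)
  if (is.null(ids) || anyDuplicated(ids)) stop("x must be a uniquely named list")
  n <- length(x)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- switch(measure,
        cosine = {
          if (sqrt(sum(x[[i]]^2)) == 0) stop("zero-norm vector: ", ids[i])
          if (sqrt(sum(x[[j]]^2)) == 0) stop("zero-norm vector: ", ids[j])
          cosine_similarity(x[[i]], x[[j]])
        },
        pearson = stats::cor(x[[i]], x[[j]]),
        ssim = ssim(x[[i]], x[[j]], ...)
      )
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Read a feature-vector table
#'
#' CSV schema: first column `id`, remaining columns `v1..vn` numeric.
#'
#' @param path CSV path.
#' @return Named list of numeric vectors.
#' @export
read_feature_vectors <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(names(tab)[1] == "id")
  vecs <- lapply(seq_len(nrow(tab)), function(i) as.numeric(tab[i, -1]))
  names(vecs) <- tab$id
  if (any(!vapply(vecs, function(v) all(is.finite(v)), TRUE))) {
    stop("non-finite feature values")
  }
  vecs
}
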