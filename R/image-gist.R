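# GIST descriptor: whitening + local contrast normalization, a polar Gabor
# filterbank in the frequency domain, and grid-averaged filter energies.
# Parameterization follows the published LMgist defaults (4 scales, 8
# orientations per scale, 4x4 grid, prefilter coefficient 4).

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
    c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))]
}

pad_symmetric <- function(m, w) {
  m <- rbind(m[w:1, , drop = FALSE], m, m[nrow(m):(nrow(m) - w + 1), , drop = FALSE])
  cbind(m[, w:1, drop = FALSE], m, m[, ncol(m):(ncol(m) - w + 1), drop = FALSE])
}

# Whitening + local contrast normalization (prefilter coefficient fc).
gist_prefilter <- function(img, fc = 4, pad = 5) {
  img <- log(img + 1)
  img <- pad_symmetric(img, pad)
  n <- nrow(img)
  stopifnot(ncol(img) == n, n %% 2 == 0)
  s1 <- fc / sqrt(log(2))
  fx <- matrix(rep(seq(-n / 2, n / 2 - 1), each = n), n, n)
  fy <- t(fx)
  gf <- fftshift2(exp(-(fx^2 + fy^2) / s1^2))
  ft <- stats::fft(img)
  low <- Re(stats::fft(ft * gf, inverse = TRUE)) / n^2
  out <- img - low
  lv <- Re(stats::fft(stats::fft(out^2) * gf, inverse = TRUE)) / n^2
  local_std <- sqrt(abs(lv))
  out <- out / (0.2 + local_std)
  out[(pad + 1):(n - pad), (pad + 1):(n - pad)]
}

# Polar log-Gabor-style transfer functions of the LMgist filterbank for an
# n x n grid: one filter per (scale, orientation).
gist_gabor_bank <- function(n, n_scales = 4, n_orientations = 8) {
  params <- NULL
  for (i in seq_len(n_scales)) {
    for (j in seq_len(n_orientations)) {
      params <- rbind(params, c(
        0.35,
        0.3 / (1.85^(i - 1)),
        16 * n_orientations^2 / 32^2,
        pi / n_orientations * (j - 1)
      ))
    }
  }
  fx <- matrix(rep(seq(-n / 2, n / 2 - 1), each = n), n, n)
  fy <- t(fx)
  fr <- fftshift2(sqrt(fx^2 + fy^2))
  th <- fftshift2(atan2(fy, fx))
  # zero the unpaired Nyquist row/column and the DC bin (no oriented
  # energy) so the spectral support is symmetric under 90-degree rotation
  nyq <- fftshift2(fx == -n / 2 | fy == -n / 2 | (fx == 0 & fy == 0))
  G <- array(0, dim = c(n, n, nrow(params)))
  for (k in seq_len(nrow(params))) {
    tr <- th + params[k, 4]
    tr <- tr + 2 * pi * (tr < -pi) - 2 * pi * (tr > pi)
    g <- exp(-10 * params[k, 1] * (fr / n / params[k, 2] - 1)^2 -
               2 * params[k, 3] * pi * tr^2)
    g[nyq] <- 0
    G[, , k] <- g
  }
  G
}

# Block-average a map over an ng x ng grid.
grid_average <- function(m, ng) {
  n <- nrow(m)
  stopifnot(n %% ng == 0, ncol(m) == n)
  step <- n / ng
  out <- matrix(0, ng, ng)
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      out[i, j] <- mean(m[((i - 1) * step + 1):(i * step),
                          ((j - 1) * step + 1):(j * step)])
    }
  }
  out
}

#' GIST descriptor of a grayscale image
#'
#' Rescales intensities to `[0, 255]` (making the descriptor exactly
#' invariant to global intensity scaling), applies whitening and local
#' contrast normalization with the given prefilter coefficient, filters
#' with a Gabor bank of `n_scales x n_orientations` frequency-domain
#' filters, and averages each filter's output magnitude over an
#' `grid x grid` spatial grid. Default configuration (4, 8, 4x4) gives a
#' descriptor of length 4 * 8 * 16 = 512.
#'
#' @param image Square numeric matrix (grayscale intensities); images are
#'   expected resized to 256x256 (see [resize_bilinear()]).
#' @param n_scales Spatial scales (4).
#' @param n_orientations Orientations per scale (8).
#' @param grid Spatial grid size (4).
#' @param prefilter Prefiltering coefficient (4).
#' @param boundary Symmetric boundary extension in pixels (32).
#' @return Numeric descriptor of length `n_scales * n_orientations *
#'   grid^2`.
#' @export
gist_descriptor <- function(image, n_scales = 4, n_orientations = 8,
                            grid = 4, prefilter = 4, boundary = 32) {
  if (nrow(image) != ncol(image)) stop("GIST requires a square image")
  stopifnot(all(is.finite(image)))
  rng <- range(image)
  img <- if (rng[2] > rng[1]) 255 * (image - rng[1]) / (rng[2] - rng[1]) else
    image * 0
  img <- gist_prefilter(img, fc = prefilter)
  img <- pad_symmetric(img, boundary)
  n <- nrow(img)
  G <- gist_gabor_bank(n, n_scales, n_orientations)
  ft <- stats::fft(img)
  desc <- numeric(0)
  for (k in seq_len(dim(G)[3])) {
    ig <- Mod(stats::fft(ft * G[, , k], inverse = TRUE)) / n^2
    ig <- ig[(boundary + 1):(n - boundary), (boundary + 1):(n - boundary)]
    desc <- c(desc, as.numeric(grid_average(ig, grid)))
  }
  desc
}

#' Bilinear image resize
#'
#' Antialiasing-free bilinear interpolation onto a `target x target` grid
#' (pixel centers aligned to the source image extent).
#'
#' @param image Numeric matrix.
#' @param target Output side length.
#' @return `target x target` matrix.
#' @export
resize_bilinear <- function(image, target = 256) {
  nr <- nrow(image); nc <- ncol(image)
  map <- function(n_out, n_in) {
    x <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pmin(pmax(x, 1), n_in)
  }
  xs <- map(target, nr); ys <- map(target, nc)
  x0 <- floor(xs); x1 <- pmin(x0 + 1, nr); wx <- xs - x0
  y0 <- floor(ys); y1 <- pmin(y0 + 1, nc); wy <- ys - y0
  a <- image[x0, y0, drop = FALSE] * outer(1 - wx, 1 - wy)
  b <- image[x1, y0, drop = FALSE] * outer(wx, 1 - wy)
  c2 <- image[x0, y1, drop = FALSE] * outer(1 - wx, wy)
  d <- image[x1, y1, drop = FALSE] * outer(wx, wy)
  a + b + c2 + d
}
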