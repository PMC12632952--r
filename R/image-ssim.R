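# Structural similarity index (SSIM) on grayscale images in [0, 1].

# Separable Gaussian filtering with symmetric (reflect) boundary padding.
# Returns a map of the same size as the input.
gaussian_filter2 <- function(x, sigma = 1.5, radius = 5) {
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_sym <- function(m, r) {
    top <- m[r:1, , drop = FALSE]
    bot <- m[nrow(m):(nrow(m) - r + 1), , drop = FALSE]
    rbind(top, m, bot)
  }
  conv_rows <- function(m, r) {
    mp <- pad_sym(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[i:(i + nrow(m) - 1), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(x, radius)), radius))
}

#' Structural similarity index between two grayscale images
#'
#' Mean local SSIM (luminance, contrast, structure) computed with an 11x11
#' Gaussian window (sigma 1.5), the standard stabilizing constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with data range `L = 1` for images
#' in `[0, 1]`, population (Gaussian-weighted) moments, and symmetric
#' boundary handling with the window-radius border of the SSIM map excluded
#' from the mean. Identical images score exactly 1; values lie in
#' `[-1, 1]`.
#'
#' @param image_a,image_b Numeric matrices of equal shape with finite
#'   values in `[0, 1]`.
#' @param window Window width (odd; default 11).
#' @param sigma Gaussian window SD (default 1.5).
#' @param data_range Dynamic range `L` (default 1).
#' @return Scalar SSIM value.
#' @export
ssim <- function(image_a, image_b, window = 11, sigma = 1.5, data_range = 1) {
  if (!all(dim(image_a) == dim(image_b))) stop("images must have equal shapes")
  stopifnot(window %% 2 == 1, all(is.finite(image_a)), all(is.finite(image_b)))
  radius <- (window - 1) / 2
  if (any(dim(image_a) < window)) stop("image smaller than the SSIM window")
  f <- function(m) gaussian_filter2(m, sigma = sigma, radius = radius)
  ux <- f(image_a); uy <- f(image_b)
  vx <- f(image_a^2) - ux^2
  vy <- f(image_b^2) - uy^2
  vxy <- f(image_a * image_b) - ux * uy
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  core <- S[(radius + 1):(nrow(S) - radius), (radius + 1):(ncol(S) - radius)]
  mean(core)
}
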