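#' Fisher z transform of a correlation
#'
#' `atanh` with clipping of `|r|` at `1 - eps` so that z stays finite for
#' degenerate (noise-free) inputs.
#'
#' @param r Correlation value(s).
#' @param eps Clipping margin; `|r|` is capped at `1 - eps`. Default `1e-7`.
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r, eps = 1e-7) {
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Inverse Fisher z transform
#'
#' @param z Fisher z value(s).
#' @return Correlation value(s) (`tanh(z)`).
#' @export
fisher_z_inv <- function(z) tanh(z)

# Derive a component-specific RNG seed from a dataset seed. Keeps the result
# a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97L + offset * 1009L) %% 2147483647)
}

# Run `expr` with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Upper-triangle (i < j) vector of a symmetric matrix, row/col order fixed.
upper_vec <- function(m) m[upper.tri(m)]

# Assert a matrix is (numerically) symmetric.
check_symmetric <- function(m, tol = 1e-12, what = "matrix") {
  if (nrow(m) != ncol(m) || max(abs(m - t(m)), na.rm = TRUE) > tol) {
    stop(what, " is not symmetric (tolerance ", tol, ")", call. = FALSE)
  }
  invisible(m)
}
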