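#' @keywords internal
"_PACKAGE"

# Canonical covariate order used throughout the package.
COVARIATE_NAMES <- c("sst", "chlorophyll_a", "salinity", "depth", "slope",
                     "dist_shore")

DYNAMIC_LAYERS <- c("sst", "chlorophyll_a", "salinity")
STATIC_LAYERS  <- c("depth", "slope", "dist_shore")

#' Derive a reproducible child seed from a base seed and string labels
#'
#' Every stochastic stage of the pipeline draws its RNG state from the run
#' seed plus a stage label, so stages are independent and any one of them is
#' reproducible in isolation.
#'
#' @param seed integer base seed.
#' @param ... character or numeric labels identifying the stage.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(labels)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# Round half away from zero (Eq.-style arithmetic rounding; base round()
# rounds half to even which is wrong for the absence-count contract).
round_half_up <- function(x) {
  floor(x + 0.5)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Gaussian smoothing of a matrix
#'
#' Separable Gaussian convolution with edge renormalization (the kernel mass
#' falling outside the matrix is redistributed, so constant fields stay
#' constant near edges). `sigma = 0` returns the input unchanged.
#'
#' @param mat numeric matrix.
#' @param sigma kernel standard deviation in cells.
#' @return smoothed matrix of the same shape.
#' @export
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth_1d <- function(m, kern) {
    # convolve each column with kern, renormalizing at the edges
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (off in seq_along(kern)) {
      d <- off - half - 1L
      src <- seq_len(n) + d
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + kern[off] * m[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + kern[off]
    }
    out / wsum
  }
  t(smooth_1d(t(smooth_1d(mat, k)), k))
}
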