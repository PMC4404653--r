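# Separable isotropic Gaussian convolution with reflective boundaries.
# Implemented as banded operator matrices (one per axis) so boundary
# handling is exact mirror reflection; the kernel is truncated at 3.5 sigma
# and normalized to unit sum, so a constant image is a fixed point and an
# impulse integrates to its own value.
gaussian_blur <- function(img, sigma) {
  stopifnot(sigma > 0)
  R <- max(1L, ceiling(3.5 * sigma))
  w <- exp(-((-R:R)^2) / (2 * sigma^2))
  w <- w / sum(w)
  img <- blur_op(nrow(img), R, w) %*% img
  img %*% t(blur_op(ncol(img), R, w))
}

blur_op <- function(n, R, w) {
  A <- matrix(0, n, n)
  ii <- seq_len(n)
  for (k in -R:R) {
    src <- reflect_index(ii + k, n)
    A[cbind(ii, src)] <- A[cbind(ii, src)] + w[k + R + 1L]
  }
  A
}

# Whole-sample mirror reflection of out-of-range indices (1-based).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  while (any(i < 1L | i > n)) {
    i <- ifelse(i < 1L, 2L - i, i)
    i <- ifelse(i > n, 2L * n - i, i)
  }
  i
}
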