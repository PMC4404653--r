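#' Extract a square patch around a bundle center
#'
#' Copies a `size` x `size` region surrounding the center coordinate (default
#' 40 x 40). With a 1-based center (r, c) the patch covers rows
#' `(r - size/2):(r + size/2 - 1)`; patches clipped by the image edge are
#' padded by mirror reflection and flagged.
#'
#' @param gray Numeric matrix.
#' @param center `(row, col)` 1-based center.
#' @param size Even patch side length >= 8 (default 40).
#' @return `size` x `size` matrix with attribute `edge_clipped` (logical).
#' @export
extract_patch <- function(gray, center, size = 40L) {
  if (size %% 2L != 0L || size < 8L) {
    stop("stalkscan parameter error: patch size must be even and >= 8")
  }
  r <- center[[1]]; c <- center[[2]]
  if (r < 1 || r > nrow(gray) || c < 1 || c > ncol(gray)) {
    stop("stalkscan domain error: patch center outside image")
  }
  rows <- (r - size %/% 2L):(r + size %/% 2L - 1L)
  cols <- (c - size %/% 2L):(c + size %/% 2L - 1L)
  clipped <- any(rows < 1L | rows > nrow(gray) | cols < 1L | cols > ncol(gray))
  patch <- gray[reflect_index(rows, nrow(gray)),
                reflect_index(cols, ncol(gray))]
  attr(patch, "edge_clipped") <- clipped
  patch
}

#' Homomorphic illumination correction of a patch
#'
#' Log-domain frequency filtering: `y = exp(IDFT(H . DFT(log(1 + patch)))) - 1`
#' with a Gaussian high-emphasis transfer function
#' `H(f) = gain_low + (gain_high - gain_low) * (1 - exp(-|f|^2 / (2 (cutoff_frac N)^2)))`.
#' Low-frequency content (illumination, scanner reflectance artifacts) is
#' attenuated toward `gain_low` while high-frequency reflectance detail is
#' boosted toward `gain_high`. The output is rescaled to [0, 255] (a constant
#' patch, having only the zero frequency, stays constant and is returned
#' unrescaled).
#'
#' @param patch Non-negative numeric matrix.
#' @param cutoff_frac Gaussian cutoff as a fraction of the patch side
#'   (default 0.08).
#' @param gain_low Gain at zero frequency (default 0.5).
#' @param gain_high Asymptotic high-frequency gain (default 1.5).
#' @return Enhanced patch in [0, 255].
#' @export
homomorphic_filter <- function(patch, cutoff_frac = 0.08, gain_low = 0.5,
                               gain_high = 1.5) {
  if (min(patch) < 0) {
    stop("stalkscan domain error: negative patch values")
  }
  nr <- nrow(patch); nc <- ncol(patch)
  # mirror-extend before the DFT: the transform's periodic wrap-around would
  # otherwise turn any illumination ramp into a sawtooth whose discontinuity
  # rings across the small patch
  lp <- log1p(patch)
  ext <- rbind(lp, lp[nr:1, , drop = FALSE])
  ext <- cbind(ext, ext[, nc:1, drop = FALSE])
  fr <- fft_freq(2L * nr); fc <- fft_freq(2L * nc)
  f2 <- outer(fr^2, fc^2, `+`)
  s2 <- 2 * (cutoff_frac * (nr + nc))^2
  H <- gain_low + (gain_high - gain_low) * (1 - exp(-f2 / s2))
  y <- Re(stats::fft(H * stats::fft(ext), inverse = TRUE)) /
    (4 * nr * nc)
  y <- expm1(y[seq_len(nr), seq_len(nc)])
  rng <- range(y)
  if (diff(rng) <= 1e-9 * max(abs(rng), 1)) {
    return(matrix(pmin(pmax(y, 0), 255), nr, nc))
  }
  (y - rng[1]) / diff(rng) * 255
}

fft_freq <- function(n) {
  f <- 0:(n - 1L)
  f[f > n / 2] <- f[f > n / 2] - n
  f
}

#' Fit a full-covariance 2D Gaussian to a bundle patch
#'
#' Least-squares fit of `baseline + amplitude * exp(-q' S^-1 q / 2)` (q the
#' offset from the patch center, S a full 2 x 2 covariance) via
#' Levenberg-Marquardt, initialized from intensity moments. The reported
#' bundle area is that of the level-contour ellipse at `contour_multiplier`
#' standard deviations (default 2):
#' `area = pi * (k * sigma_major) * (k * sigma_minor)`.
#'
#' A fit is flagged `converged` only when the optimizer succeeds, the
#' amplitude is positive and exceeds three times its standard error, the
#' fitted center lies inside the patch, and the shape matrix is positive
#' definite; degenerate fits on pure noise fail the significance check.
#'
#' @param patch Numeric matrix (non-constant).
#' @param contour_multiplier Level-contour multiplier k (default 2).
#' @return A `bundle_fit`: `center_offset` (d_row, d_col from patch center),
#'   `amplitude`, `sigma_major`, `sigma_minor`, `theta` (major-axis angle
#'   from the column axis, in [-pi/2, pi/2)), `baseline`, `area_px2`,
#'   `converged`. `area_px2` is NA when not converged.
#' @export
fit_gaussian2d <- function(patch, contour_multiplier = 2) {
  nr <- nrow(patch); nc <- ncol(patch)
  if (diff(range(patch)) <= 0) {
    stop("stalkscan degenerate-input error: constant patch")
  }
  cr0 <- (nr + 1) / 2; cc0 <- (nc + 1) / 2
  dr <- row(patch) - cr0; dc <- col(patch) - cc0
  b0 <- stats::quantile(patch, 0.25, names = FALSE)
  w <- pmax(patch - b0, 0)
  sw <- sum(w)
  fail <- function() structure(list(
    center_offset = c(d_row = NA_real_, d_col = NA_real_),
    amplitude = NA_real_, sigma_major = NA_real_, sigma_minor = NA_real_,
    theta = NA_real_, baseline = NA_real_, area_px2 = NA_real_,
    contour_multiplier = contour_multiplier, converged = FALSE),
    class = "bundle_fit")
  if (sw <= 0) return(fail())
  mr <- sum(w * dr) / sw; mc <- sum(w * dc) / sw
  vrr <- max(sum(w * (dr - mr)^2) / sw, 0.25)
  vcc <- max(sum(w * (dc - mc)^2) / sw, 0.25)
  vrc <- sum(w * (dr - mr) * (dc - mc)) / sw
  det0 <- vrr * vcc - vrc^2
  if (det0 <= 0) { vrc <- 0; det0 <- vrr * vcc }
  # parameters of the inverse covariance: Q = a dr^2 + 2 c dr dc + b dc^2
  p0 <- c(baseline = b0, A = max(patch) - b0, r0 = mr, c0 = mc,
          a = vcc / det0, b = vrr / det0, cc = -vrc / det0)
  model <- function(p) {
    q <- p["a"] * (dr - p["r0"])^2 + p["b"] * (dc - p["c0"])^2 +
      2 * p["cc"] * (dr - p["r0"]) * (dc - p["c0"])
    p["baseline"] + p["A"] * exp(-pmin(q, 1e6) / 2)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = function(p) as.vector(model(p) - patch),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(fail())
  p <- fit$par
  M <- matrix(c(p["a"], p["cc"], p["cc"], p["b"]), 2L)
  ev <- eigen(M, symmetric = TRUE)
  if (any(ev$values <= 0) || p["A"] <= 0) return(fail())
  if (abs(p["r0"]) > nr / 2 || abs(p["c0"]) > nc / 2) return(fail())
  se_A <- tryCatch(summary(fit)$coefficients["A", "Std. Error"],
                   error = function(e) NA_real_)
  if (!is.finite(se_A) || p["A"] <= 3 * se_A) {
    # noiseless fits have ~zero residuals: treat se 0/NaN with tiny deviance
    # as significant
    if (!(fit$deviance < 1e-8 * sum(patch^2))) return(fail())
  }
  # covariance = inverse of the shape matrix; eigenvalues are sigma^2
  sig2 <- rev(1 / ev$values)          # ascending eigenvalues of M -> sigma^2
  sigma_major <- sqrt(max(sig2)); sigma_minor <- sqrt(min(sig2))
  # major axis of the covariance = eigenvector of M with smallest eigenvalue
  v <- ev$vectors[, which.min(ev$values)]
  theta <- atan2(v[1], v[2])
  if (theta >= pi / 2) theta <- theta - pi
  if (theta < -pi / 2) theta <- theta + pi
  k <- contour_multiplier
  structure(list(
    center_offset = c(d_row = unname(p["r0"]), d_col = unname(p["c0"])),
    amplitude = unname(p["A"]),
    sigma_major = sigma_major, sigma_minor = sigma_minor, theta = theta,
    baseline = unname(p["baseline"]),
    area_px2 = pi * (k * sigma_major) * (k * sigma_minor),
    contour_multiplier = k, converged = TRUE), class = "bundle_fit")
}

#' Measure all bundle sizes for one transection
#'
#' For each detected center: extract a patch, enhance it homomorphically, and
#' fit the 2D Gaussian. The summary mean area is taken over converged fits
#' only.
#'
#' @param gray Grayscale matrix of the cropped object.
#' @param centers n x 2 matrix of (row, col) centers (or a `bundle_set`).
#' @param cal A `calibration`.
#' @param patch_size Patch side (default 40).
#' @param contour_multiplier Level-contour multiplier (default 2).
#' @param homomorphic Apply illumination correction before fitting
#'   (default TRUE).
#' @param cutoff_frac,gain_low,gain_high Passed to [homomorphic_filter()].
#' @return List with `fits` (data frame: row, col, sigma_major, sigma_minor,
#'   theta, area_px2, area_cm2, converged) and `mean_bundle_area_cm2`
#'   (NA with a warning when no fit converged or no centers given).
#' @export
bundle_sizes <- function(gray, centers, cal, patch_size = 40L,
                         contour_multiplier = 2, homomorphic = TRUE,
                         cutoff_frac = 0.08, gain_low = 0.5,
                         gain_high = 1.5) {
  if (inherits(centers, "bundle_set")) centers <- centers$centers
  centers <- as_centers(centers)
  n <- nrow(centers)
  if (n == 0L) {
    return(list(fits = data.frame(
      row = numeric(0), col = numeric(0), sigma_major = numeric(0),
      sigma_minor = numeric(0), theta = numeric(0), area_px2 = numeric(0),
      area_cm2 = numeric(0), converged = logical(0)),
      mean_bundle_area_cm2 = NA_real_))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    patch <- extract_patch(gray, centers[i, ], patch_size)
    if (homomorphic) {
      patch <- homomorphic_filter(patch, cutoff_frac, gain_low, gain_high)
    }
    f <- tryCatch(fit_gaussian2d(patch, contour_multiplier),
                  error = function(e) NULL)
    if (is.null(f)) {
      rows[[i]] <- data.frame(row = centers[i, 1], col = centers[i, 2],
                              sigma_major = NA, sigma_minor = NA, theta = NA,
                              area_px2 = NA, area_cm2 = NA, converged = FALSE)
    } else {
      rows[[i]] <- data.frame(
        row = centers[i, 1], col = centers[i, 2],
        sigma_major = f$sigma_major, sigma_minor = f$sigma_minor,
        theta = f$theta, area_px2 = f$area_px2,
        area_cm2 = f$area_px2 / cal$px_per_cm^2, converged = f$converged)
    }
  }
  fits <- do.call(rbind, rows)
  ok <- fits$converged & is.finite(fits$area_cm2)
  if (!any(ok)) {
    warning("stalkscan: no converged bundle fits; mean bundle area missing")
    mean_area <- NA_real_
  } else {
    mean_area <- mean(fits$area_cm2[ok])
  }
  list(fits = fits, mean_bundle_area_cm2 = mean_area)
}
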