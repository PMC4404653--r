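#' Bundle-scale Gaussian smoothing
#'
#' Convolution with an isotropic Gaussian whose full width is approximately
#' one vascular bundle (`sigma = bundle_width_px / 2`), merging the internal
#' structure of each bundle into a single peak while leaving inter-bundle
#' spacing resolved. Reflective boundaries.
#'
#' @param gray Numeric matrix.
#' @param bundle_width_px Typical bundle diameter in pixels (> 0).
#' @return Smoothed matrix, same shape.
#' @export
bundle_smooth <- function(gray, bundle_width_px) {
  stopifnot(bundle_width_px > 0)
  gaussian_blur(gray, bundle_width_px / 2)
}

#' Diffusion parameters for [anisotropic_diffusion()]
#'
#' @param kappa Conduction threshold in intensity units (> 0); gradients well
#'   below `kappa` diffuse freely, edges well above are preserved.
#' @param n_iter Number of explicit Euler steps (>= 1).
#' @param dt Time step; must be in (0, 0.25] for stability of the 4-neighbor
#'   explicit scheme.
#' @param conduction `"exponential"` for `g = exp(-(grad/kappa)^2)` or
#'   `"rational"` for `g = 1/(1 + (grad/kappa)^2)`.
#' @return A `diffusion_params` list.
#' @export
diffusion_params <- function(kappa = 30, n_iter = 20L, dt = 0.2,
                             conduction = c("exponential", "rational")) {
  conduction <- match.arg(conduction)
  stopifnot(kappa > 0, n_iter >= 1)
  if (dt <= 0 || dt > 0.25) {
    stop("stalkscan stability error: dt must be in (0, 0.25]")
  }
  structure(list(kappa = kappa, n_iter = as.integer(n_iter), dt = dt,
                 conduction = conduction), class = "diffusion_params")
}

#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving smoothing: 4-neighbor fluxes with a conduction coefficient
#' that decays with local gradient magnitude, explicit Euler steps, and
#' Neumann (reflecting) boundaries. The scheme is flux-conservative, so total
#' intensity is preserved to floating-point accuracy and constant images are
#' fixed points. Flattens parenchyma texture while keeping bundle-scale edges,
#' so each bundle appears as a single rather than split peak.
#'
#' @param img Numeric matrix.
#' @param params A [diffusion_params()] list.
#' @return Diffused matrix, same shape.
#' @export
anisotropic_diffusion <- function(img, params = diffusion_params()) {
  if (!inherits(params, "diffusion_params")) {
    params <- do.call(diffusion_params, params)
  }
  g <- if (params$conduction == "exponential") {
    function(d) exp(-(d / params$kappa)^2)
  } else {
    function(d) 1 / (1 + (d / params$kappa)^2)
  }
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(params$n_iter)) {
    dN <- rbind(img[1, , drop = FALSE], img[-nr, , drop = FALSE]) - img
    dS <- rbind(img[-1, , drop = FALSE], img[nr, , drop = FALSE]) - img
    dW <- cbind(img[, 1, drop = FALSE], img[, -nc, drop = FALSE]) - img
    dE <- cbind(img[, -1, drop = FALSE], img[, nc, drop = FALSE]) - img
    img <- img + params$dt *
      (g(abs(dN)) * dN + g(abs(dS)) * dS + g(abs(dW)) * dW + g(abs(dE)) * dE)
  }
  img
}

#' Detect bundle peaks by non-maximum suppression
#'
#' Returns the pixels that lie inside the pith mask, are maxima within a disc
#' of the suppression radius, and exceed the Otsu level of the in-pith
#' intensities by at least `min_prominence`. The Otsu level is computed over
#' 256 levels spanning the observed in-pith range, which makes the output
#' invariant to adding a constant to the image. Plateau ties are broken
#' toward the smaller (row, col), and no two returned peaks are closer than
#' the suppression radius, so the output is fully deterministic.
#'
#' @param img Processed intensity matrix (smoothed + diffused).
#' @param pith_mask Logical matrix, same shape.
#' @param suppression_radius_px Disc radius for the non-maximum suppression
#'   (>= 1).
#' @param min_prominence Minimum excess over the in-pith Otsu level
#'   (default 0).
#' @return n x 2 matrix of (row, col) peak coordinates, 1-based.
#' @export
detect_peaks <- function(img, pith_mask, suppression_radius_px,
                         min_prominence = 0) {
  stopifnot(suppression_radius_px >= 1)
  if (!any(pith_mask)) stop("stalkscan domain error: empty pith mask")
  vals <- img[pith_mask]
  rng <- range(vals)
  if (diff(rng) <= 0) {
    stop("stalkscan degenerate-input error: constant in-pith image")
  }
  t <- otsu_level(vals, rng[1], rng[2], 256L)
  brush <- EBImage::makeBrush(2L * floor(suppression_radius_px) + 1L, "disc")
  mx <- EBImage::imageData(EBImage::dilate(EBImage::Image(img), brush))
  cand <- which(pith_mask & img >= mx & img > t &
                  (img - t) >= min_prominence)
  if (length(cand) == 0L) return(matrix(integer(0), 0L, 2L,
                                        dimnames = list(NULL, c("row", "col"))))
  rr <- ((cand - 1L) %% nrow(img)) + 1L
  cc <- ((cand - 1L) %/% nrow(img)) + 1L
  v <- img[cand]
  ord <- order(-v, rr, cc)
  rr <- rr[ord]; cc <- cc[ord]
  keep_r <- numeric(0); keep_c <- numeric(0)
  r2 <- suppression_radius_px^2
  for (i in seq_along(rr)) {
    if (length(keep_r) == 0L ||
        all((keep_r - rr[i])^2 + (keep_c - cc[i])^2 >= r2)) {
      keep_r <- c(keep_r, rr[i]); keep_c <- c(keep_c, cc[i])
    }
  }
  ord2 <- order(keep_r, keep_c)
  cbind(row = keep_r[ord2], col = keep_c[ord2])
}

#' Combine automatic and manual bundle centers into a bundle set
#'
#' Manual centers outside the pith mask are dropped with a warning; manual
#' centers within the suppression radius of an automatic (or earlier manual)
#' center are treated as duplicates and dropped. Density is the total count
#' divided by the pith area in cm^2.
#'
#' @param auto n x 2 matrix of automatic (row, col) centers, 1-based.
#' @param manual m x 2 matrix of manual centers, 1-based (may be empty).
#' @param seg A `pith_segmentation`.
#' @param cal A `calibration`.
#' @param suppression_radius_px Radius used for duplicate suppression.
#' @return A `bundle_set`: `centers` (all retained centers), `n_auto`,
#'   `n_manual`, `density_per_cm2`.
#' @export
count_bundles <- function(auto, manual, seg, cal, suppression_radius_px) {
  auto <- as_centers(auto)
  manual <- as_centers(manual)
  kept <- matrix(numeric(0), 0L, 2L)
  if (nrow(manual) > 0L) {
    inside <- seg$pith_mask[manual]
    if (any(!inside)) {
      warning("stalkscan: ", sum(!inside),
              " manual bundle center(s) outside the pith mask dropped")
    }
    manual <- manual[inside, , drop = FALSE]
    r2 <- suppression_radius_px^2
    for (i in seq_len(nrow(manual))) {
      ref <- rbind(auto, kept)
      if (nrow(ref) == 0L ||
          all((ref[, 1] - manual[i, 1])^2 +
                (ref[, 2] - manual[i, 2])^2 >= r2)) {
        kept <- rbind(kept, manual[i, , drop = FALSE])
      }
    }
  }
  pith_cm2 <- seg$pith_area_px / cal$px_per_cm^2
  n <- nrow(auto) + nrow(kept)
  structure(list(
    centers = rbind(auto, kept), n_auto = nrow(auto), n_manual = nrow(kept),
    density_per_cm2 = if (pith_cm2 > 0) n / pith_cm2 else 0),
    class = "bundle_set")
}

as_centers <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2L)
  colnames(x) <- c("row", "col")
  x
}

#' Detect vascular bundles in one transection
#'
#' The full detection chain of the counting pipeline: grayscale crop ->
#' bundle-scale Gaussian smoothing -> Perona-Malik diffusion -> non-maximum
#' suppression restricted to the pith.
#'
#' @param image A `scan_image`.
#' @param obj A `transection`.
#' @param seg A `pith_segmentation` for `obj`.
#' @param config A [pipeline_config()]; supplies the bundle width, diffusion
#'   and suppression parameters.
#' @return n x 2 matrix of (row, col) centers in the cropped object frame,
#'   1-based.
#' @export
detect_bundles <- function(image, obj, seg, config = pipeline_config()) {
  cal <- calibration_from_dpi(image$dpi)
  gray <- to_grayscale(image)[obj$box[1]:obj$box[3], obj$box[2]:obj$box[4]]
  width_px <- config$bundle_width_cm * cal$px_per_cm
  sm <- bundle_smooth(gray, width_px)
  df <- anisotropic_diffusion(sm, config$diffusion)
  radius <- if (is.null(config$nms_radius_px)) width_px else
    config$nms_radius_px
  detect_peaks(df, seg$pith_mask, radius, config$min_prominence)
}
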