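#' Locate the pith/rind boundary of a transection
#'
#' The green channel inside the object is smoothed with an isotropic Gaussian
#' wide enough to suppress the textured rind signal while keeping the bright
#' pith signal, then thresholded with Otsu's method over the in-object
#' intensities only (the dark background would otherwise dominate the
#' histogram). The pith is the largest above-threshold 8-connected component,
#' hole-filled; the rind is the remainder of the object mask.
#'
#' The `filter_width` is a dimensionless multiplier on a base standard
#' deviation proportional to the section diameter
#' (`sigma = filter_width * sigma0_frac * mean_diameter_px`), so the default
#' transfers across species with very different stalk sizes. Filtering uses
#' normalized masked convolution (out-of-object pixels carry zero weight) so
#' the dark background cannot bleed in and shrink the pith.
#'
#' @param image A `scan_image`.
#' @param obj A `transection` from [extract_objects()].
#' @param filter_width Dimensionless Gaussian width multiplier (default 1.5;
#'   useful range roughly 1--2.5).
#' @param sigma0_frac Base sigma as a fraction of mean section diameter
#'   (default 0.012; large enough to flatten tissue texture, small enough
#'   that the boundary stays put across the filter_width range).
#' @param min_contrast Minimum separation of the pith and rind class means
#'   on the 0--255 scale; smaller separations are rejected as a degenerate
#'   (near-uniform) interior (default 10).
#' @return A `pith_segmentation`: `pith_mask` and `rind_mask` (logical, in
#'   the cropped object frame), `filter_width`, `pith_area_px`,
#'   `rind_thickness_px`, and `boundary_touch` (TRUE when the pith touches
#'   more than 20% of the object's outer boundary, flagging a likely failed
#'   rind suppression).
#' @export
pith_boundary <- function(image, obj, filter_width = 1.5,
                          sigma0_frac = 0.012, min_contrast = 10) {
  stopifnot(filter_width > 0, sigma0_frac > 0)
  box <- obj$box
  green <- image$pixels[box[1]:box[3], box[2]:box[4], 2]
  m <- obj$mask
  if (!any(m)) stop("stalkscan domain error: empty object mask")
  vals <- green[m]
  sigma <- filter_width * sigma0_frac * obj$mean_diameter_px
  # normalized masked convolution: out-of-object pixels carry no weight, so
  # the dark background cannot bleed in and shift the pith boundary
  num <- gaussian_blur(green * m, sigma)
  den <- gaussian_blur(m * 1, sigma)
  sm <- num / pmax(den, 1e-12)
  inside <- sm[m]
  rng <- range(inside)
  if (diff(rng) <= 0) {
    stop("stalkscan segmentation error: constant filtered interior")
  }
  t <- otsu_level(inside, rng[1], rng[2], 256L)
  cand <- sm > t & m
  lab <- label8(cand)
  if (max(lab) == 0L) {
    stop("stalkscan segmentation error: no above-threshold pith component")
  }
  # a genuine pith/rind boundary separates two well-contrasted classes;
  # near-uniform interiors produce splits a few gray levels apart
  contrast <- mean(inside[inside > t]) - mean(inside[inside <= t])
  if (!is.finite(contrast) || contrast < min_contrast) {
    stop("stalkscan segmentation error: pith/rind contrast ",
         round(contrast, 1), " below the minimum of ", min_contrast)
  }
  areas <- tabulate(lab[lab > 0])
  pith <- fill_holes(lab == which.max(areas)) & m
  if (sum(pith) > 0.95 * sum(m)) {
    stop("stalkscan segmentation error: no discernible rind (pith fills ",
         round(100 * sum(pith) / sum(m)), "% of the section)")
  }
  rind <- m & !pith
  outer_b <- boundary_pixels(m)
  touch <- sum(pith & outer_b) / sum(outer_b)
  seg <- structure(list(
    pith_mask = pith, rind_mask = rind, filter_width = filter_width,
    pith_area_px = sum(pith),
    rind_thickness_px = NA_real_,
    boundary_touch = touch > 0.2), class = "pith_segmentation")
  seg$rind_thickness_px <- rind_thickness_px(obj, seg)
  if (seg$boundary_touch) {
    warning("stalkscan: pith touches ", round(100 * touch),
            "% of the object boundary; rind suppression may have failed")
  }
  seg
}

# Mean Euclidean distance from each outer-boundary pixel of the object to the
# nearest pith-boundary pixel, via an exact Euclidean distance transform of
# the pith-boundary pixel set. Outer boundary: object pixels with a
# background 4-neighbor; pith boundary: pith pixels with a non-pith
# 4-neighbor.
rind_thickness_px <- function(obj, seg) {
  pith_b <- boundary_pixels(seg$pith_mask)
  outer_b <- boundary_pixels(obj$mask)
  if (!any(pith_b)) stop("stalkscan domain error: empty pith boundary")
  if (!any(outer_b)) stop("stalkscan domain error: empty object boundary")
  field <- matrix(1, nrow(obj$mask), ncol(obj$mask))
  field[pith_b] <- 0
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(field)))
  mean(dm[outer_b])
}

#' Mean rind thickness in centimeters
#'
#' For every pixel on the object's outer boundary, the Euclidean distance to
#' the nearest pixel of the pith/rind boundary is computed (by exact distance
#' transform); the mean of these distances, converted with the calibration,
#' is the rind thickness.
#'
#' @param obj A `transection`.
#' @param seg A `pith_segmentation` from [pith_boundary()].
#' @param cal A `calibration`.
#' @return Thickness in cm.
#' @export
rind_thickness <- function(obj, seg, cal) {
  rind_thickness_px(obj, seg) / cal$px_per_cm
}
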