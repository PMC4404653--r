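#' Specification for one synthetic stalk transection
#'
#' Defines the rendered geometry and realism of a scanner-like transection:
#' a bright pith disc inside a darker rind annulus on a dark background,
#' scattered bright elliptical vascular bundles with a minimum-spacing
#' constraint, low-amplitude smoothed parenchyma texture, a planar
#' illumination gradient, i.i.d. Gaussian pixel noise, 8-bit quantization,
#' and occasional debris (thin bright strokes with eccentricity > 0.99 and
#' small blobs below the size filter). Defaults emulate a maize section
#' scanned at 800 dpi.
#'
#' @param image_shape `c(rows, cols)` canvas size.
#' @param center Transection center `c(row, col)`; NULL = canvas center.
#' @param outer_radius_px Outer (rind) radius.
#' @param rind_thickness_px Annulus thickness (< outer radius).
#' @param pith_intensity,rind_intensity,background_intensity 8-bit levels.
#' @param n_bundles Number of vascular bundles.
#' @param sigma_major_range Range of bundle major-axis sigma (px).
#' @param sigma_minor_frac_range Minor axis as a fraction of the major.
#' @param bundle_intensity_boost Peak intensity added by a bundle.
#' @param min_spacing_px Minimum center spacing; must be at least 2x the
#'   maximum bundle radius (radius taken as 2 sigma_major).
#' @param bundle_margin_px Bundles are placed at least this far inside the
#'   true pith boundary.
#' @param illumination_gradient Planar gradient amplitude as a fraction
#'   (0.15 = +/-15% across the canvas).
#' @param noise_sigma Gaussian pixel noise sd, 8-bit units.
#' @param texture_amplitude,texture_sigma Parenchyma texture: sd of smoothed
#'   noise added in the pith and its smoothing sigma.
#' @param n_debris Number of debris objects (alternating strokes/blobs).
#' @param debris_length_range,debris_blob_radius_range Debris geometry (px).
#' @param dpi Nominal scan resolution carried into the `scan_image`.
#' @param seed Integer RNG seed; identical specs render bit-identical images.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(image_shape = c(700L, 700L), center = NULL,
                           outer_radius_px = 290, rind_thickness_px = 50,
                           pith_intensity = 120, rind_intensity = 80,
                           background_intensity = 18, n_bundles = 140L,
                           sigma_major_range = c(3.5, 5),
                           sigma_minor_frac_range = c(0.7, 1),
                           bundle_intensity_boost = 130,
                           min_spacing_px = 20, bundle_margin_px = 15,
                           illumination_gradient = 0.15, noise_sigma = 5,
                           texture_amplitude = 4, texture_sigma = 3,
                           n_debris = 0L, debris_length_range = c(60, 150),
                           debris_blob_radius_range = c(8, 25),
                           dpi = 800, seed = 1L) {
  spec <- list(image_shape = as.integer(image_shape), center = center,
               outer_radius_px = outer_radius_px,
               rind_thickness_px = rind_thickness_px,
               pith_intensity = pith_intensity,
               rind_intensity = rind_intensity,
               background_intensity = background_intensity,
               n_bundles = as.integer(n_bundles),
               sigma_major_range = sigma_major_range,
               sigma_minor_frac_range = sigma_minor_frac_range,
               bundle_intensity_boost = bundle_intensity_boost,
               min_spacing_px = min_spacing_px,
               bundle_margin_px = bundle_margin_px,
               illumination_gradient = illumination_gradient,
               noise_sigma = noise_sigma,
               texture_amplitude = texture_amplitude,
               texture_sigma = texture_sigma,
               n_debris = as.integer(n_debris),
               debris_length_range = debris_length_range,
               debris_blob_radius_range = debris_blob_radius_range,
               dpi = dpi, seed = as.integer(seed))
  if (spec$rind_thickness_px >= spec$outer_radius_px) {
    stop("stalkscan spec error: rind thickness must be < outer radius")
  }
  if (spec$min_spacing_px < 4 * max(spec$sigma_major_range)) {
    stop("stalkscan spec error: min spacing must be >= 2 x max bundle radius",
         " (radius = 2 sigma_major)")
  }
  ints <- c(spec$pith_intensity, spec$rind_intensity,
            spec$background_intensity)
  if (any(ints < 0 | ints > 255)) {
    stop("stalkscan spec error: intensities must be in [0, 255]")
  }
  structure(spec, class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Antialiased disc coverage by 4x supersampling + box downsample, over the
# window rows r0..r1, cols c0..c1 (1-based, within canvas).
disc_coverage <- function(r0, r1, c0, c1, cr, cc, radius) {
  s <- 4L
  ys <- r0 - 0.5 + (seq_len((r1 - r0 + 1L) * s) - 0.5) / s
  xs <- c0 - 0.5 + (seq_len((c1 - c0 + 1L) * s) - 0.5) / s
  inside <- outer((ys - cr)^2, (xs - cc)^2, `+`) <= radius^2
  dn <- dim(inside) / s
  m <- matrix(inside, s, prod(dn) * s)
  m <- colMeans(m)                         # average over sub-rows
  m <- matrix(m, dn[1], dn[2] * s)
  t(matrix(colMeans(matrix(t(m), s, prod(dn))), dn[2], dn[1]))
}

# Place n points uniformly in a disc of radius rmax about (cr, cc) with
# minimum pairwise spacing; up to 10^4 candidate draws per point.
place_bundles <- function(n, cr, cc, rmax, spacing) {
  pts <- matrix(numeric(0), 0L, 2L)
  s2 <- spacing^2
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(10000L)) {
      rad <- rmax * sqrt(stats::runif(1))
      ang <- stats::runif(1, 0, 2 * pi)
      p <- c(cr + rad * sin(ang), cc + rad * cos(ang))
      if (nrow(pts) == 0L ||
          all((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 >= s2)) {
        pts <- rbind(pts, p)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("stalkscan spec error: could not place ", n,
           " bundles at spacing ", spacing, " (stuck at ", i - 1L, ")")
    }
  }
  pts
}

# Add one rotated 2D Gaussian boost to the canvas, in place.
add_blob <- function(img, cr, cc, amp, smaj, smin, theta) {
  ext <- ceiling(4 * smaj)
  r0 <- max(1L, floor(cr - ext)); r1 <- min(nrow(img), ceiling(cr + ext))
  c0 <- max(1L, floor(cc - ext)); c1 <- min(ncol(img), ceiling(cc + ext))
  dr <- (r0:r1) - cr; dc <- (c0:c1) - cc
  # major axis direction (sin theta, cos theta) in (row, col)
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dr * st, dc * ct, `+`)     # along major axis
  v <- outer(dr * ct, -dc * st, `+`)    # along minor axis
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
    amp * exp(-(u^2 / smaj^2 + v^2 / smin^2) / 2)
  img
}

render_scene <- function(specs, centers, shape, canvas_spec) {
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(canvas_spec$background_intensity, nr, nc)
  truth <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    ctr <- centers[[k]]
    R <- sp$outer_radius_px
    rp <- R - sp$rind_thickness_px
    r0 <- max(1L, floor(ctr[1] - R - 2)); r1 <- min(nr, ceiling(ctr[1] + R + 2))
    c0 <- max(1L, floor(ctr[2] - R - 2)); c1 <- min(nc, ceiling(ctr[2] + R + 2))
    covO <- disc_coverage(r0, r1, c0, c1, ctr[1], ctr[2], R)
    covP <- disc_coverage(r0, r1, c0, c1, ctr[1], ctr[2], rp)
    win <- img[r0:r1, c0:c1]
    win <- win * (1 - covO) + sp$rind_intensity * (covO - covP) +
      sp$pith_intensity * covP
    if (sp$texture_amplitude > 0) {
      tex <- gaussian_blur(matrix(stats::rnorm(length(win)), nrow(win)),
                           sp$texture_sigma)
      tex <- tex / stats::sd(tex) * sp$texture_amplitude
      win <- win + tex * covP
    }
    img[r0:r1, c0:c1] <- win
    if (sp$n_bundles > 0L) {
      pts <- place_bundles(sp$n_bundles, ctr[1], ctr[2],
                           rp - sp$bundle_margin_px, sp$min_spacing_px)
      smaj <- stats::runif(sp$n_bundles, sp$sigma_major_range[1],
                           sp$sigma_major_range[2])
      smin <- smaj * stats::runif(sp$n_bundles,
                                  sp$sigma_minor_frac_range[1],
                                  sp$sigma_minor_frac_range[2])
      theta <- stats::runif(sp$n_bundles, -pi / 2, pi / 2)
      for (i in seq_len(sp$n_bundles)) {
        img <- add_blob(img, pts[i, 1], pts[i, 2],
                        sp$bundle_intensity_boost, smaj[i], smin[i],
                        theta[i])
      }
    } else {
      pts <- matrix(numeric(0), 0L, 2L)
      smaj <- smin <- theta <- numeric(0)
    }
    obj_mask <- covO >= 0.5
    pith_mask <- covP >= 0.5
    truth[[k]] <- list(
      box = c(top = r0, left = c0, bottom = r1, right = c1),
      center = ctr, outer_radius_px = R, pith_radius_px = rp,
      rind_thickness_px = sp$rind_thickness_px,
      object_mask = obj_mask, pith_mask = pith_mask,
      object_area_px = sum(obj_mask), pith_area_px = sum(pith_mask),
      centers = pts, sigma_major = smaj, sigma_minor = smin, theta = theta)
  }
  # debris, kept clear of the transection discs
  nstk <- canvas_spec$n_debris
  if (nstk > 0L) {
    far_enough <- function(p, margin) {
      all(vapply(seq_along(specs), function(k) {
        sqrt(sum((centers[[k]] - p)^2)) >
          specs[[k]]$outer_radius_px + margin
      }, logical(1)))
    }
    for (d in seq_len(nstk)) {
      for (try in seq_len(1000L)) {
        p <- c(stats::runif(1, 20, nr - 20), stats::runif(1, 20, nc - 20))
        if (length(specs) == 0L || far_enough(p, 160)) break
      }
      if (d %% 2L == 1L) {
        len <- stats::runif(1, canvas_spec$debris_length_range[1],
                            canvas_spec$debris_length_range[2])
        ang <- stats::runif(1, 0, pi)
        tt <- seq(0, 1, length.out = ceiling(len) * 2L)
        rr <- round(p[1] + tt * len * sin(ang))
        cc <- round(p[2] + tt * len * cos(ang))
        keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        img[cbind(rr[keep], cc[keep])] <- 180
      } else {
        rad <- stats::runif(1, canvas_spec$debris_blob_radius_range[1],
                            canvas_spec$debris_blob_radius_range[2])
        r0 <- max(1L, floor(p[1] - rad)); r1 <- min(nr, ceiling(p[1] + rad))
        c0 <- max(1L, floor(p[2] - rad)); c1 <- min(nc, ceiling(p[2] + rad))
        cov <- disc_coverage(r0, r1, c0, c1, p[1], p[2], rad)
        img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] * (1 - cov) + 150 * cov
      }
    }
  }
  if (canvas_spec$illumination_gradient > 0) {
    ang <- stats::runif(1, 0, 2 * pi)
    u <- outer((seq_len(nr) - (nr + 1) / 2) * sin(ang),
               (seq_len(nc) - (nc + 1) / 2) * cos(ang), `+`)
    u <- u / max(abs(u))
    img <- img * (1 + canvas_spec$illumination_gradient * u)
  }
  if (canvas_spec$noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), 0, canvas_spec$noise_sigma)
  }
  img <- round(pmin(pmax(img, 0), 255))   # 8-bit quantization
  list(image = scan_image(array(img, dim = c(nr, nc, 3L)),
                          dpi = canvas_spec$dpi, source_id = "<synthetic>"),
       truth = truth)
}

#' Render one synthetic transection with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return List with `image` (a `scan_image`) and `truth` (a one-element
#'   list; each element holds the window `box`, true object and pith masks
#'   in the window frame, true bundle `centers` (canvas frame, 1-based) with
#'   per-bundle `sigma_major`, `sigma_minor`, `theta`, and the true radii,
#'   areas, and rind thickness in px). Identical specs give bit-identical
#'   output; the caller's RNG state is untouched.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ctr <- if (is.null(spec$center)) (spec$image_shape + 1) / 2 else spec$center
  with_seed(spec$seed,
            render_scene(list(spec), list(ctr), spec$image_shape, spec))
}

#' Render a multi-transection scan (the 12-per-scan layout)
#'
#' Places each spec's transection on a regular grid in one canvas, the way
#' twelve sections are laid out on the scanner bed, plus canvas-level debris,
#' illumination gradient and noise (taken from the first spec).
#'
#' @param specs List of [synthetic_spec()]s (may be empty).
#' @param layout `c(rows, cols)` grid; must hold `length(specs)` sections
#'   without overlap.
#' @param spacing_px Clearance added between grid cells.
#' @return As [generate()], with one `truth` entry per transection in
#'   row-major grid order.
#' @export
composite_scene <- function(specs, layout, spacing_px = 60) {
  if (length(specs) == 0L) {
    empty <- synthetic_spec(n_bundles = 0L)
    return(with_seed(empty$seed,
                     render_scene(list(), list(), c(256L, 256L), empty)))
  }
  stopifnot(length(specs) <= prod(layout))
  maxR <- max(vapply(specs, function(s) s$outer_radius_px, numeric(1)))
  cell <- 2 * maxR + spacing_px
  for (s in specs) {
    if (2 * s$outer_radius_px >= cell) {
      stop("stalkscan spec error: transections overlap in the grid")
    }
  }
  shape <- c(as.integer(layout[1] * cell), as.integer(layout[2] * cell))
  centers <- lapply(seq_along(specs) - 1L, function(i) {
    c((i %/% layout[2]) * cell + cell / 2,
      (i %% layout[2]) * cell + cell / 2)
  })
  with_seed(specs[[1]]$seed,
            render_scene(specs, centers, shape, specs[[1]]))
}

#' Write a synthetic scene to disk
#'
#' Writes the rendered image as TIFF and the ground truth (boxes, centers,
#' bundle shapes, radii; masks omitted) as a JSON sidecar with 0-based
#' coordinates.
#'
#' @param scene Result of [generate()] or [composite_scene()].
#' @param image_path Output TIFF path.
#' @param truth_path Optional output JSON path.
#' @export
write_scene <- function(scene, image_path, truth_path = NULL) {
  tiff::writeTIFF(scene$image$pixels / 255, image_path)
  if (!is.null(truth_path)) {
    tr <- lapply(scene$truth, function(t) {
      list(box = c(top = t$box[[1]] - 1L, left = t$box[[2]] - 1L,
                   bottom = t$box[[3]], right = t$box[[4]]),
           center = t$center - 1, outer_radius_px = t$outer_radius_px,
           pith_radius_px = t$pith_radius_px,
           rind_thickness_px = t$rind_thickness_px,
           object_area_px = t$object_area_px,
           pith_area_px = t$pith_area_px,
           centers = if (nrow(t$centers)) unname(t$centers - 1) else list(),
           sigma_major = t$sigma_major, sigma_minor = t$sigma_minor,
           theta = t$theta)
    })
    jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(image_path)
}
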