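#' Pipeline configuration
#'
#' All tunable parameters of the measurement pipeline, with defaults suited
#' to maize sections scanned at 800 dpi. Effective values are echoed to the
#' provenance sidecar so every CSV number is reproducible from the sidecar
#' alone.
#'
#' @param min_area Minimum object area in px (debris filter).
#' @param max_eccentricity Maximum object eccentricity (debris filter).
#' @param filter_width Rind Gaussian width multiplier (see
#'   [pith_boundary()]).
#' @param sigma0_frac Base rind sigma as a fraction of section diameter.
#' @param bundle_width_cm Typical bundle diameter in cm; converted with the
#'   calibration to the smoothing width and default suppression radius
#'   (0.03 cm is about 9 px at 315 px/cm; reduce for small-bundled species
#'   such as Miscanthus).
#' @param nms_radius_px Non-maximum suppression radius in px; NULL = use the
#'   bundle width in px.
#' @param min_prominence Minimum peak excess over the in-pith Otsu level.
#' @param diffusion A [diffusion_params()] list.
#' @param patch_size Bundle-size patch side in px.
#' @param contour_multiplier Bundle-area level contour, in sigmas.
#' @param cutoff_frac,gain_low,gain_high Homomorphic filter settings.
#' @param dpi_override Resolution fallback for files without metadata.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_area = 15000L, max_eccentricity = 0.99,
                            filter_width = 1.5, sigma0_frac = 0.012,
                            bundle_width_cm = 0.03, nms_radius_px = NULL,
                            min_prominence = 0,
                            diffusion = diffusion_params(),
                            patch_size = 40L, contour_multiplier = 2,
                            cutoff_frac = 0.08, gain_low = 0.5,
                            gain_high = 1.5, dpi_override = NULL) {
  stopifnot(min_area >= 1, max_eccentricity >= 0, max_eccentricity < 1,
            filter_width > 0, sigma0_frac > 0, bundle_width_cm > 0,
            patch_size >= 8, contour_multiplier > 0)
  if (!inherits(diffusion, "diffusion_params")) {
    diffusion <- do.call(diffusion_params, diffusion)
  }
  structure(list(min_area = as.integer(min_area),
                 max_eccentricity = max_eccentricity,
                 filter_width = filter_width, sigma0_frac = sigma0_frac,
                 bundle_width_cm = bundle_width_cm,
                 nms_radius_px = nms_radius_px,
                 min_prominence = min_prominence, diffusion = diffusion,
                 patch_size = as.integer(patch_size),
                 contour_multiplier = contour_multiplier,
                 cutoff_frac = cutoff_frac, gain_low = gain_low,
                 gain_high = gain_high, dpi_override = dpi_override),
            class = "pipeline_config")
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$diffusion <- unclass(out$diffusion)
  out
}

#' Analyze one scan end to end
#'
#' Load -> grayscale -> Otsu segmentation -> debris filter -> object
#' extraction -> per-object morphometry, rind segmentation, bundle detection
#' and bundle sizing -> one trait record per transection. A failure in one
#' object (e.g. a rind segmentation error on a uniform interior) is logged
#' as a warning and leaves that object's affected fields NA without aborting
#' the scan.
#'
#' @param x A file path or a `scan_image`.
#' @param config A [pipeline_config()].
#' @param overrides Optional list from [read_overrides()]: `crop_boxes`
#'   (per-object, scan order) and `manual_bundles` (n x 2, 1-based,
#'   full-image frame).
#' @param sidecar Optional path; when given, a provenance JSON sidecar with
#'   the effective parameters, crop boxes and bundle centers is written.
#' @return Data frame of trait records (one row per transection; columns as
#'   [trait_columns()]).
#' @export
run_scan <- function(x, config = pipeline_config(), overrides = NULL,
                     sidecar = NULL) {
  image <- if (inherits(x, "scan_image")) x else
    load_scan(x, dpi_override = config$dpi_override)
  cal <- calibration_from_dpi(image$dpi)
  gray <- to_grayscale(image)
  mask <- filter_objects(segment_foreground(gray), config$min_area,
                         config$max_eccentricity)
  objs <- extract_objects(image, mask, overrides$crop_boxes)
  if (length(objs) == 0L) {
    warning("stalkscan: no stalk objects found in ", image$source_id)
  }
  manual_all <- overrides$manual_bundles
  rows <- vector("list", length(objs))
  boxes <- vector("list", length(objs))
  all_centers <- list()
  for (i in seq_along(objs)) {
    obj <- objs[[i]]
    boxes[[i]] <- obj$box
    morph <- measure_morphology(obj, cal)
    rec <- data.frame(
      source_id = image$source_id, transection_index = obj$index,
      area_cm2 = morph$area_cm2, mean_diameter_cm = morph$mean_diameter_cm,
      perimeter_cm = morph$perimeter_cm, rind_thickness_cm = NA_real_,
      pith_area_cm2 = NA_real_, bundle_count = NA_integer_,
      bundle_density_per_cm2 = NA_real_, mean_bundle_area_cm2 = NA_real_,
      n_manual_bundles = 0L)
    seg <- tryCatch(
      pith_boundary(image, obj, config$filter_width, config$sigma0_frac),
      error = function(e) {
        warning("stalkscan: object ", obj$index, " of ", image$source_id,
                ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(seg)) {
      rec$rind_thickness_cm <- seg$rind_thickness_px / cal$px_per_cm
      rec$pith_area_cm2 <- seg$pith_area_px / cal$px_per_cm^2
      manual <- manual_in_box(manual_all, obj$box)
      res <- tryCatch({
        auto <- detect_bundles(image, obj, seg, config)
        width_px <- config$bundle_width_cm * cal$px_per_cm
        radius <- if (is.null(config$nms_radius_px)) width_px else
          config$nms_radius_px
        bs <- count_bundles(auto, manual, seg, cal, radius)
        g <- gray[obj$box[1]:obj$box[3], obj$box[2]:obj$box[4]]
        sizes <- bundle_sizes(g, bs, cal, config$patch_size,
                              config$contour_multiplier, TRUE,
                              config$cutoff_frac, config$gain_low,
                              config$gain_high)
        list(bs = bs, sizes = sizes)
      }, error = function(e) {
        warning("stalkscan: object ", obj$index, " of ", image$source_id,
                ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) {
        rec$bundle_count <- res$bs$n_auto + res$bs$n_manual
        rec$n_manual_bundles <- res$bs$n_manual
        rec$bundle_density_per_cm2 <- res$bs$density_per_cm2
        rec$mean_bundle_area_cm2 <- res$sizes$mean_bundle_area_cm2
        if (nrow(res$bs$centers) > 0L) {
          all_centers[[length(all_centers) + 1L]] <-
            cbind(res$bs$centers[, 1] + obj$box[1] - 1L,
                  res$bs$centers[, 2] + obj$box[2] - 1L)
        }
      }
    }
    rows[[i]] <- rec
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    utils::read.csv(text = paste(trait_columns(), collapse = ","))
  if (!is.null(sidecar)) {
    centers <- if (length(all_centers)) do.call(rbind, all_centers) else NULL
    write_sidecar(sidecar, config_as_list(config), boxes, centers,
                  extra = list(source_id = image$source_id))
  }
  out
}

manual_in_box <- function(manual, box) {
  if (is.null(manual) || nrow(manual) == 0L) {
    return(matrix(numeric(0), 0L, 2L))
  }
  keep <- manual[, 1] >= box[1] & manual[, 1] <= box[3] &
    manual[, 2] >= box[2] & manual[, 2] <= box[4]
  m <- manual[keep, , drop = FALSE]
  m[, 1] <- m[, 1] - box[1] + 1L
  m[, 2] <- m[, 2] - box[2] + 1L
  m
}

#' Analyze a batch of scans
#'
#' Processes every page of every input, writes a combined trait CSV (rows in
#' path order, then object scan order) and one provenance sidecar per scan,
#' and logs per-file failures without aborting the batch.
#'
#' @param paths Character vector of image paths (>= 1).
#' @param config A [pipeline_config()].
#' @param out_csv Output trait CSV path.
#' @param sidecar_dir Optional directory for per-scan JSON sidecars.
#' @param overrides Optional list (or single set) of overrides per path.
#' @return Invisibly, a list with `records` (the combined data frame),
#'   `n_failed` (failed input files), and `failures` (messages). Errors if
#'   every input failed.
#' @export
run_batch <- function(paths, config = pipeline_config(), out_csv = NULL,
                      sidecar_dir = NULL, overrides = NULL) {
  if (length(paths) == 0L) {
    stop("stalkscan usage error: no input paths given")
  }
  all_rows <- list()
  failures <- character(0)
  for (j in seq_along(paths)) {
    p <- paths[j]
    ov <- if (is.null(overrides)) NULL
    else if (!is.null(names(overrides)) && p %in% names(overrides))
      overrides[[p]]
    else if (length(overrides) == length(paths)) overrides[[j]]
    else overrides
    res <- tryCatch({
      npg <- scan_pages(p)
      pages <- lapply(seq_len(npg), function(pg) {
        img <- load_scan(p, dpi_override = config$dpi_override, page = pg)
        sc <- if (is.null(sidecar_dir)) NULL else
          file.path(sidecar_dir,
                    paste0(sub("\\.[^.]*$", "", basename(p)),
                           if (npg > 1L) paste0("_p", pg) else "",
                           ".json"))
        run_scan(img, config, ov, sidecar = sc)
      })
      do.call(rbind, pages)
    }, error = function(e) {
      message("stalkscan: FAILED ", p, ": ", conditionMessage(e))
      failures <<- c(failures, paste0(p, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) all_rows[[length(all_rows) + 1L]] <- res
  }
  if (length(all_rows) == 0L) {
    stop("stalkscan batch error: all ", length(paths), " input(s) failed")
  }
  records <- do.call(rbind, all_rows)
  if (!is.null(out_csv)) write_traits(records, out_csv)
  message(sprintf("stalkscan: %d transection(s) from %d scan(s); %d file(s) failed",
                  nrow(records), length(paths) - length(failures),
                  length(failures)))
  invisible(list(records = records, n_failed = length(failures),
                 failures = failures))
}
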