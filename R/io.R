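#' Read a scanner image with physical calibration
#'
#' Reads a TIFF or PNG scan of stalk transections into a `scan_image`: an
#' 8-bit-scaled RGB raster plus the scan resolution. Grayscale inputs are
#' replicated across the three channels so the green-channel rind step
#' degrades gracefully; 16-bit inputs are rescaled to the 0--255 range all
#' downstream thresholds assume. Multi-page TIFFs hold one scan per page.
#'
#' @param path Path to a TIFF or PNG file.
#' @param dpi_override Scan resolution in dots per inch, used when the file
#'   carries no resolution metadata. Ignored if metadata is present.
#' @param page Page to read from a multi-page TIFF (1-based). See
#'   [scan_pages()].
#' @return A `scan_image`: list with `pixels` (rows x cols x 3 numeric array,
#'   values in 0--255), `dpi`, and `source_id` (the file path, with
#'   `#<page>` appended for pages beyond the first).
#' @seealso [calibration_from_dpi()], [run_scan()]
#' @export
load_scan <- function(path, dpi_override = NULL, page = 1L) {
  if (!file.exists(path)) {
    stop("stalkscan input error: file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  dpi <- NULL
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (page < 1L || page > length(pages)) {
      stop("stalkscan input error: page ", page, " of ", length(pages),
           "-page TIFF: ", path)
    }
    raw <- pages[[page]]
    xres <- attr(raw, "x.resolution")
    unit <- attr(raw, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0) {
      dpi <- switch(if (is.null(unit)) "inch" else unit,
                    inch = xres, cm = xres * 2.54, NULL)
    }
  } else if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (!is.null(info$dpi) && all(is.finite(info$dpi)) && info$dpi[1] > 0) {
      dpi <- info$dpi[1]
    }
  } else {
    stop("stalkscan input error: unsupported format '", ext,
         "' (TIFF or PNG required): ", path)
  }
  if (is.null(dpi)) {
    if (is.null(dpi_override)) {
      stop("stalkscan calibration error: no resolution metadata in ", path,
           " and no dpi_override given")
    }
    stopifnot(is.numeric(dpi_override), dpi_override > 0)
    dpi <- dpi_override
  }
  # readTIFF/readPNG scale any bit depth to [0, 1]; x 255 recovers the 8-bit
  # scale exactly (a 16-bit value v maps to v/257, i.e. 65535 -> 255).
  px <- as_rgb255(raw)
  source_id <- if (page > 1L) paste0(path, "#", page) else path
  scan_image(px, dpi = dpi, source_id = source_id)
}

#' Number of pages (scans) in an image file
#'
#' @param path Path to a TIFF or PNG file.
#' @return Integer page count (always 1 for PNG).
#' @export
scan_pages <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    length(tiff::readTIFF(path, all = TRUE))
  } else {
    1L
  }
}

as_rgb255 <- function(raw) {
  if (length(dim(raw)) == 2L) {
    px <- array(raw * 255, dim = c(dim(raw), 3L))
  } else {
    # drop an alpha channel if present; replicate single channel
    nc <- dim(raw)[3]
    if (nc >= 3L) {
      px <- raw[, , 1:3, drop = FALSE] * 255
    } else {
      px <- array(raw[, , 1L] * 255, dim = c(dim(raw)[1:2], 3L))
    }
  }
  px
}

#' Construct a scan_image from an in-memory raster
#'
#' @param pixels rows x cols x 3 array with values in 0--255, or a matrix
#'   (replicated to 3 channels).
#' @param dpi Scan resolution in dots per inch.
#' @param source_id Identifier carried into trait records.
#' @return A `scan_image` object.
#' @export
scan_image <- function(pixels, dpi, source_id = "<memory>") {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 3L))
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            dim(pixels)[1] >= 1L, dim(pixels)[2] >= 1L)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("stalkscan input error: pixel values outside [0, 255]")
  }
  stopifnot(is.numeric(dpi), length(dpi) == 1L, dpi > 0)
  structure(list(pixels = pixels, dpi = as.numeric(dpi),
                 source_id = source_id),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("scan_image: %d x %d px, 3 channels, %g dpi [%s]\n",
              d[1], d[2], x$dpi, x$source_id))
  invisible(x)
}

#' Physical calibration from scan resolution
#'
#' Converts dots per inch to pixels per centimeter using exactly
#' 2.54 cm/inch. At the scanner's native 800 dpi this gives 314.96 px/cm,
#' i.e. the commonly quoted 315 px/cm once rounded; the exact value is kept
#' internally and never rounded.
#'
#' @param dpi Scan resolution, dots per inch (> 0).
#' @return A `calibration`: list with `px_per_cm`.
#' @examples
#' round(calibration_from_dpi(800)$px_per_cm)  # 315
#' @export
calibration_from_dpi <- function(dpi) {
  if (!is.numeric(dpi) || length(dpi) != 1L || !is.finite(dpi) || dpi <= 0) {
    stop("stalkscan domain error: dpi must be a positive number")
  }
  structure(list(px_per_cm = dpi / 2.54), class = "calibration")
}

#' Column order of the trait table
#' @return Character vector of trait CSV column names, in file order.
#' @export
trait_columns <- function() {
  c("source_id", "transection_index", "area_cm2", "mean_diameter_cm",
    "perimeter_cm", "rind_thickness_cm", "pith_area_cm2", "bundle_count",
    "bundle_density_per_cm2", "mean_bundle_area_cm2", "n_manual_bundles")
}

#' Write per-transection trait records to CSV
#'
#' One header row plus one row per transection, columns in the fixed order of
#' [trait_columns()]. Floats are serialized with 6 significant digits.
#' A record with zero pith area is written with density 0 (with a warning)
#' rather than NaN, keeping downstream CSV consumers simple.
#'
#' @param records Data frame of trait records (missing columns are filled
#'   with NA; `transection_index` is 0-based).
#' @param path Output CSV path.
#' @return Invisibly, the formatted data frame that was written.
#' @export
write_traits <- function(records, path) {
  cols <- trait_columns()
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    records <- as.data.frame(records)
    for (cl in setdiff(cols, names(records))) records[[cl]] <- NA
    df <- records[, cols]
    zero_pith <- !is.na(df$pith_area_cm2) & df$pith_area_cm2 <= 0
    if (any(zero_pith)) {
      warning("stalkscan: ", sum(zero_pith),
              " record(s) with zero pith area; density written as 0")
      df$bundle_density_per_cm2[zero_pith] <- 0
    }
  }
  out <- df
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("transection_index", "bundle_count", "n_manual_bundles"))
  for (cl in names(out)[num]) {
    out[[cl]] <- ifelse(is.na(df[[cl]]), NA,
                        formatC(df[[cl]], digits = 6, format = "g"))
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(out)
}

#' Read a trait CSV written by [write_traits()]
#' @param path CSV path.
#' @return Data frame with the trait columns.
#' @export
read_traits <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a per-scan provenance sidecar
#'
#' Records crop boxes, manual bundle coordinates and all effective parameters
#' as JSON so every number in the trait CSV can be reproduced from the sidecar
#' alone. Coordinates in the sidecar are 0-based (row, col); crop boxes are
#' 0-based half-open (top, left, bottom, right), matching the documented
#' external convention. The in-memory R API is 1-based.
#'
#' @param path Output JSON path.
#' @param params Named list of effective pipeline parameters.
#' @param boxes List of crop boxes, each `c(top, left, bottom, right)`
#'   1-based closed as used internally (converted on write).
#' @param manual_bundles Optional n x 2 matrix of manual (row, col) centers,
#'   1-based (converted on write).
#' @param extra Optional named list merged into the sidecar.
#' @export
write_sidecar <- function(path, params, boxes = list(), manual_bundles = NULL,
                          extra = list()) {
  side <- c(list(
    params = params,
    crop_boxes = lapply(boxes, function(b) {
      if (is.null(b)) return(NULL)
      list(top = unname(b[1]) - 1L, left = unname(b[2]) - 1L,
           bottom = unname(b[3]), right = unname(b[4]))
    }),
    manual_bundles = if (is.null(manual_bundles) || nrow(manual_bundles) == 0L)
      list() else unname(apply(manual_bundles - 1L, 1L, as.list))
  ), extra)
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read user overrides from a JSON sidecar
#'
#' @param path Sidecar JSON path.
#' @return List with `crop_boxes` (list of 1-based closed
#'   `c(top, left, bottom, right)` vectors or NULLs) and `manual_bundles`
#'   (n x 2 matrix of 1-based (row, col) centers).
#' @export
read_overrides <- function(path) {
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  boxes <- side$crop_boxes
  if (!is.null(boxes) && length(boxes) > 0L) {
    if (is.data.frame(boxes)) boxes <- split(boxes, seq_len(nrow(boxes)))
    boxes <- lapply(boxes, function(b) {
      if (is.null(b) || all(is.na(unlist(b)))) return(NULL)
      b <- unlist(b)
      c(top = b[["top"]] + 1L, left = b[["left"]] + 1L,
        bottom = b[["bottom"]], right = b[["right"]])
    })
  } else boxes <- list()
  mb <- side$manual_bundles
  mb <- if (is.null(mb) || length(mb) == 0L) {
    matrix(numeric(0), 0L, 2L)
  } else if (is.matrix(mb)) {
    mb + 1
  } else {
    do.call(rbind, lapply(mb, unlist)) + 1
  }
  list(crop_boxes = boxes, manual_bundles = mb)
}
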