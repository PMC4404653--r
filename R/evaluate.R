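#' One-to-one matching of detected and true bundle centers
#'
#' Greedy nearest-pair matching: candidate pairs within `radius` are matched
#' in order of increasing distance, each center used at most once. Used to
#' score detection against synthetic ground truth.
#'
#' @param detected n x 2 matrix of (row, col) centers.
#' @param truth m x 2 matrix of true centers (same frame).
#' @param radius Maximum match distance in px (default 8).
#' @return List with `n_matched`, `recall` (matched / m), `fdr`
#'   (unmatched detections / n; 0 when n = 0).
#' @export
match_centers <- function(detected, truth, radius = 8) {
  detected <- as_centers(detected)
  truth <- as_centers(truth)
  if (nrow(truth) == 0L || nrow(detected) == 0L) {
    return(list(n_matched = 0L,
                recall = if (nrow(truth) == 0L) NA_real_ else 0,
                fdr = if (nrow(detected) == 0L) 0 else 1))
  }
  D <- outer(detected[, 1], truth[, 1], `-`)^2 +
    outer(detected[, 2], truth[, 2], `-`)^2
  pairs <- which(D <= radius^2, arr.ind = TRUE)
  pairs <- pairs[order(D[pairs]), , drop = FALSE]
  free_d <- rep(TRUE, nrow(detected))
  free_t <- rep(TRUE, nrow(truth))
  m <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (free_d[i] && free_t[j]) {
      m <- m + 1L
      free_d[i] <- FALSE
      free_t[j] <- FALSE
    }
  }
  list(n_matched = m, recall = m / nrow(truth), fdr = 1 - m / nrow(detected))
}

#' Score bundle detection on one synthetic transection
#'
#' Runs the standard detection chain (segment, filter, extract, pith
#' boundary, smooth + diffuse + non-maximum suppression) on a generated
#' scene and matches the detected centers against the ground truth.
#'
#' @param scene Result of [generate()] (single transection).
#' @param config A [pipeline_config()].
#' @param radius Match radius in px (default 8).
#' @return List with `recall`, `fdr`, `n_detected`, `n_true`.
#' @export
score_detection <- function(scene, config = pipeline_config(), radius = 8) {
  img <- scene$image
  gray <- to_grayscale(img)
  mask <- filter_objects(segment_foreground(gray), config$min_area,
                         config$max_eccentricity)
  objs <- extract_objects(img, mask)
  if (length(objs) != 1L) {
    stop("stalkscan: expected one transection, found ", length(objs))
  }
  obj <- objs[[1]]
  seg <- pith_boundary(img, obj, config$filter_width, config$sigma0_frac)
  auto <- detect_bundles(img, obj, seg, config)
  truth <- scene$truth[[1]]
  tc <- truth$centers
  tc[, 1] <- tc[, 1] - obj$box[1] + 1
  tc[, 2] <- tc[, 2] - obj$box[2] + 1
  m <- match_centers(auto, tc, radius)
  list(recall = m$recall, fdr = m$fdr, n_detected = nrow(auto),
       n_true = nrow(tc))
}
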