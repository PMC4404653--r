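# Small geometric fixtures and independent oracles used across tests.

# Filled disc / ellipse masks (logical matrices).
mk_disc <- function(nr, nc, cr, cc, radius) {
  outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, `+`) <= radius^2
}

mk_ellipse <- function(nr, nc, cr, cc, a_row, a_col) {
  outer(((seq_len(nr) - cr) / a_row)^2, ((seq_len(nc) - cc) / a_col)^2,
        `+`) <= 1
}

# A scan_image with identical channels from a plain matrix.
mk_image <- function(gray, dpi = 800) {
  stalkscan::scan_image(array(gray, dim = c(dim(gray), 3L)), dpi = dpi)
}

# Rotated 2D Gaussian blob evaluated on an nr x nc grid; theta is the
# major-axis angle from the column axis, matching the generator and fitter.
mk_blob <- function(nr, nc, cr, cc, A, smaj, smin, theta, baseline = 0) {
  dr <- outer(seq_len(nr) - cr, rep(1, nc))
  dc <- outer(rep(1, nr), seq_len(nc) - cc)
  u <- dr * sin(theta) + dc * cos(theta)
  v <- dr * cos(theta) - dc * sin(theta)
  baseline + A * exp(-(u^2 / smaj^2 + v^2 / smin^2) / 2)
}

# Exhaustive-scan Otsu oracle: brute-force loop over all 256 candidate
# levels of the 0..255 histogram, maximizing between-class variance.
otsu_bruteforce <- function(gray) {
  bin <- round(as.numeric(gray))
  bin[bin < 0] <- 0; bin[bin > 255] <- 255
  counts <- tabulate(bin + 1L, nbins = 256L)
  p <- counts / sum(counts)
  best_t <- NA_real_; best_v <- -Inf
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)])
    if (w0 <= 0 || w0 >= 1) next
    mu0 <- sum(p[1:(t + 1)] * (0:t)) / w0
    mu1 <- sum(p[(t + 2):256] * ((t + 1):255)) / (1 - w0)
    v <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# O(N^2) brute-force mean nearest-boundary distance oracle: for each pixel
# on the outer boundary of `obj_mask`, the minimum Euclidean distance to any
# pixel on the pith boundary.
thickness_bruteforce <- function(obj_mask, pith_mask) {
  bp <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    up    <- rbind(FALSE, mask[-nr, , drop = FALSE])
    down  <- rbind(mask[-1, , drop = FALSE], FALSE)
    left  <- cbind(FALSE, mask[, -nc, drop = FALSE])
    right <- cbind(mask[, -1, drop = FALSE], FALSE)
    which(mask & !(up & down & left & right), arr.ind = TRUE)
  }
  ob <- bp(obj_mask); pb <- bp(pith_mask)
  d <- numeric(nrow(ob))
  for (i in seq_len(nrow(ob))) {
    d[i] <- sqrt(min((pb[, 1] - ob[i, 1])^2 + (pb[, 2] - ob[i, 2])^2))
  }
  mean(d)
}

# Closed-form Ramanujan ellipse perimeter.
ramanujan_perimeter <- function(a, b) {
  h <- (a - b)^2 / (a + b)^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

with_seed_local <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# The default-realism spec of the validation study: everything at package
# defaults except the per-image seed and bundle count.
realism_spec <- function(seed, n_bundles) {
  stalkscan::synthetic_spec(seed = seed, n_bundles = n_bundles)
}
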