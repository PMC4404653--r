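test_that("patch extraction covers the documented window and pads edges", {
  gray <- matrix(seq_len(300 * 300), 300, 300)
  p <- extract_patch(gray, c(101, 101), 40)       # 0-based center (100, 100)
  expect_identical(unclass(p)[seq_len(40), seq_len(40)], gray[81:120, 81:120])
  expect_false(attr(p, "edge_clipped"))
  pe <- extract_patch(gray, c(6, 6), 40)
  expect_true(attr(pe, "edge_clipped"))
  expect_equal(dim(pe), c(40L, 40L))
  expect_error(extract_patch(gray, c(10, 10), 7), "parameter error")
  expect_error(extract_patch(gray, c(0, 10), 40), "outside")
  expect_error(extract_patch(gray, c(10, 301), 40), "outside")
})

test_that("homomorphic filter keeps constants and identity gains trivial", {
  const <- matrix(100, 40, 40)
  out <- homomorphic_filter(const)
  expect_equal(max(out) - min(out), 0)
  p <- matrix(runif(1600, 10, 200), 40)
  ident <- homomorphic_filter(p, gain_low = 1, gain_high = 1)
  # identity transfer: output equals input up to the monotone rescale
  expect_equal(cor(as.vector(ident), as.vector(p)), 1, tolerance = 1e-9)
  expect_error(homomorphic_filter(p - 100), "negative")
})

test_that("homomorphic filter suppresses an illumination ramp relative to the bump", {
  n <- 40
  ramp <- outer(rep(1, n), seq_len(n)) * 2
  p_in <- 60 + ramp + mk_blob(n, n, 20.5, 20.5, 80, 4, 4, 0)
  p_out <- homomorphic_filter(p_in)
  ratio <- function(p) {
    d <- data.frame(y = as.vector(p), r = as.vector(row(p)),
                    c = as.vector(col(p)))
    f <- stats::lm(y ~ r + c, data = d)
    sqrt(sum(stats::coef(f)[2:3]^2)) * n / max(stats::residuals(f))
  }
  # plane-slope span relative to bump contrast drops by at least 10%
  # (measured 16% at the default gains) and the bump stays the brightest spot
  expect_lt(ratio(p_out), 0.9 * ratio(p_in))
  ai <- arrayInd(which.max(p_in), dim(p_in))
  ao <- arrayInd(which.max(p_out), dim(p_out))
  expect_lte(max(abs(ai - ao)), 1)
})

test_that("noiseless Gaussian parameters are recovered within 1%", {
  f <- fit_gaussian2d(mk_blob(40, 40, 20.5, 20.5, 100, 5, 3, 0.4,
                              baseline = 10))
  expect_true(f$converged)
  expect_equal(f$sigma_major, 5, tolerance = 0.01)
  expect_equal(f$sigma_minor, 3, tolerance = 0.01)
  expect_equal(f$theta, 0.4, tolerance = 0.01)
  expect_equal(f$amplitude, 100, tolerance = 0.01)
  expect_equal(f$baseline, 10, tolerance = 0.01)
  expect_gte(f$sigma_major, f$sigma_minor)
})

test_that("isotropic sigma-4 blob yields the 2-sigma contour area", {
  f <- fit_gaussian2d(mk_blob(40, 40, 20.5, 20.5, 100, 4, 4, 0,
                              baseline = 5))
  expect_equal(f$area_px2, pi * 8 * 8, tolerance = 0.005)
})

test_that("a pure-noise patch does not converge", {
  set.seed(99)
  f <- fit_gaussian2d(matrix(runif(1600, 0, 255), 40))
  expect_false(f$converged)
  expect_true(is.na(f$area_px2))
  expect_error(fit_gaussian2d(matrix(1, 40, 40)), "degenerate")
})

test_that("fitting is rotation invariant", {
  p <- mk_blob(40, 40, 20.5, 20.5, 90, 6, 3.5, 0.7, baseline = 12)
  p90 <- t(p)[, rev(seq_len(40))]                 # 90-degree rotation
  a1 <- fit_gaussian2d(p)$area_px2
  a2 <- fit_gaussian2d(p90)$area_px2
  expect_equal(a1, a2, tolerance = 0.005)
})

test_that("sigma recovery holds across random blobs, clean and noisy", {
  set.seed(17)
  err_clean <- replicate(40, {
    smaj <- runif(1, 3, 7); smin <- smaj * runif(1, 0.5, 1)
    th <- runif(1, -pi / 2, pi / 2)
    f <- fit_gaussian2d(mk_blob(40, 40, 20.5, 20.5, 100, smaj, smin, th,
                                baseline = 15))
    max(abs(f$sigma_major - smaj) / smaj, abs(f$sigma_minor - smin) / smin)
  })
  expect_lt(max(err_clean), 0.01)
  err_noisy <- replicate(40, {
    smaj <- runif(1, 3, 7); smin <- smaj * runif(1, 0.5, 1)
    th <- runif(1, -pi / 2, pi / 2)
    p <- mk_blob(40, 40, 20.5, 20.5, 100, smaj, smin, th, baseline = 15) +
      rnorm(1600, 0, 5)
    f <- fit_gaussian2d(p)
    true_area <- pi * (2 * smaj) * (2 * smin)
    if (!f$converged) NA else abs(f$area_px2 - true_area) / true_area
  })
  expect_lt(median(err_noisy, na.rm = TRUE), 0.10)
})

test_that("bundle size summary averages converged fits only", {
  cal <- calibration_from_dpi(800)
  gray <- matrix(20, 400, 400)
  centers <- as.matrix(expand.grid(row = seq(60, 340, by = 70),
                                   col = seq(60, 340, by = 70)))
  for (i in seq_len(nrow(centers))) {
    gray <- gray + mk_blob(400, 400, centers[i, 1], centers[i, 2], 100,
                           4, 4, 0)
  }
  res <- bundle_sizes(gray, centers, cal, homomorphic = FALSE)
  expect_true(all(res$fits$converged))
  expect_equal(res$mean_bundle_area_cm2, pi * 64 / cal$px_per_cm^2,
               tolerance = 0.005)
  # a center on flat background is excluded from the mean
  centers2 <- rbind(centers, c(200, 25))
  res2 <- bundle_sizes(gray, centers2, cal, homomorphic = FALSE)
  expect_equal(sum(!res2$fits$converged), 1L)
  expect_equal(res2$mean_bundle_area_cm2, res$mean_bundle_area_cm2,
               tolerance = 1e-6)
  # no centers -> no summary
  res0 <- bundle_sizes(gray, NULL, cal)
  expect_true(is.na(res0$mean_bundle_area_cm2))
  expect_equal(nrow(res0$fits), 0L)
})

test_that("bundle area in cm^2 scales as the inverse square of calibration", {
  gray <- mk_blob(80, 80, 40, 40, 100, 5, 4, 0.2, baseline = 10)
  res <- lapply(c(200, 800), function(dpi) {
    bundle_sizes(gray, cbind(40, 40), calibration_from_dpi(dpi),
                 homomorphic = FALSE)$fits
  })
  expect_identical(res[[1]]$area_px2, res[[2]]$area_px2)
  expect_equal(res[[1]]$area_cm2 / res[[2]]$area_cm2, (800 / 200)^2,
               tolerance = 1e-9)
  k <- calibration_from_dpi(800)$px_per_cm
  expect_equal(res[[2]]$area_cm2, res[[2]]$area_px2 / k^2, tolerance = 1e-12)
})
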