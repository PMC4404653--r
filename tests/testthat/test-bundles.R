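test_that("bundle smoothing is a normalized convolution", {
  imp <- matrix(0, 41, 41); imp[21, 21] <- 100
  sm <- bundle_smooth(imp, bundle_width_px = 8)
  expect_equal(sum(sm), 100)                      # mass preserved
  expect_equal(which.max(sm), which.max(imp))     # kernel centered
  expect_equal(sm, t(sm))                         # isotropic
  const <- matrix(7.5, 30, 30)
  expect_equal(bundle_smooth(const, 8), const)
})

test_that("two impulses 4 sigma apart stay separate peaks", {
  img <- matrix(0, 60, 60)
  img[30, 20] <- 100; img[30, 40] <- 100          # 20 px apart
  sm <- bundle_smooth(img, bundle_width_px = 10)  # sigma 5, gap 4 sigma
  pk <- detect_peaks(sm, matrix(TRUE, 60, 60), suppression_radius_px = 5)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk[, "col"], c(20, 40))
})

test_that("anisotropic diffusion conserves intensity and fixes constants", {
  const <- matrix(42, 50, 50)
  expect_equal(anisotropic_diffusion(const), const)
  set.seed(21)
  img <- matrix(runif(8000, 0, 255), 80, 100)
  for (cond in c("exponential", "rational")) {
    out <- anisotropic_diffusion(img, diffusion_params(conduction = cond))
    expect_equal(sum(out), sum(img), tolerance = 1e-6)
    expect_equal(dim(out), dim(img))
  }
  expect_error(diffusion_params(dt = 0.3), "stability")
  expect_error(diffusion_params(kappa = -1))
})

test_that("diffusion flattens flat-region noise but preserves strong edges", {
  set.seed(8)
  img <- cbind(matrix(0, 80, 40), matrix(200, 80, 40)) +
    matrix(rnorm(6400, 0, 10), 80)
  out <- anisotropic_diffusion(img, diffusion_params(kappa = 30, n_iter = 50,
                                                     dt = 0.2))
  edge_before <- mean(abs(img[, 41] - img[, 40]))
  edge_after <- mean(abs(out[, 41] - out[, 40]))
  expect_gt(edge_after, 0.95 * edge_before)
  flat_before <- stats::var(as.numeric(img[, 5:35]))
  flat_after <- stats::var(as.numeric(out[, 5:35]))
  expect_lt(flat_after, 0.5 * flat_before)
})

test_that("a single blob yields exactly its center as a peak", {
  img <- mk_blob(100, 120, 50, 60, A = 80, smaj = 5, smin = 5, theta = 0,
                 baseline = 20)
  pith <- mk_disc(100, 120, 50, 60, 45)
  pk <- detect_peaks(img, pith, suppression_radius_px = 8)
  expect_equal(unname(pk), cbind(50, 60), ignore_attr = TRUE)
})

test_that("peaks outside the pith mask are not counted", {
  img <- mk_blob(100, 100, 50, 15, A = 80, smaj = 5, smin = 5, theta = 0,
                 baseline = 20)                   # blob in the rind band
  pith <- mk_disc(100, 100, 50, 50, 20)
  pk <- detect_peaks(img, pith, suppression_radius_px = 8)
  expect_equal(nrow(pk), 0L)
})

test_that("all well-separated synthetic bundles are found within 2 px", {
  scene <- generate(synthetic_spec(
    n_bundles = 100L, illumination_gradient = 0, noise_sigma = 0,
    texture_amplitude = 0, seed = 42L))
  truth <- scene$truth[[1]]
  gray <- to_grayscale(scene$image)
  win <- gray[truth$box[1]:truth$box[3], truth$box[2]:truth$box[4]]
  sm <- anisotropic_diffusion(bundle_smooth(win, 9.45))
  pk <- detect_peaks(sm, truth$pith_mask, suppression_radius_px = 9.45)
  expect_equal(nrow(pk), 100L)
  tc <- truth$centers
  tc[, 1] <- tc[, 1] - truth$box[1] + 1
  tc[, 2] <- tc[, 2] - truth$box[2] + 1
  m <- match_centers(pk, tc, radius = 2)
  expect_equal(m$n_matched, 100L)
})

test_that("peak detection is shift-invariant and deterministic", {
  set.seed(31)
  img <- matrix(0, 90, 90)
  for (i in 1:6) {
    img <- img + mk_blob(90, 90, 15 + 12 * i, 80 - 11 * i, A = 60,
                         smaj = 4, smin = 4, theta = 0)
  }
  img <- img + matrix(rnorm(8100, 0, 0.5), 90)
  pith <- matrix(TRUE, 90, 90)
  pk1 <- detect_peaks(img, pith, 8)
  pk2 <- detect_peaks(img + 25.3, pith, 8)
  expect_identical(pk1, pk2)
  expect_identical(pk1, detect_peaks(img, pith, 8))
})

test_that("bundle counting divides by pith area and deduplicates", {
  cal <- calibration_from_dpi(127)                # 50 px/cm exactly
  k2 <- cal$px_per_cm^2
  pith <- mk_disc(200, 200, 100, 100, sqrt(4 * k2 / pi))  # 4 cm^2 of pith
  seg <- structure(list(pith_mask = pith, pith_area_px = sum(pith)),
                   class = "pith_segmentation")
  auto <- cbind(row = seq(60, 140, length.out = 120),
                col = rep(100, 120))
  bs <- count_bundles(auto, NULL, seg, cal, suppression_radius_px = 8)
  expect_equal(bs$density_per_cm2, 120 / (sum(pith) / k2))
  expect_equal(bs$density_per_cm2, 30, tolerance = 0.01)
  # manual point 3 px from an auto center is a duplicate
  bs2 <- count_bundles(cbind(100, 100), cbind(103, 100), seg, cal, 8)
  expect_equal(bs2$n_auto + bs2$n_manual, 1L)
  # manual-only counting works
  man <- cbind(c(90, 100, 110, 95, 105), rep(100, 5))
  bs3 <- count_bundles(NULL, man, seg, cal, 4)
  expect_equal(bs3$n_manual, 5L)
  # manual centers outside the pith are dropped with a warning
  expect_warning(
    bs4 <- count_bundles(NULL, cbind(c(100, 3), c(100, 3)), seg, cal, 8),
    "outside")
  expect_equal(bs4$n_manual, 1L)
})

test_that("bundles placed in the rind band cause undercounting, not overcounting", {
  # negative margin lets true bundles spill past the pith boundary
  scene <- generate(synthetic_spec(n_bundles = 120L, bundle_margin_px = -25,
                                   seed = 13L))
  s <- score_detection(scene)
  expect_lte(s$n_detected, s$n_true)
  expect_gt(s$recall, 0.5)
})
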