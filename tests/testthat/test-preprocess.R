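test_that("grayscale conversion uses Rec. 601 luminance weights", {
  white <- mk_image(matrix(255, 2, 2))
  expect_equal(to_grayscale(white), matrix(255, 2, 2))
  green <- scan_image(array(rep(c(0, 255, 0), each = 4), c(2, 2, 3)), 800)
  expect_equal(to_grayscale(green), matrix(0.587 * 255, 2, 2))
  black <- mk_image(matrix(0, 3, 5))
  expect_equal(to_grayscale(black), matrix(0, 3, 5))
})

test_that("Otsu separates a perfectly bimodal image", {
  gray <- matrix(c(rep(10, 200), rep(200, 200)), 20, 20)
  t <- otsu_threshold(gray)
  expect_gte(t, 10)
  expect_lt(t, 200)
  expect_error(otsu_threshold(matrix(42, 10, 10)), "degenerate")
})

test_that("Otsu equals the exhaustive between-class-variance scan", {
  set.seed(7)
  for (i in 1:12) {
    gray <- switch(1 + i %% 3,
      matrix(sample(0:255, 900, replace = TRUE), 30, 30),
      matrix(round(pmin(pmax(c(rnorm(450, 60, 25), rnorm(450, 180, 20)),
                             0), 255)), 30, 30),
      matrix(round(255 * rbeta(900, 0.4, 0.7)), 30, 30))
    expect_equal(otsu_threshold(gray), otsu_bruteforce(gray))
  }
})

test_that("foreground segmentation fills interior holes", {
  gray <- matrix(5, 120, 120)
  gray[mk_disc(120, 120, 60, 60, 40)] <- 200
  solid <- segment_foreground(gray)
  expect_equal(sum(solid), sum(mk_disc(120, 120, 60, 60, 40)))
  # darker specks inside the disc are filled
  gray2 <- gray
  gray2[58:62, 58:62] <- 10
  expect_equal(segment_foreground(gray2), solid)
})

test_that("segmentation finds every disc and scratch as its own component", {
  set.seed(11)
  gray <- matrix(4, 400, 400)
  centers <- expand.grid(r = c(80, 280), c = c(80, 280))
  for (i in 1:4) gray[mk_disc(400, 400, centers$r[i], centers$c[i], 45)] <- 180
  for (i in 1:10) {
    r0 <- sample(10:390, 1); c0 <- sample(155:190, 1)
    gray[r0:(r0 + 3), c0:(c0 + sample(4:9, 1))] <- 150
  }
  mask <- segment_foreground(gray)
  n_oracle <- max(EBImage::bwlabel(EBImage::Image(mask * 1)))
  expect_equal(n_oracle, 14)
})

test_that("size filter enforces the 15000-px boundary exactly", {
  mask <- matrix(FALSE, 400, 600)
  mask[11:160, 11:110] <- TRUE              # 150 x 100 = 15000 px, kept
  mask[201:350, 201:300] <- TRUE            # 15000 px
  mask[350, 300] <- FALSE                   # ... minus 1 = 14999 px, removed
  out <- filter_objects(mask)
  expect_equal(sum(out), 15000L)
  expect_true(all(which(out) %in% which(mask)))
  expect_true(out[11, 11])
  expect_false(out[201, 201])
})

test_that("eccentricity filter removes line-like debris, keeps discs", {
  mask <- matrix(FALSE, 600, 2200)
  disc <- mk_disc(600, 2200, 300, 300, 100)   # area ~31416, ecc ~0
  mask[disc] <- TRUE
  mask[295:304, 701:2200] <- TRUE             # 10 x 1500 bar, 15000 px
  out <- filter_objects(mask)
  expect_equal(sum(out), sum(disc))
  # the bar exceeds the eccentricity bound: rectangle moments give
  # ecc = sqrt(1 - (h^2-1)/(w^2-1)) ~ 0.99998
  ecc_bar <- sqrt(1 - (10^2 - 1) / (1500^2 - 1))
  expect_gt(ecc_bar, 0.99)
})

test_that("object filter is idempotent", {
  set.seed(3)
  mask <- matrix(runif(250000) > 0.65, 500, 500)
  mask[mk_disc(500, 500, 250, 250, 90)] <- TRUE
  once <- filter_objects(mask, min_area = 5000, max_eccentricity = 0.95)
  twice <- filter_objects(once, min_area = 5000, max_eccentricity = 0.95)
  expect_identical(once, twice)
})

test_that("eccentricity of digitized shapes matches their geometry", {
  disc <- mk_disc(201, 201, 101, 101, 80)
  lab <- matrix(as.integer(disc), 201)
  expect_lt(stalkscan:::region_props(lab)$ecc, 0.1)
  line <- matrix(FALSE, 50, 200)
  line[25, 10:190] <- TRUE
  expect_gt(stalkscan:::region_props(matrix(as.integer(line), 50))$ecc, 0.99)
})

test_that("objects come out in row-major centroid order with tight boxes", {
  gray <- matrix(5, 700, 520)
  k <- 0
  for (r in c(100, 280, 460, 640)) for (c in c(90, 260, 430)) {
    k <- k + 1
    gray[mk_disc(700, 520, r, c, 75)] <- 150 + k  # distinct intensities
  }
  img <- mk_image(gray)
  mask <- filter_objects(segment_foreground(gray))
  objs <- extract_objects(img, mask)
  expect_length(objs, 12L)
  cents <- t(vapply(objs, function(o) o$centroid, numeric(2)))
  expect_equal(cents[, 1], rep(c(100, 280, 460, 640), each = 3),
               tolerance = 0.01)
  expect_equal(cents[, 2], rep(c(90, 260, 430), 4), tolerance = 0.01)
  o1 <- objs[[1]]
  expect_equal(unname(o1$box), c(100 - 75, 90 - 75, 100 + 75, 90 + 75))
  expect_equal(o1$area_px, sum(mk_disc(700, 520, 100, 90, 75)))
})

test_that("an override crop box drops mask pixels outside it", {
  gray <- matrix(5, 300, 300)
  disc <- mk_disc(300, 300, 150, 150, 70)
  gray[disc] <- 200
  img <- mk_image(gray)
  mask <- filter_objects(segment_foreground(gray), min_area = 1000)
  full <- extract_objects(img, mask)[[1]]
  halved <- extract_objects(img, mask,
                            overrides = list(c(1, 1, 300, 150)))[[1]]
  expect_equal(halved$area_px / full$area_px, 0.5, tolerance = 0.02)
  expect_equal(unname(halved$box)[4], 150)
  expect_error(
    extract_objects(img, mask, overrides = list(c(1, 1, 40, 40))),
    "configuration error")
})

test_that("circle and square morphometry match closed forms", {
  cal <- calibration_from_dpi(315 * 2.54)   # exactly 315 px/cm
  disc <- mk_disc(701, 701, 351, 351, 315)
  img <- mk_image(matrix(0, 701, 701))
  obj <- structure(list(mask = disc, box = c(1, 1, 701, 701),
                        area_px = sum(disc),
                        mean_diameter_px = stalkscan:::mean_diameter_px(disc),
                        perimeter_px = stalkscan:::contour_perimeter(disc),
                        eccentricity = 0, index = 0L),
                   class = "transection")
  m <- measure_morphology(obj, cal)
  expect_equal(m$mean_diameter_cm, 2.0, tolerance = 0.02)
  expect_equal(m$area_cm2, pi, tolerance = 0.02)
  # pixel-area identity is exact
  expect_equal(m$area_cm2 * cal$px_per_cm^2, sum(disc))
  sq <- matrix(FALSE, 400, 400)
  sq[43:357, 43:357] <- TRUE                 # 315 x 315
  obj$mask <- sq; obj$area_px <- sum(sq)
  expect_equal(measure_morphology(obj, cal)$area_cm2, 1.0)
})

test_that("ellipse perimeter is within 3% of Ramanujan's approximation", {
  ell <- mk_ellipse(500, 900, 250, 450, 200, 400)
  p <- stalkscan:::contour_perimeter(ell)
  expect_equal(p, ramanujan_perimeter(400, 200), tolerance = 0.03)
})
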