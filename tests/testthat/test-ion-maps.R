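test_that("category maps sum the right channels and conserve counts", {
  set.seed(6)
  counts <- array(rpois(6 * 6 * 4, 5), c(6, 6, 4))
  cube <- sims_cube(counts, c(10, 20, 30, 40), 5)
  pk <- data.frame(mz = c(10, 20, 30, 40),
                   category = c("GDAP", "GDAP", "Gold", "Unassigned"))
  gold <- category_image(cube, pk, "Gold")
  expect_equal(gold$image, counts[, , 3])  # single-channel identity
  gdap <- category_image(cube, pk, "GDAP")
  una <- category_image(cube, pk, "Unassigned")
  expect_equal(gdap$image + gold$image + una$image, total_ion_image(cube))
  expect_error(category_image(cube, pk, "OEG/SAM"), "no peaks")
})

test_that("contaminant maps need an explicit QC flag", {
  cube <- sims_cube(array(1, c(2, 2, 1)), 29.04, 1)
  pk <- data.frame(mz = 29.04, category = "Hydrocarbon")
  expect_error(category_image(cube, pk, "Hydrocarbon"), "contaminant")
  qc <- category_image(cube, pk, "Hydrocarbon", allow_contaminants = TRUE)
  expect_equal(qc$image, matrix(1, 2, 2))
})

test_that("the glycan map lights up the spot", {
  gt <- tiny_truth()
  cube <- simulate_sims_cube(gt, seed = 0)
  pk <- data.frame(mz = gt$signatures$mz, category = gt$signatures$category)
  gmap <- category_image(cube, pk, "GDAP")
  inside <- gt$density_map > 0
  expect_gt(mean(gmap$image[inside]) / mean(gmap$image[!inside]), 10)
})

test_that("min-max normalization", {
  m <- matrix(c(0, 10, 5, 5), 2, 2)
  expect_equal(normalize_image(m), matrix(c(0, 1, 0.5, 0.5), 2, 2))
  expect_equal(normalize_image(normalize_image(m)), normalize_image(m))
  set.seed(1)
  r <- normalize_image(matrix(runif(100, 2, 9), 10, 10))
  expect_equal(range(r), c(0, 1))
  expect_error(normalize_image(matrix(3, 2, 2)), "degenerate contrast")
})

test_that("binarization: bimodal images, idempotence, Otsu oracle", {
  m <- matrix(c(0, 0, 1, 1, 0, 1), 2, 3)
  b <- binarize(m)
  expect_equal(unname(b[, ]), m == 1, ignore_attr = TRUE)
  # idempotence: re-thresholding a mask reproduces it
  expect_equal(unname(binarize(b + 0)[, ]), unname(b[, ]),
               ignore_attr = TRUE)
  # Otsu on a 50/50 Gaussian mixture lands between the modes, and agrees
  # with an exhaustive 256-level between-class-variance search
  set.seed(10)
  img <- matrix(pmin(pmax(c(rnorm(500, 0.2, 0.05), rnorm(500, 0.8, 0.05)),
                          0), 1), 25, 40)
  th <- attr(binarize(img), "threshold")
  expect_gt(th, 0.4); expect_lt(th, 0.6)
  oracle <- otsu_exhaustive(img)
  expect_gt(oracle$threshold, 0.4); expect_lt(oracle$threshold, 0.6)
  # the implementation's threshold attains the oracle's maximal
  # between-class variance (tie-breaks on the plateau may differ)
  expect_gte(th + 1e-9, oracle$plateau[1])
  expect_lte(th - 1e-9, oracle$plateau[2])
  expect_equal(oracle$objective(th), oracle$objective(oracle$threshold),
               tolerance = 1e-6)
  expect_error(binarize(img, method = "fixed"), "level")
  expect_error(binarize(img * 2), "normalized")
})

test_that("RGB composites stack category maps on the declared channels", {
  mask <- matrix(0, 4, 4); mask[2:3, 2:3] <- 1
  comp <- composite_rgb(mask, matrix(0, 4, 4), matrix(0, 4, 4))
  expect_equal(comp$rgb[2, 2, ], c(1, 0, 0))   # pure red inside
  expect_equal(comp$rgb[1, 1, ], c(0, 0, 0))
  black <- composite_rgb(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(all(black$rgb == 0))
  expect_equal(black$channel_categories, c("GDAP", "OEG/SAM", "Gold"))
  expect_error(composite_rgb(mask, matrix(0, 3, 3), matrix(0, 4, 4)),
               "shape mismatch")
  # composite of a synthetic spot centers on the planted spot
  gt <- tiny_truth()
  cube <- simulate_sims_cube(gt, seed = 0)
  pk <- data.frame(mz = gt$signatures$mz, category = gt$signatures$category)
  masks <- lapply(c("GDAP", "OEG/SAM", "Gold"), function(cc)
    binarize(normalize_image(category_image(cube, pk, cc))))
  comp2 <- composite_rgb(masks[[1]] + 0, masks[[2]] + 0, masks[[3]] + 0)
  ij <- which(comp2$rgb[, , 1] > 0, arr.ind = TRUE)
  centroid <- c(mean((ij[, 2] - 0.5) * gt$pixel_um),
                mean((ij[, 1] - 0.5) * gt$pixel_um))
  expect_lt(max(abs(centroid - gt$spot_center_um)), 2 * gt$pixel_um)
})

test_that("spot morphology metrics against planted truth", {
  gt <- make_ground_truth(spot_diameter_um = 200)
  sm <- spot_metrics(truth_mask(gt), 3.9, gt)
  expect_equal(sm$dice, 1)
  expect_lt(abs(sm$equivalent_diameter_um - 200), 3.9)
  expect_lt(max(abs(sm$centroid_um - c(250, 250))), 3.9)
  expect_lt(sm$eccentricity, 0.2)
  # disjoint masks
  a <- matrix(FALSE, 4, 4); a[1, 1] <- TRUE
  b <- matrix(FALSE, 4, 4); b[4, 4] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)
  # empty mask: undefined size metrics, Dice 0
  e <- spot_metrics(matrix(FALSE, 4, 4), 1, truth = a)
  expect_true(is.na(e$area_um2))
  expect_equal(e$dice, 0)
})

test_that("component labeling is 8-connected", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal chain
  sm <- spot_metrics(m, 1)
  expect_equal(sm$n_components, 1L)
  expect_equal(sm$area_um2, 3)
})

test_that("coffee-stain ring shows up as a rim maximum in the radial profile", {
  gt <- make_ground_truth(ring_fraction = 0.25)
  cube <- simulate_sims_cube(gt, seed = 0)
  pk <- data.frame(mz = gt$signatures$mz, category = gt$signatures$category)
  gmap <- normalize_image(category_image(cube, pk, "GDAP"))
  rp <- radial_profile(gmap$image, gt$spot_center_um, gt$pixel_um, bin_um = 5)
  r_peak <- rp$r_um[which.max(rp$mean)]
  w <- gt$ring_width_frac * gt$spot_diameter_um
  expect_gte(r_peak, 100 - w - 5)
  expect_lte(r_peak, 100 + 5)
})

test_that("maps and composites write to TIFF and PNG", {
  gt <- tiny_truth()
  cube <- simulate_sims_cube(gt, seed = 0)
  pk <- data.frame(mz = gt$signatures$mz, category = gt$signatures$category)
  gmap <- normalize_image(category_image(cube, pk, "GDAP"))
  tf <- tempfile(fileext = ".tiff")
  write_ion_map_tiff(gmap, tf)
  expect_true(file.exists(tf))
  back <- tiff::readTIFF(tf)
  expect_equal(back, gmap$image, tolerance = 1e-4)
  pf <- tempfile(fileext = ".png")
  write_composite_png(composite_rgb(gmap$image, gmap$image, gmap$image), pf)
  expect_true(file.exists(pf))
})
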