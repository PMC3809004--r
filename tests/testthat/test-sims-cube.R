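make_cube <- function(counts, mz = seq_len(dim(counts)[3]) * 10,
                      pixel_um = 10) {
  sims_cube(counts, mz, pixel_um)
}

test_that("cube constructor enforces its invariants", {
  expect_error(sims_cube(array(1, c(2, 2, 2)), c(2, 1), 1),
               "strictly increasing")
  expect_error(sims_cube(array(-1, c(2, 2, 1)), 1, 1), "non-negative")
  expect_error(sims_cube(array(1, c(2, 2, 2)), c(1, 2), 0), "pixel_um")
  expect_error(sims_cube(matrix(1, 2, 2), 1, 1), "3-D")
})

test_that("total ion image sums channels per pixel", {
  cube <- make_cube(array(1, c(4, 4, 3)))
  expect_equal(total_ion_image(cube), matrix(3, 4, 4))
  one <- make_cube(array(rpois(16, 5), c(4, 4, 1)))
  expect_equal(total_ion_image(one), one$counts[, , 1])
  gt <- tiny_truth()
  cube <- simulate_sims_cube(gt, seed = 0)
  tic <- total_ion_image(cube)
  expect_gt(mean(tic[gt$density_map > 0]), mean(tic[gt$density_map == 0]))
})

test_that("ROI spectra are pixel-center means over half-open rectangles", {
  cube <- make_cube(array(1, c(8, 8, 2)))
  pk <- data.frame(mz = c(10, 20))
  full <- extract_roi_spectrum(cube, roi_spec(0, 0, 80, 80), pk)
  expect_equal(unname(full), c(1, 1))
  # oracle: brute-force mean over pixel centers for an asymmetric cube
  set.seed(4)
  cube2 <- make_cube(array(rpois(8 * 8 * 2, 6), c(8, 8, 2)))
  roi <- roi_spec(13, 27, 30, 42)
  got <- extract_roi_spectrum(cube2, roi, pk)
  acc <- c(0, 0); n <- 0
  for (i in 1:8) for (j in 1:8) {
    x <- (j - 0.5) * 10; y <- (i - 0.5) * 10
    if (x >= 13 && x < 43 && y >= 27 && y < 69) {
      acc <- acc + cube2$counts[i, j, ]; n <- n + 1
    }
  }
  expect_equal(unname(got), acc / n)
  expect_error(extract_roi_spectrum(cube2, roi_spec(70, 0, 30, 10), pk),
               "outside field")
})

test_that("a 100 um ROI on the 3.9 um grid averages 625 pixel centers", {
  # pixel-count probe: a cube with a single nonzero pixel has ROI mean
  # 1/n_pixels for any ROI containing it
  counts <- array(0, c(128, 128, 1))
  counts[64, 64, 1] <- 1
  cube <- sims_cube(counts, 1, 3.9)
  roi <- roi_spec(10.8 * 3.9, 10.8 * 3.9, 100, 100)  # placed mid-pixel
  # brute-force center count
  n_oracle <- 0L
  for (k in 1:128) {
    c_k <- (k - 0.5) * 3.9
    if (c_k >= 10.8 * 3.9 && c_k < 10.8 * 3.9 + 100) n_oracle <- n_oracle + 1L
  }
  expect_equal(n_oracle, 25L)
  probe <- roi_spec(10.8 * 3.9, 10.8 * 3.9, 100, 100)
  counts2 <- array(0, c(128, 128, 1))
  counts2[20, 20, 1] <- 625  # center (76.05, 76.05) um lies inside the ROI
  cube2 <- sims_cube(counts2, 1, 3.9)
  expect_equal(unname(extract_roi_spectrum(cube2, probe, data.frame(mz = 1))),
               1)
})

test_that("three ROIs on five images give a 15-row spectrum matrix", {
  gt <- tiny_truth(field_um = 500, pixel_um = 10, spot_diameter_um = 200)
  cubes <- lapply(0:4, function(s) simulate_sims_cube(gt, seed = s))
  pk <- data.frame(mz = gt$signatures$mz)
  m <- build_spectrum_matrix(cubes, standard_rois(500), pk)
  expect_equal(dim(m), c(15L, nrow(pk)))
  expect_equal(attr(m, "roi"), rep(c("I", "II", "III"), 5))
  # full-field ROI equals the channel-wise cube mean
  whole <- extract_roi_spectrum(cubes[[1]], roi_spec(0, 0, 500, 500), pk)
  expect_equal(unname(whole), unname(apply(cubes[[1]]$counts, 3, mean)))
})

test_that("peak picking thresholds the summed spectrum inclusively", {
  counts <- array(0, c(2, 2, 3))
  counts[, , 1] <- 7.5  # summed 30
  counts[, , 2] <- 7.475 # summed 29.9
  counts[, , 3] <- 25
  cube <- sims_cube(counts, c(50, 60, 70), 1)
  pk <- pick_peaks(cube, background = c(10, 10, 10), k = 3)
  expect_equal(pk$mz, c(50, 70))      # >= boundary keeps exactly 3x
  expect_false(60 %in% pk$mz)         # 29.9 < 30 is excluded
  expect_error(pick_peaks(cube, c(-1, 0, 0)), "non-negative")
  expect_error(pick_peaks(cube, c(1, 1)), "one value per channel")
})

test_that("peak picking recovers exactly the planted species", {
  gt <- tiny_truth()
  sig <- gt$signatures
  planted <- seq_len(20)                      # 20 high-yield species
  sig$yield[-planted] <- 0                    # the rest are floor-only
  cube <- simulate_sims_cube(gt, signatures = sig, noise_scale = 1, seed = 7)
  npx <- prod(dim(cube$counts)[1:2])
  bg <- sig$background * npx
  pk <- pick_peaks(cube, bg, k = 3)
  expect_setequal(pk$mz, sig$mz[planted])
  expect_true(all(pk$category == "Unassigned"))
  # monotone in k: raising the multiplier never adds channels
  for (k2 in c(5, 20, 100)) {
    expect_true(all(pick_peaks(cube, bg, k2)$mz %in% pk$mz))
  }
  # assignment transfers reference categories
  asg <- assign_categories(pk, gdap_peak_table())
  expect_true(all(asg$category != "Unassigned"))
})

test_that("background helper takes the ROI median on the summed scale", {
  counts <- array(0, c(4, 4, 2))
  counts[, , 1] <- matrix(c(rep(2, 8), rep(6, 8)), 4, 4)
  counts[, , 2] <- 1
  cube <- sims_cube(counts, c(10, 20), 10)
  bg <- background_from_roi(cube, roi_spec(0, 0, 40, 40))
  expect_equal(bg, c(median(counts[, , 1]), 1) * 16)
})

test_that("normalization divides by total selected intensity then centers", {
  m <- rbind(c(2, 2, 4), c(1, 1, 2))
  out <- normalize_spectra(m)
  expect_equal(out$normalized[1, ], c(0.25, 0.25, 0.5))
  # identical compositions center to zero
  expect_true(all(abs(out$centered) < 1e-15))
  set.seed(8)
  m2 <- matrix(rexp(15 * 33) + 0.01, 15, 33)
  out2 <- normalize_spectra(m2)
  expect_true(all(abs(rowSums(out2$normalized) - 1) < 1e-12))
  expect_true(all(abs(colMeans(out2$centered)) < 1e-12))
  m3 <- rbind(c(1, 2), c(0, 0))
  expect_error(normalize_spectra(m3), "empty spectrum in ROI")
})

test_that("peak and ROI tables round-trip through CSV", {
  pk <- gdap_peak_table()
  expect_equal(nrow(pk), 33L)
  expect_setequal(unique(pk$category),
                  c("GDAP", "OEG/SAM", "Gold", "Hydrocarbon", "Salt"))
  path <- tempfile(fileext = ".csv")
  write_peak_table(pk, path)
  expect_equal(read_peak_table(path), pk)
  rois <- standard_rois()
  path2 <- tempfile(fileext = ".csv")
  write_roi_table(rois, path2)
  back <- read_roi_table(path2)
  expect_equal(back$II$x_um, rois$II$x_um)
  expect_equal(names(back), c("I", "II", "III"))
})
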