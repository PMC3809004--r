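uniform_stack <- function(v, nT = 60, n = 10, pixel_um = 10) {
  spri_stack(array(v, c(n, n, nT)), seq_len(nT), pixel_um)
}

test_that("sensorgrams of uniform stacks are constant with zero sd", {
  st <- uniform_stack(7)
  sg <- roi_sensorgram(st, roi_spec(20, 20, 50, 50), frame_average = 30)
  expect_equal(sg$response, c(7, 7))
  expect_equal(sg$response_sd, c(0, 0))
  expect_equal(sg$t_seconds, c(15.5, 45.5))
  # frame_average = n_frames degenerates to a single point
  sg1 <- roi_sensorgram(st, roi_spec(20, 20, 50, 50), frame_average = 60)
  expect_length(sg1$response, 1)
  expect_error(roi_sensorgram(st, roi_spec(20, 20, 50, 50), 61),
               "frame_average")
  expect_error(roi_sensorgram(st, roi_spec(20, 20, 2, 2), 30),
               "no pixel centers")
})

test_that("frame averaging reduces replicate noise as sigma/sqrt(30 m)", {
  m <- 25; sig <- 1
  reps <- vapply(1:100, function(i) {
    set.seed(i)
    st <- spri_stack(array(rnorm(10 * 10 * 30, sd = sig), c(10, 10, 30)),
                     1:30, 10)
    roi_sensorgram(st, roi_spec(20, 20, 50, 50), 30)$response
  }, numeric(1))
  theory <- sig / sqrt(30 * m)
  expect_lt(abs(sd(reps) - theory) / theory, 0.2)
})

test_that("concentric ROIs nest and respect the field", {
  rois <- concentric_rois(c(250, 250), c(50, 87, 125, 162, 200),
                          field_um = 500)
  expect_length(rois, 5)
  for (i in 1:4) {
    a <- rois[[i]]; b <- rois[[i + 1]]
    expect_gt(a$x_um, b$x_um)
    expect_lt(a$x_um + a$width_um, b$x_um + b$width_um)
    # pixel membership is nested (exhaustive check on a 3.9 um grid)
    ca <- glycosims:::.roi_cells(a, 3.9, c(128, 128))
    cb <- glycosims:::.roi_cells(b, 3.9, c(128, 128))
    expect_true(all(ca$rows %in% cb$rows) && all(ca$cols %in% cb$cols))
  }
  one <- concentric_rois(c(100, 100), 40)
  expect_equal(one[[1]]$x_um, 80)
  expect_error(concentric_rois(c(250, 250), c(50, 600), field_um = 500),
               "exceeds field")
  expect_error(concentric_rois(c(0, 0), c(50, 50)), "strictly increasing")
})

test_that("response_at uses nearby samples or interpolates", {
  st <- uniform_stack(1, nT = 3)
  sg <- structure(list(t_seconds = c(600, 660, 720),
                       response = c(10, 20, 40),
                       response_sd = c(0, 0, 0)), class = "sensorgram")
  expect_equal(response_at(sg, 11), 20)           # exact sample at 660 s
  sg2 <- structure(list(t_seconds = c(0, 500, 1000),
                        response = c(0, 10, 30),
                        response_sd = c(0, 0, 0)), class = "sensorgram")
  expect_equal(response_at(sg2, 11), 10 + 20 * 160 / 500)  # interpolated
  expect_error(response_at(sg, 30), "outside")
})

test_that("noiseless sensorgram hits the Langmuir closed form at 11 min", {
  gt <- make_ground_truth(spot_density = 1, center_dip = 0,
                          ring_fraction = 0)
  st <- simulate_spri_stack(gt, times = seq(20, 1200, 20), noise_sd = 0)
  sg <- roi_sensorgram(st, roi_spec(230, 230, 40, 40), frame_average = 1)
  expect_equal(response_at(sg, 11),
               langmuir_response(660, gt$kinetics), tolerance = 1e-9)
})

test_that("ROI sweep: dilution past the spot boundary, rising variability", {
  gt <- make_ground_truth(spot_diameter_um = 150)
  st <- simulate_spri_stack(gt, times = seq(30, 720, 30), noise_sd = 0.5)
  sw <- roi_sweep(st, c(250, 250), c(50, 87, 125, 162, 200),
                  t_minutes = 11, frame_average = 1)
  expect_true(all(diff(sw$sd) >= 0))
  contained <- sw$size_um <= 150 / sqrt(2)   # squares inside the disk
  larger <- sw$size_um > 150
  expect_true(all(sw$mean[larger] < max(sw$mean[contained])))
  expect_true(all(sw$norm_mean <= 1))
  expect_equal(max(sw$norm_mean), 1)
  expect_equal(sw$area_um2, sw$size_um^2)
  # uniform stack: every ROI sees the same mean
  su <- uniform_stack(3, nT = 30, n = 50, pixel_um = 10)
  swu <- roi_sweep(su, c(250, 250), c(100, 200, 300), t_minutes = 0.25,
                   frame_average = 30)
  expect_true(all(swu$norm_mean == 1))
})

test_that("disjoint-ROI sensorgrams combine by pixel-count weighting", {
  set.seed(21)
  st <- spri_stack(array(rnorm(20 * 20 * 10, 5), c(20, 20, 10)), 1:10, 10)
  a <- roi_spec(0, 0, 100, 200)     # left half, 10 x 20 px
  b <- roi_spec(100, 0, 100, 200)   # right half
  u <- roi_spec(0, 0, 200, 200)
  sga <- roi_sensorgram(st, a, 5)
  sgb <- roi_sensorgram(st, b, 5)
  sgu <- roi_sensorgram(st, u, 5)
  w <- sga$n_pixels / (sga$n_pixels + sgb$n_pixels)
  expect_equal(sgu$response, w * sga$response + (1 - w) * sgb$response,
               tolerance = 1e-12)
})

test_that("Langmuir fitting recovers planted kinetics", {
  kin <- kinetic_params()
  times <- seq(5, 1500, by = 5)
  sg <- structure(list(t_seconds = times,
                       response = langmuir_response(times, kin)),
                  class = "sensorgram")
  ft <- fit_langmuir(sg, kin$concentration, kin$t_assoc_end)$kinetics
  expect_equal(ft$k_on, kin$k_on, tolerance = 0.01)
  expect_equal(ft$k_off, kin$k_off, tolerance = 0.01)
  expect_equal(ft$R_max, kin$R_max, tolerance = 0.01)
  # mostly-dissociation trace still pins k_off via the log-linear start
  kin2 <- kinetic_params(t_assoc_end = 150)
  t2 <- c(seq(5, 150, 5), seq(160, 3000, 20))
  sg2 <- structure(list(t_seconds = t2,
                        response = langmuir_response(t2, kin2)),
                   class = "sensorgram")
  ft2 <- fit_langmuir(sg2, kin2$concentration, 150)$kinetics
  expect_equal(ft2$k_off, kin2$k_off, tolerance = 0.01)
  expect_error(fit_langmuir(sg, 0, 900), "concentration")
})

test_that("SPRi stacks round-trip through float TIFF plus times CSV", {
  gt <- tiny_truth()
  st <- simulate_spri_stack(gt, times = c(5, 15, 40), noise_sd = 0.3,
                            seed = 2)
  tf <- tempfile(fileext = ".tiff")
  write_spri_stack(st, tf)
  back <- read_spri_stack(tf)
  expect_equal(back$frames, st$frames, tolerance = 1e-6)
  expect_equal(back$t_seconds, st$t_seconds)
  expect_equal(back$pixel_um, st$pixel_um)
  # times CSV has the declared columns
  csv <- read.csv(sub("\\.tiff$", ".csv", tf))
  expect_equal(names(csv), c("frame_index", "t_seconds"))
})
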