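#' SPRi reflectance image stack
#'
#' A time-ordered sequence of reflectance images (pixel-intensity units)
#' on the same coordinate frame as the SIMS cube: rows top to bottom (y),
#' columns left to right (x), half-open square pixels.
#'
#' @param frames rows x cols x n_frames numeric array.
#' @param t_seconds Strictly increasing frame times (s).
#' @param pixel_um Pixel edge (um).
#' @return An object of class `spri_stack`.
#' @export
spri_stack <- function(frames, t_seconds, pixel_um) {
  if (length(dim(frames)) != 3) stop("frames must be a 3-D array")
  if (dim(frames)[3] != length(t_seconds))
    stop("one time per frame required")
  if (is.unsorted(t_seconds, strictly = TRUE))
    stop("times must be strictly increasing")
  if (pixel_um <= 0) stop("pixel_um must be > 0")
  structure(list(frames = frames, t_seconds = as.numeric(t_seconds),
                 pixel_um = pixel_um), class = "spri_stack")
}

#' @export
print.spri_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("spri_stack: %d x %d pixels (%g um/pixel), %d frames (%.0f-%.0f s)\n",
              d[1], d[2], x$pixel_um, d[3],
              min(x$t_seconds), max(x$t_seconds)))
  invisible(x)
}

#' Write / read an SPRi stack as multi-page TIFF plus times CSV
#'
#' Frames are stored as 32-bit float TIFF pages. Because baseline TIFF
#' readers expect sample values in `[0, 1]`, frames are affinely mapped
#' into that range on write; the mapping and the pixel size are recorded
#' in a JSON sidecar (`<tiff>.json`) and undone on read. Times go to a
#' CSV with columns `frame_index,t_seconds`.
#'
#' @param stack An [spri_stack()].
#' @param tiff_path Output TIFF path.
#' @param times_path Output CSV path (default: TIFF path with `.csv`).
#' @return `read_spri_stack()` returns the restored [spri_stack()].
#' @export
write_spri_stack <- function(stack, tiff_path,
                             times_path = sub("\\.tiff?$", ".csv",
                                              tiff_path, ignore.case = TRUE)) {
  stopifnot(inherits(stack, "spri_stack"))
  lo <- min(stack$frames); hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  nT <- dim(stack$frames)[3]
  pages <- lapply(seq_len(nT), function(k)
    (stack$frames[, , k] - lo) / scale)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L,
                  compression = "none")
  write.csv(data.frame(frame_index = seq_len(nT) - 1L,
                       t_seconds = stack$t_seconds),
            times_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(pixel_um = stack$pixel_um, offset = lo,
                            scale = scale),
                       paste0(tiff_path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(tiff_path)
}

#' @rdname write_spri_stack
#' @export
read_spri_stack <- function(tiff_path,
                            times_path = sub("\\.tiff?$", ".csv",
                                             tiff_path, ignore.case = TRUE)) {
  meta <- jsonlite::read_json(paste0(tiff_path, ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  times <- read.csv(times_path)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages))
    frames[, , k] <- pages[[k]] * meta$scale + meta$offset
  spri_stack(frames, times$t_seconds, meta$pixel_um)
}

#' Extract a sensorgram from an SPRi stack over one ROI
#'
#' Consecutive frames are grouped into blocks of `frame_average` and
#' averaged before ROI statistics are taken, mirroring the instrument
#' convention of averaging ~30 raw images per displayed frame. The
#' response is the spatial mean over ROI pixels of each averaged frame;
#' `response_sd` is the spatial standard deviation within the ROI, a
#' measure of spot inhomogeneity. Leftover frames that do not fill a
#' block are dropped.
#'
#' @param stack An [spri_stack()].
#' @param roi An [roi_spec()] within the field.
#' @param frame_average Frames per averaging block (>= 1, <= n_frames).
#' @return An object of class `sensorgram`: list with `t_seconds` (block
#'   mean times), `response`, `response_sd`, `roi` and `n_pixels`.
#' @export
roi_sensorgram <- function(stack, roi, frame_average = 30L) {
  stopifnot(inherits(stack, "spri_stack"))
  nT <- dim(stack$frames)[3]
  if (frame_average < 1 || frame_average > nT)
    stop("frame_average must be in [1, n_frames]")
  cells <- .roi_cells(roi, stack$pixel_um, dim(stack$frames)[1:2])
  nblock <- nT %/% frame_average
  t_out <- resp <- rsd <- numeric(nblock)
  for (b in seq_len(nblock)) {
    fr <- ((b - 1) * frame_average + 1):(b * frame_average)
    avg <- apply(stack$frames[, , fr, drop = FALSE], c(1, 2), mean)
    px <- avg[cells$rows, cells$cols]
    t_out[b] <- mean(stack$t_seconds[fr])
    resp[b] <- mean(px)
    rsd[b] <- stats::sd(px)
  }
  structure(list(t_seconds = t_out, response = resp, response_sd = rsd,
                 roi = roi,
                 n_pixels = length(cells$rows) * length(cells$cols)),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("sensorgram: %d time points (%.0f-%.0f s), ROI %g x %g um (%d px)\n",
              length(x$t_seconds), min(x$t_seconds), max(x$t_seconds),
              x$roi$width_um, x$roi$height_um, x$n_pixels))
  invisible(x)
}

#' @export
as.data.frame.sensorgram <- function(x, ...) {
  data.frame(t_seconds = x$t_seconds, response = x$response,
             response_sd = x$response_sd)
}

#' Concentric square ROIs around a common center
#'
#' The conventional sweep design: nested square ROIs (e.g. 50 x 50 um up
#' to 200 x 200 um) sharing a center placed over a printed spot.
#'
#' @param center_um Common center `c(x, y)` (um).
#' @param sizes_um Strictly increasing square edge lengths (um).
#' @param field_um Optional field edge; if given, an error is raised when
#'   the largest ROI exceeds the field (ROIs are never clipped).
#' @return List of [roi_spec()]s named by size.
#' @export
concentric_rois <- function(center_um, sizes_um, field_um = NULL) {
  if (is.unsorted(sizes_um, strictly = TRUE))
    stop("sizes must be strictly increasing")
  if (!is.null(field_um)) {
    s <- max(sizes_um)
    if (center_um[1] - s / 2 < 0 || center_um[1] + s / 2 > field_um ||
        center_um[2] - s / 2 < 0 || center_um[2] + s / 2 > field_um)
      stop("largest ROI exceeds field")
  }
  out <- lapply(sizes_um, function(s)
    roi_spec(center_um[1] - s / 2, center_um[2] - s / 2, s, s,
             name = sprintf("%g", s)))
  names(out) <- sprintf("%g", sizes_um)
  out
}

#' Sensorgram response at a given time
#'
#' Returns the response at the nearest sampled time if it lies within
#' 60 s of the requested time, otherwise linearly interpolates between
#' the neighbouring samples. The conventional readout is 11 min, near
#' maximal binding.
#'
#' @param sg A [roi_sensorgram()] result.
#' @param t_minutes Readout time (minutes).
#' @return Response value (pixel-intensity units).
#' @export
response_at <- function(sg, t_minutes = 11) {
  stopifnot(inherits(sg, "sensorgram"))
  t <- 60 * t_minutes
  i <- which.min(abs(sg$t_seconds - t))
  if (abs(sg$t_seconds[i] - t) <= 60) return(sg$response[i])
  if (t < min(sg$t_seconds) || t > max(sg$t_seconds))
    stop("time outside sensorgram range")
  stats::approx(sg$t_seconds, sg$response, xout = t)$y
}

.sd_at <- function(sg, t_minutes) {
  t <- 60 * t_minutes
  i <- which.min(abs(sg$t_seconds - t))
  if (abs(sg$t_seconds[i] - t) <= 60) return(sg$response_sd[i])
  stats::approx(sg$t_seconds, sg$response_sd, xout = t)$y
}

#' Concentric ROI sweep of SPR response and variability
#'
#' Quantifies how ROI choice shapes the reported response: for each
#' concentric ROI, the response at `t_minutes` and the within-ROI spatial
#' standard deviation. ROIs that extend beyond the printed spot dilute
#' the response with non-glycan background and inflate the spatial
#' standard deviation.
#'
#' @param stack An [spri_stack()].
#' @param center_um Sweep center (um).
#' @param sizes_um Strictly increasing ROI edges (um); the default
#'   interpolates five sizes across the conventional 50-200 um range.
#' @param t_minutes Readout time (min).
#' @param frame_average Frames per averaging block.
#' @param normalize Add `norm_mean`, the mean response divided by the
#'   maximum across the sweep.
#' @return `data.frame` with `size_um`, `area_um2`, `mean`, `sd` and
#'   optionally `norm_mean`.
#' @export
roi_sweep <- function(stack, center_um,
                      sizes_um = round(seq(50, 200, length.out = 5)),
                      t_minutes = 11, frame_average = 30L,
                      normalize = TRUE) {
  stopifnot(inherits(stack, "spri_stack"))
  field <- dim(stack$frames)[2] * stack$pixel_um
  rois <- concentric_rois(center_um, sizes_um, field_um = field)
  mu <- s <- numeric(length(rois))
  for (i in seq_along(rois)) {
    sg <- roi_sensorgram(stack, rois[[i]], frame_average)
    mu[i] <- response_at(sg, t_minutes)
    s[i] <- .sd_at(sg, t_minutes)
  }
  out <- data.frame(size_um = sizes_um, area_um2 = sizes_um^2,
                    mean = mu, sd = s)
  if (normalize) out$norm_mean <- mu / max(mu)
  out
}

# Piecewise Langmuir model and its Jacobian in log-parameter space
# (theta = log(k_on, k_off, R_max)), used by fit_langmuir.
.langmuir_model <- function(theta, t, C, te) {
  kon <- exp(theta[1]); koff <- exp(theta[2]); Rmax <- exp(theta[3])
  S <- C * kon + koff
  A <- Rmax * C * kon / S
  ta <- pmin(t, te)
  e <- exp(-S * ta)
  r_assoc <- A * (1 - e)
  dA_dkon <- Rmax * C * koff / S^2
  dA_dkoff <- -Rmax * C * kon / S^2
  dr_dkon <- dA_dkon * (1 - e) + A * ta * C * e
  dr_dkoff <- dA_dkoff * (1 - e) + A * ta * e
  dr_dRmax <- r_assoc / Rmax
  r <- r_assoc
  late <- t > te
  if (any(late)) {
    dt <- t[late] - te
    decay <- exp(-koff * dt)
    r[late] <- r_assoc[late] * decay
    dr_dkon[late] <- dr_dkon[late] * decay
    dr_dkoff[late] <- dr_dkoff[late] * decay - r_assoc[late] * dt * decay
    dr_dRmax[late] <- r[late] / Rmax
  }
  list(r = r,
       jac = cbind(dr_dkon * kon, dr_dkoff * koff, dr_dRmax * Rmax))
}

#' Fit 1:1 Langmuir binding kinetics to a sensorgram
#'
#' Nonlinear least squares of the piecewise 1:1 Langmuir model (see
#' [langmuir_response()]) for `k_on`, `k_off` and `R_max`, given the
#' analyte concentration and the end of the association phase. The fit
#' runs in log-parameter space with analytic gradients
#' (Levenberg-Marquardt via \pkg{minpack.lm}) from five deterministic
#' starts whose `k_on` seeds span two decades either side of a
#' data-derived initial estimate; `k_off` is seeded from the log-linear
#' slope of the dissociation tail when one is present.
#'
#' @param sg A [roi_sensorgram()] result (or any object with `t_seconds`
#'   and `response`).
#' @param concentration Analyte concentration (M), > 0.
#' @param t_assoc_end End of association (s).
#' @return List with `kinetics` (a [kinetic_params()]), `residual_norm`
#'   (root-mean-square residual) and `n_starts_converged`.
#' @export
fit_langmuir <- function(sg, concentration, t_assoc_end) {
  if (concentration <= 0) stop("concentration must be > 0")
  t <- sg$t_seconds; y <- sg$response
  if (length(t) < 4) stop("too few time points to fit")
  te <- t_assoc_end

  # data-derived seeds
  i_end <- which(t <= te)
  R_end <- if (length(i_end)) y[max(i_end)] else max(y)
  diss <- which(t > te & y > 0)
  koff0 <- if (length(diss) >= 3) {
    sl <- coef(lm(log(y[diss]) ~ t[diss]))[2]
    max(-sl, 1e-6)
  } else 1e-3
  i63 <- which(y >= (1 - exp(-1)) * R_end & t <= te)
  kobs0 <- if (length(i63)) 1 / max(t[i63][1], 1e-6) else 1 / (te / 3)
  kon0 <- max((kobs0 - koff0) / concentration, 1e-2 / concentration / te)
  Rmax0 <- max(R_end, 1e-6) * (concentration + koff0 / kon0) / concentration

  best <- NULL
  n_conv <- 0L
  diag_msgs <- character(0)
  for (f in 10^seq(-2, 2, length.out = 5)) {
    theta0 <- log(c(kon0 * f, koff0, Rmax0))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = theta0,
        fn = function(th) .langmuir_model(th, t, concentration, te)$r - y,
        jac = function(th) .langmuir_model(th, t, concentration, te)$jac,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diag_msgs <- c(diag_msgs, conditionMessage(fit))
      next
    }
    n_conv <- n_conv + 1L
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("Langmuir fit failed to converge from any start: ",
         paste(unique(diag_msgs), collapse = "; "))
  p <- exp(best$par)
  list(kinetics = kinetic_params(k_on = p[1], k_off = p[2], R_max = p[3],
                                 concentration = concentration,
                                 t_assoc_end = te),
       residual_norm = sqrt(best$deviance / length(y)),
       n_starts_converged = n_conv)
}
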