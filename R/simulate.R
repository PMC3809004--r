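# Each simulator draws from its own RNG stream keyed by (seed, kind), so
# running either alone reproduces the same data as running both.
.with_stream <- function(seed, kind, expr) {
  offset <- match(kind, c("sims", "spri"))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed((as.integer(seed) %% 1073741824L) * 2L + offset - 1L)
  expr
}

#' Simulate a ToF-SIMS hyperspectral cube from a ground truth
#'
#' Draws per-pixel, per-channel secondary-ion counts independently from
#' Poisson laws whose means encode the surface chemistry of a printed
#' glycan spot: glycan (GDAP) channel means scale with the local glycan
#' density, OEG/SAM and gold channel means scale with `1 - density` (the
#' immobilized glycan masks the underlying monolayer and substrate from
#' the shallow SIMS sampling depth), and hydrocarbon/salt contaminant
#' channels are density-independent. Every channel additionally receives a
#' stray-count floor of `noise_scale * background`.
#'
#' The SIMS-side density map includes the wash tail when the ground truth
#' has one, reflecting that the tail is deposited material visible to SIMS.
#'
#' @param gt A [make_ground_truth()] object.
#' @param signatures Channel signature table (defaults to `gt$signatures`).
#' @param noise_scale Non-negative multiplier on the per-channel stray
#'   background; 0 gives channels whose only counts come from category
#'   sources.
#' @param seed Integer seed (defaults to `gt$seed`). Equal seeds give
#'   bit-identical cubes.
#' @return A [sims_cube()].
#' @export
simulate_sims_cube <- function(gt, signatures = gt$signatures,
                               noise_scale = 1, seed = gt$seed) {
  stopifnot(inherits(gt, "ground_truth"))
  if (noise_scale < 0) stop("negative noise_scale")
  .validate_signatures(signatures)
  dens <- gt$density_map
  n <- gt$n_pixels
  nch <- nrow(signatures)
  counts <- array(0L, dim = c(n, n, nch))
  .with_stream(seed, "sims", {
    for (j in seq_len(nch)) {
      cat_j <- signatures$category[j]
      lam <- noise_scale * signatures$background[j] + signatures$yield[j] *
        switch(cat_j,
               GDAP = dens,
               `OEG/SAM` = 1 - dens,
               Gold = 1 - dens,
               Hydrocarbon = matrix(1, n, n),
               Salt = matrix(1, n, n),
               stop("unknown category label: ", cat_j))
      counts[, , j] <- rpois(n * n, lam)
    }
  })
  sims_cube(counts, channel_mz = signatures$mz, pixel_um = gt$pixel_um)
}

#' Closed-form 1:1 Langmuir binding response
#'
#' Response of a 1:1 Langmuir interaction at unit saturation density:
#' during association, `R(t) = R_max * C/(C + K_D) * (1 - exp(-(C*k_on +
#' k_off)*t))` with `K_D = k_off/k_on`; after `t_assoc_end` the response
#' decays exponentially at rate `k_off` from its value at the end of
#' association.
#'
#' @param t Time points (s).
#' @param kin A [kinetic_params()] object.
#' @return Numeric vector of responses (pixel-intensity units).
#' @export
langmuir_response <- function(t, kin) {
  stopifnot(inherits(kin, "kinetic_params"))
  C <- kin$concentration
  if (C == 0) return(numeric(length(t)))
  KD <- kin$k_off / kin$k_on
  kobs <- C * kin$k_on + kin$k_off
  Req <- kin$R_max * C / (C + KD)
  te <- kin$t_assoc_end
  r <- Req * (1 - exp(-kobs * pmin(t, te)))
  late <- t > te
  r[late] <- r[late] * exp(-kin$k_off * (t[late] - te))
  r
}

#' Simulate an SPRi reflectance stack from a ground truth
#'
#' Generates a time-ordered image sequence on the same pixel grid as the
#' SIMS cube. The per-pixel response is the closed-form 1:1 Langmuir curve
#' ([langmuir_response()]) scaled by the local bioavailable glycan density,
#' with additive Gaussian read noise per frame. By default the wash tail is
#' excluded from the binding density (`gt$density_map_binding`): the tail
#' is a deposition artifact seen by SIMS that does not present bioavailable
#' glycan in the replicate-surface SPRi experiment.
#'
#' @param gt A [make_ground_truth()] object.
#' @param times Strictly increasing frame times (s).
#' @param noise_sd Gaussian read-noise standard deviation per pixel and
#'   frame (pixel-intensity units).
#' @param seed Integer seed (defaults to `gt$seed`).
#' @param include_tail Use the tail-bearing density map instead.
#' @return An [spri_stack()].
#' @export
simulate_spri_stack <- function(gt, times = seq(5, 1500, by = 5),
                                noise_sd = 0.5, seed = gt$seed,
                                include_tail = FALSE) {
  stopifnot(inherits(gt, "ground_truth"))
  if (length(times) == 0) stop("empty times")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  dens <- if (include_tail) gt$density_map else gt$density_map_binding
  n <- gt$n_pixels
  resp <- langmuir_response(times, gt$kinetics)
  frames <- array(0, dim = c(n, n, length(times)))
  .with_stream(seed, "spri", {
    for (k in seq_along(times)) {
      fr <- dens * resp[k]
      if (noise_sd > 0) fr <- fr + rnorm(n * n, sd = noise_sd)
      frames[, , k] <- fr
    }
  })
  spri_stack(frames, t_seconds = times, pixel_um = gt$pixel_um)
}
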