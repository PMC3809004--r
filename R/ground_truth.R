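#' Reference fragment assignments for glycan/OEG-SAM/gold surfaces
#'
#' The published positive-ion peak list for diaminopyridine-conjugated
#' glycan (GDAP) spots printed on NHS-activated oligo(ethylene glycol)
#' self-assembled monolayers on gold: 33 fragments assigned to five source
#' categories (GDAP, OEG/SAM, Gold, Hydrocarbon, Salt). Hydrocarbon and
#' salt fragments are adventitious contaminants from printing and handling.
#'
#' @return A peak-table `data.frame` with columns `mz` (reported 2-decimal
#'   centroid, Da), `formula` and `category`.
#' @seealso [fragment_mz()] to recompute theoretical cation masses,
#'   [assign_categories()] to transfer these assignments to picked peaks.
#' @export
gdap_peak_table <- function() {
  path <- system.file("extdata", "gdap_oeg_gold_peaks.csv",
                      package = "glycosims", mustWork = TRUE)
  read_peak_table(path)
}

#' Default category yield signatures for the SIMS simulator
#'
#' One row per spectral channel of the synthetic cube: the channel m/z is
#' the theoretical cation mass of the assigned fragment, `yield` is the
#' mean secondary-ion count per pixel contributed by the category source at
#' unit glycan density (GDAP), at unit monolayer exposure (OEG/SAM, Gold),
#' or unconditionally (Hydrocarbon, Salt), and `background` is a small
#' stray-count floor common to all channels. Yields are fixed, deliberately
#' heterogeneous values spanning the dynamic range typical of low-mass
#' secondary ions, so that no two categories are distinguishable by total
#' intensity alone.
#'
#' @return A `data.frame` with columns `mz`, `formula`, `category`,
#'   `yield`, `background`, ordered by increasing m/z.
#' @export
default_signatures <- function() {
  pk <- gdap_peak_table()
  pk$mz <- fragment_mz(pk$formula)
  yields <- numeric(nrow(pk))
  for (cat in unique(pk$category)) {
    i <- which(pk$category == cat)
    yields[i] <- switch(cat,
      GDAP         = seq(25, 60, length.out = length(i)),
      `OEG/SAM`    = seq(20, 50, length.out = length(i)),
      Gold         = seq(15, 40, length.out = length(i)),
      Hydrocarbon  = rep(10, length(i)),
      Salt         = rep(8, length(i)),
      stop("unknown category: ", cat))
  }
  out <- data.frame(mz = pk$mz, formula = pk$formula,
                    category = pk$category, yield = yields,
                    background = 0.2, stringsAsFactors = FALSE)
  out[order(out$mz), , drop = FALSE]
}

#' Langmuir kinetic parameters
#'
#' Parameters of the 1:1 Langmuir binding model used by the SPRi simulator
#' and recovered by [fit_langmuir()]. Defaults describe a lectin-glycan
#' interaction of moderate affinity (K_D = 10 nM) probed at 100 nM analyte,
#' with a 15-minute association phase so that the conventional 11-minute
#' readout falls near maximal binding.
#'
#' @param k_on Association rate constant (1/M/s).
#' @param k_off Dissociation rate constant (1/s).
#' @param R_max Saturation response at unit glycan density
#'   (pixel-intensity units).
#' @param concentration Analyte concentration (M).
#' @param t_assoc_end Time at which association ends and dissociation
#'   begins (s).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_on = 1e5, k_off = 1e-3, R_max = 100,
                           concentration = 1e-7, t_assoc_end = 900) {
  if (k_on <= 0 || k_off <= 0 || R_max <= 0)
    stop("rates and R_max must be strictly positive")
  if (concentration < 0) stop("concentration must be >= 0")
  if (t_assoc_end <= 0) stop("t_assoc_end must be > 0")
  structure(list(k_on = k_on, k_off = k_off, R_max = R_max,
                 concentration = concentration, t_assoc_end = t_assoc_end),
            class = "kinetic_params")
}

#' Ground truth for co-registered synthetic SIMS and SPRi data
#'
#' Constructs the shared ground truth from which [simulate_sims_cube()] and
#' [simulate_spri_stack()] generate data: a square imaging field, a printed
#' glycan spot with the morphology typical of contact-printed microarrays,
#' per-channel category yield signatures, and Langmuir kinetic parameters.
#' Construction is fully deterministic; the `seed` field only keys the
#' random streams of the two simulators.
#'
#' The relative glycan surface density is modeled as a disk of level
#' `spot_density` with three printing artifacts:
#' \describe{
#'   \item{center dip}{evaporation-driven microheterogeneity: a parabolic
#'     depletion of relative depth `center_dip` at the spot center, rising
#'     to the full `spot_density` at the rim;}
#'   \item{coffee-stain ring}{a multiplicative boost `1 + ring_fraction`
#'     on an annulus of width `ring_width_frac * diameter` at the rim,
#'     clipped at density 1;}
#'   \item{wash tail}{an exponentially decaying half-strip of half-width
#'     half the spot radius extending beyond the rim along
#'     `tail_vector_um`, whose magnitude sets the decay length (um).
#'     `c(0, 0)` disables the tail. The tail is a rinse artifact of the
#'     deposited material; it carries glycan ions in SIMS but, by default,
#'     no protein binding in SPRi (see [simulate_spri_stack()]).}
#' }
#'
#' Pixels are half-open squares `[i*pixel_um, (i+1)*pixel_um)` indexed
#' 0-based, row-major from the top-left; the grid is
#' `floor(field_um / pixel_um)` pixels per axis, so the conventional
#' 500 um field at 3.9 um/pixel gives 128 x 128 = 16384 spectra. A pixel
#' belongs to a region iff its center does.
#'
#' @param field_um Square field edge (um).
#' @param pixel_um Pixel edge (um).
#' @param spot_center_um Spot center `c(x, y)` in um from the top-left.
#' @param spot_diameter_um Printed spot diameter (um); spots of 150-250 um
#'   are typical of contact printing. `0` gives an empty field.
#' @param spot_density Relative glycan density of the spot body, in (0, 1].
#' @param center_dip Relative central depletion in `[0, 1)`.
#' @param ring_fraction Coffee-stain density boost (>= 0; 0 disables).
#' @param ring_width_frac Ring annulus width as a fraction of the diameter.
#' @param tail_vector_um Wash-tail direction and decay length `c(dx, dy)`.
#' @param signatures Category yield table, see [default_signatures()].
#' @param kinetics A [kinetic_params()] object.
#' @param seed Integer seed keying the simulator random streams.
#' @return An object of class `ground_truth` with fields including
#'   `density_map` (per-pixel relative glycan density including the tail,
#'   the SIMS-side truth) and `density_map_binding` (tail excluded, the
#'   SPRi-side truth).
#' @examples
#' gt <- make_ground_truth()
#' dim(gt$density_map)  # 128 x 128
#' @export
make_ground_truth <- function(field_um = 500, pixel_um = 3.9,
                              spot_center_um = c(250, 250),
                              spot_diameter_um = 200,
                              spot_density = 0.8,
                              center_dip = 0.15,
                              ring_fraction = 0.25,
                              ring_width_frac = 0.1,
                              tail_vector_um = c(0, 0),
                              signatures = default_signatures(),
                              kinetics = kinetic_params(),
                              seed = 0L) {
  if (field_um <= 0 || pixel_um <= 0) stop("non-positive dimensions")
  if (pixel_um > field_um) stop("pixel_um must not exceed field_um")
  if (spot_diameter_um < 0) stop("non-positive dimensions")
  if (spot_density <= 0 || spot_density > 1)
    stop("spot_density must be in (0, 1]")
  if (center_dip < 0 || center_dip >= 1)
    stop("center_dip must be in [0, 1)")
  if (ring_fraction < 0) stop("ring_fraction must be >= 0")
  r <- spot_diameter_um / 2
  if (spot_diameter_um > 0 &&
      (spot_center_um[1] - r < 0 || spot_center_um[1] + r > field_um ||
       spot_center_um[2] - r < 0 || spot_center_um[2] + r > field_um))
    stop("spot outside field")
  stopifnot(inherits(kinetics, "kinetic_params"))
  .validate_signatures(signatures)

  n <- floor(field_um / pixel_um)
  centers <- (seq_len(n) - 0.5) * pixel_um
  X <- matrix(centers, n, n, byrow = TRUE)  # x varies along columns
  Y <- matrix(centers, n, n)                # y varies along rows
  dx <- X - spot_center_um[1]
  dy <- Y - spot_center_um[2]
  rad <- sqrt(dx^2 + dy^2)

  dens <- matrix(0, n, n)
  if (spot_diameter_um > 0) {
    inside <- rad < r
    dip <- 1 - center_dip * (1 - (rad / r)^2)
    dens[inside] <- spot_density * dip[inside]
    if (ring_fraction > 0 && ring_width_frac > 0) {
      w <- ring_width_frac * spot_diameter_um
      ring <- inside & rad >= (r - w)
      dens[ring] <- pmin(1, dens[ring] * (1 + ring_fraction))
    }
  }
  dens_binding <- dens

  tail_len <- sqrt(sum(tail_vector_um^2))
  if (spot_diameter_um > 0 && tail_len > 0) {
    u <- tail_vector_um / tail_len
    along <- dx * u[1] + dy * u[2]
    perp <- -dx * u[2] + dy * u[1]
    in_tail <- along >= r & along <= r + 4 * tail_len & abs(perp) <= r / 2 &
      dens == 0
    dens[in_tail] <- spot_density * exp(-(along[in_tail] - r) / tail_len)
  }

  structure(list(
    field_um = field_um, pixel_um = pixel_um, n_pixels = n,
    spot_center_um = spot_center_um, spot_diameter_um = spot_diameter_um,
    spot_density = spot_density, center_dip = center_dip,
    ring_fraction = ring_fraction, ring_width_frac = ring_width_frac,
    tail_vector_um = tail_vector_um,
    density_map = dens, density_map_binding = dens_binding,
    signatures = signatures, kinetics = kinetics, seed = as.integer(seed)
  ), class = "ground_truth")
}

.validate_signatures <- function(sig) {
  need <- c("mz", "category", "yield", "background")
  if (!is.data.frame(sig) || !all(need %in% names(sig)))
    stop("signatures must be a data.frame with columns ",
         paste(need, collapse = ", "))
  ok <- c("GDAP", "OEG/SAM", "Gold", "Hydrocarbon", "Salt")
  bad <- setdiff(unique(sig$category), ok)
  if (length(bad)) stop("unknown category label: ", paste(bad, collapse = ", "))
  if (is.unsorted(sig$mz, strictly = TRUE))
    stop("signature m/z values must be strictly increasing")
  invisible(sig)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %g x %g um field, %g um/pixel (%d x %d)\n",
              x$field_um, x$field_um, x$pixel_um, x$n_pixels, x$n_pixels))
  cat(sprintf("  spot: %g um diameter at (%g, %g), density %g (dip %g, ring +%g%%)\n",
              x$spot_diameter_um, x$spot_center_um[1], x$spot_center_um[2],
              x$spot_density, x$center_dip, 100 * x$ring_fraction))
  if (any(x$tail_vector_um != 0))
    cat(sprintf("  wash tail along (%g, %g) um\n",
                x$tail_vector_um[1], x$tail_vector_um[2]))
  cat(sprintf("  %d spectral channels, seed %d\n",
              nrow(x$signatures), x$seed))
  invisible(x)
}

#' Ground-truth support mask
#'
#' Binary mask of pixels with nonzero planted glycan density, the oracle
#' against which recovered spot masks are scored (e.g. by Dice overlap in
#' [spot_metrics()] or [spatial_agreement()]).
#'
#' @param gt A [make_ground_truth()] object.
#' @param include_tail Include the wash-tail support (the SIMS-side truth)
#'   or not (the SPRi-side truth).
#' @return Logical matrix.
#' @export
truth_mask <- function(gt, include_tail = TRUE) {
  stopifnot(inherits(gt, "ground_truth"))
  if (include_tail) gt$density_map > 0 else gt$density_map_binding > 0
}

#' Serialize / restore a ground truth as JSON
#'
#' Only the generating configuration is stored; the density maps are
#' recomputed on read, which keeps the file small and guarantees the
#' restored object is bit-identical to the original.
#'
#' @param gt A `ground_truth` object.
#' @param path File path.
#' @return `read_ground_truth()` returns the restored `ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  cfg <- list(
    field_um = gt$field_um, pixel_um = gt$pixel_um,
    spot_center_um = gt$spot_center_um,
    spot_diameter_um = gt$spot_diameter_um,
    spot_density = gt$spot_density, center_dip = gt$center_dip,
    ring_fraction = gt$ring_fraction, ring_width_frac = gt$ring_width_frac,
    tail_vector_um = gt$tail_vector_um,
    signatures = gt$signatures,
    kinetics = unclass(gt$kinetics),
    seed = gt$seed
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_ground_truth(
    field_um = cfg$field_um, pixel_um = cfg$pixel_um,
    spot_center_um = cfg$spot_center_um,
    spot_diameter_um = cfg$spot_diameter_um,
    spot_density = cfg$spot_density, center_dip = cfg$center_dip,
    ring_fraction = cfg$ring_fraction, ring_width_frac = cfg$ring_width_frac,
    tail_vector_um = cfg$tail_vector_um,
    signatures = as.data.frame(cfg$signatures),
    kinetics = do.call(kinetic_params, as.list(cfg$kinetics)),
    seed = cfg$seed
  )
}
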