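#' Hyperspectral SIMS image cube
#'
#' The central data object: a rows x cols x channels array of non-negative
#' secondary-ion counts on a uniform m/z axis, with the physical pixel
#' size. Rows run top to bottom (y), columns left to right (x); pixel
#' `[i, j]` covers the half-open square
#' `[(j-1)*pixel_um, j*pixel_um) x [(i-1)*pixel_um, i*pixel_um)` relative
#' to `origin`.
#'
#' @param counts 3-D array (rows x cols x channels) of non-negative counts.
#' @param channel_mz Strictly increasing m/z centers (Da), one per channel.
#' @param pixel_um Pixel edge length (um).
#' @param origin Field origin `c(x_um, y_um)`, top-left corner.
#' @return An object of class `sims_cube`.
#' @export
sims_cube <- function(counts, channel_mz, pixel_um, origin = c(0, 0)) {
  if (length(dim(counts)) != 3) stop("counts must be a 3-D array")
  if (dim(counts)[1] < 1 || dim(counts)[2] < 1) stop("empty cube")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(channel_mz) != dim(counts)[3])
    stop("channel_mz length must equal the number of channels")
  if (is.unsorted(channel_mz, strictly = TRUE))
    stop("channel_mz must be strictly increasing")
  if (pixel_um <= 0) stop("pixel_um must be > 0")
  structure(list(counts = counts, channel_mz = as.numeric(channel_mz),
                 pixel_um = pixel_um, origin = as.numeric(origin)),
            class = "sims_cube")
}

#' @export
print.sims_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("sims_cube: %d x %d pixels (%g um/pixel), %d channels (m/z %.2f-%.2f)\n",
              d[1], d[2], x$pixel_um, d[3],
              min(x$channel_mz), max(x$channel_mz)))
  cat(sprintf("  total counts: %.0f\n", sum(x$counts)))
  invisible(x)
}

#' Total ion image
#'
#' Per-pixel sum of counts over all spectral channels; the standard
#' overview image on which ROIs are placed.
#'
#' @param cube A [sims_cube()].
#' @return A rows x cols numeric matrix.
#' @export
total_ion_image <- function(cube) {
  stopifnot(inherits(cube, "sims_cube"))
  rowSums(cube$counts, dims = 2)
}

#' Rectangular region of interest
#'
#' @param x_um,y_um Top-left corner (um).
#' @param width_um,height_um Extent (um); must be strictly positive.
#' @param name Optional label.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x_um, y_um, width_um, height_um, name = "") {
  if (width_um <= 0 || height_um <= 0) stop("ROI extent must be positive")
  structure(list(x_um = x_um, y_um = y_um, width_um = width_um,
                 height_um = height_um, name = name), class = "roi_spec")
}

# Row/column indices of pixels whose centers fall in the half-open ROI
# rectangle. grid_dim = c(nrow, ncol).
.roi_cells <- function(roi, pixel_um, grid_dim, origin = c(0, 0),
                       require_inside = TRUE) {
  stopifnot(inherits(roi, "roi_spec"))
  field_w <- grid_dim[2] * pixel_um
  field_h <- grid_dim[1] * pixel_um
  if (require_inside &&
      (roi$x_um < origin[1] || roi$y_um < origin[2] ||
       roi$x_um + roi$width_um > origin[1] + field_w + 1e-9 ||
       roi$y_um + roi$height_um > origin[2] + field_h + 1e-9))
    stop("ROI outside field")
  cx <- origin[1] + (seq_len(grid_dim[2]) - 0.5) * pixel_um
  cy <- origin[2] + (seq_len(grid_dim[1]) - 0.5) * pixel_um
  cols <- which(cx >= roi$x_um & cx < roi$x_um + roi$width_um)
  rows <- which(cy >= roi$y_um & cy < roi$y_um + roi$height_um)
  if (length(rows) == 0 || length(cols) == 0)
    stop("ROI covers no pixel centers")
  list(rows = rows, cols = cols)
}

#' Standard three-ROI layout for ROI-based PCA
#'
#' The conventional layout for spot-versus-background PCA of a single
#' printed array element: square ROIs in the upper-left (I), center (II)
#' and lower-right (III) of the field, with the center ROI over the spot
#' and the corner ROIs on the surrounding monolayer.
#'
#' @param field_um Field edge (um).
#' @param roi_um ROI edge (um), conventionally 100.
#' @param margin_um Corner ROI inset from the field edge.
#' @return Named list of three [roi_spec()]s: `I`, `II`, `III`.
#' @export
standard_rois <- function(field_um = 500, roi_um = 100,
                          margin_um = field_um / 20) {
  ctr <- (field_um - roi_um) / 2
  lr <- field_um - margin_um - roi_um
  list(I   = roi_spec(margin_um, margin_um, roi_um, roi_um, "I"),
       II  = roi_spec(ctr, ctr, roi_um, roi_um, "II"),
       III = roi_spec(lr, lr, roi_um, roi_um, "III"))
}

#' Mean ROI spectrum
#'
#' Per-peak mean count over all pixels whose centers fall in the ROI.
#'
#' @param cube A [sims_cube()].
#' @param roi An [roi_spec()]; must lie within the field.
#' @param peaks Peak table (`data.frame` with column `mz`); each peak is
#'   matched to the nearest cube channel within `tol` Da.
#' @param tol Peak-to-channel matching tolerance (Da).
#' @return Named numeric vector, one mean count per peak.
#' @export
extract_roi_spectrum <- function(cube, roi, peaks, tol = 0.02) {
  stopifnot(inherits(cube, "sims_cube"))
  if (NROW(peaks) == 0) stop("peaks must be non-empty")
  cells <- .roi_cells(roi, cube$pixel_um, dim(cube$counts)[1:2], cube$origin)
  ch <- match_channels(peaks$mz, cube$channel_mz, tol)
  sub <- cube$counts[cells$rows, cells$cols, ch, drop = FALSE]
  out <- apply(sub, 3, mean)
  names(out) <- sprintf("%.2f", peaks$mz)
  out
}

#' Match peak m/z values to cube channels
#'
#' @param mz Peak m/z values to match.
#' @param channel_mz Cube channel axis.
#' @param tol Maximum |difference| (Da).
#' @return Integer channel indices.
#' @export
match_channels <- function(mz, channel_mz, tol = 0.02) {
  idx <- vapply(mz, function(m) {
    d <- abs(channel_mz - m)
    j <- which.min(d)
    if (d[j] > tol) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx))
    stop("no channel within ", tol, " Da of m/z ",
         paste(sprintf("%.2f", mz[is.na(idx)]), collapse = ", "))
  idx
}

#' Per-channel background from a blank region
#'
#' Estimates the per-channel background of the summed spectrum as the
#' median per-pixel intensity within a user-chosen background ROI, scaled
#' by the total pixel count of the cube so that it is directly comparable
#' to the summed-spectrum intensities used by [pick_peaks()].
#'
#' @param cube A [sims_cube()].
#' @param roi Background [roi_spec()].
#' @return Numeric vector, one background level per channel.
#' @export
background_from_roi <- function(cube, roi) {
  stopifnot(inherits(cube, "sims_cube"))
  cells <- .roi_cells(roi, cube$pixel_um, dim(cube$counts)[1:2], cube$origin)
  sub <- cube$counts[cells$rows, cells$cols, , drop = FALSE]
  med <- apply(sub, 3, median)
  med * prod(dim(cube$counts)[1:2])
}

#' Pick peaks above a background threshold
#'
#' Selects the channels whose summed-spectrum intensity is greater than or
#' equal to `k` times the per-channel background (boundary inclusive),
#' restricted to the m/z 1-350 analysis window. Categories are initialized
#' to `"Unassigned"`; use [assign_categories()] to transfer reference
#' assignments.
#'
#' @param cube A [sims_cube()].
#' @param background Per-channel background on the summed-spectrum scale
#'   (see [background_from_roi()]); length must equal the channel count.
#' @param k Threshold multiplier (conventionally 3).
#' @param mz_range Analysis window (Da).
#' @return Peak table `data.frame` with columns `mz`, `formula`,
#'   `category`, `intensity`.
#' @export
pick_peaks <- function(cube, background, k = 3, mz_range = c(1, 350)) {
  stopifnot(inherits(cube, "sims_cube"))
  if (length(background) != length(cube$channel_mz))
    stop("background must have one value per channel")
  if (any(background < 0)) stop("background must be non-negative")
  if (k <= 0) stop("k must be > 0")
  total <- apply(cube$counts, 3, sum)
  keep <- total >= k * background &
    cube$channel_mz >= mz_range[1] & cube$channel_mz <= mz_range[2]
  data.frame(mz = cube$channel_mz[keep],
             formula = "",
             category = "Unassigned",
             intensity = total[keep],
             stringsAsFactors = FALSE)
}

#' Assign picked peaks to source categories
#'
#' Transfers `formula` and `category` from a reference assignment table
#' (e.g. [gdap_peak_table()]) to picked peaks by nearest-m/z matching
#' within `tol`; unmatched peaks stay `"Unassigned"`.
#'
#' @param peaks Picked peak table (column `mz`).
#' @param reference Reference table with columns `mz`, `formula`,
#'   `category`.
#' @param tol Matching tolerance (Da).
#' @param drop_contaminants Drop hydrocarbon and salt peaks, the
#'   adventitious contaminants conventionally removed before multivariate
#'   analysis and mapping.
#' @return The peak table with categories filled in.
#' @export
assign_categories <- function(peaks, reference, tol = 0.02,
                              drop_contaminants = FALSE) {
  stopifnot(is.data.frame(peaks), is.data.frame(reference))
  for (i in seq_len(nrow(peaks))) {
    d <- abs(reference$mz - peaks$mz[i])
    j <- which.min(d)
    if (d[j] <= tol) {
      peaks$category[i] <- reference$category[j]
      if ("formula" %in% names(reference)) peaks$formula[i] <- reference$formula[j]
    }
  }
  if (drop_contaminants)
    peaks <- peaks[!peaks$category %in% c("Hydrocarbon", "Salt"), ,
                   drop = FALSE]
  peaks
}

#' Build the ROI spectrum matrix for PCA
#'
#' Extracts one mean spectrum per (cube, ROI) pair: the conventional
#' design of three ROIs on each of five replicate images gives a 15-row
#' matrix.
#'
#' @param cubes A [sims_cube()] or list of cubes (replicate acquisitions).
#' @param rois Named list of [roi_spec()]s.
#' @param peaks Peak table (column `mz`).
#' @return Matrix with one row per spectrum, labelled
#'   `"<cube>:<roi>"`, with attributes `peak_mz` and `roi` (the per-row
#'   ROI name, used to designate background rows).
#' @export
build_spectrum_matrix <- function(cubes, rois, peaks) {
  if (inherits(cubes, "sims_cube")) cubes <- list(cubes)
  if (is.null(names(cubes)))
    names(cubes) <- sprintf("img%d", seq_along(cubes))
  if (is.null(names(rois)))
    names(rois) <- vapply(rois, function(r) r$name, character(1))
  rows <- list()
  roi_of_row <- character(0)
  for (ci in names(cubes)) for (ri in names(rois)) {
    rows[[paste(ci, ri, sep = ":")]] <-
      extract_roi_spectrum(cubes[[ci]], rois[[ri]], peaks)
    roi_of_row <- c(roi_of_row, ri)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("%.2f", peaks$mz)
  attr(m, "peak_mz") <- peaks$mz
  attr(m, "roi") <- roi_of_row
  m
}

#' Total-ion normalization and mean centering of ROI spectra
#'
#' Each spectrum (row) is divided by its total intensity over the selected
#' peaks, so rows sum to one and describe composition rather than raw
#' yield; each peak (column) is then mean-centered across spectra. The
#' normalized-only matrix is returned for reporting, the centered matrix
#' for [fit_pca()].
#'
#' @param m Spectrum matrix (rows = spectra, columns = peaks), e.g. from
#'   [build_spectrum_matrix()].
#' @return List with elements `normalized` and `centered`; both retain the
#'   `peak_mz` and `roi` attributes of the input.
#' @export
normalize_spectra <- function(m) {
  m <- as.matrix(m)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("empty spectrum in ROI")
  norm <- sweep(m, 1, tot, "/")
  centered <- sweep(norm, 2, colMeans(norm), "-")
  for (a in c("peak_mz", "roi")) {
    attr(norm, a) <- attr(m, a)
    attr(centered, a) <- attr(m, a)
  }
  list(normalized = norm, centered = centered)
}

#' Read / write a peak table as CSV
#'
#' Plain CSV with header `mz,formula,category` (additional columns such as
#' `intensity` are preserved).
#'
#' @param path File path.
#' @param peaks Peak table `data.frame`.
#' @return `read_peak_table()` returns the peak table.
#' @export
read_peak_table <- function(path) {
  pk <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mz", "formula", "category")
  if (!all(need %in% names(pk)))
    stop("peak table must have columns ", paste(need, collapse = ", "))
  pk$formula[is.na(pk$formula)] <- ""
  pk
}

#' @rdname read_peak_table
#' @export
write_peak_table <- function(peaks, path) {
  write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write ROI lists as CSV
#'
#' CSV with header `name,x_um,y_um,width_um,height_um`.
#'
#' @param path File path.
#' @param rois List of [roi_spec()]s.
#' @return `read_roi_table()` returns a named list of [roi_spec()]s.
#' @export
read_roi_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    roi_spec(df$x_um[i], df$y_um[i], df$width_um[i], df$height_um[i],
             df$name[i]))
  names(out) <- df$name
  out
}

#' @rdname read_roi_table
#' @export
write_roi_table <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(name = r$name, x_um = r$x_um, y_um = r$y_um,
               width_um = r$width_um, height_um = r$height_um)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
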