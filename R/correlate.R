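#' Single-time SPRi response image
#'
#' Averages the block of `frame_average` consecutive frames whose mean
#' time is nearest the requested readout, giving the binding image that
#' is compared against SIMS glycan maps.
#'
#' @param stack An [spri_stack()].
#' @param t_minutes Readout time (min).
#' @param frame_average Frames per averaging block.
#' @return Numeric matrix (rows x cols).
#' @export
response_image <- function(stack, t_minutes = 11, frame_average = 30L) {
  stopifnot(inherits(stack, "spri_stack"))
  nT <- dim(stack$frames)[3]
  frame_average <- min(frame_average, nT)
  nblock <- nT %/% frame_average
  t_block <- vapply(seq_len(nblock), function(b)
    mean(stack$t_seconds[((b - 1) * frame_average + 1):(b * frame_average)]),
    numeric(1))
  b <- which.min(abs(t_block - 60 * t_minutes))
  fr <- ((b - 1) * frame_average + 1):(b * frame_average)
  apply(stack$frames[, , fr, drop = FALSE], c(1, 2), mean)
}

#' Co-register an SPRi image onto the SIMS pixel grid
#'
#' Resamples the SPRi response image onto the SIMS grid by bilinear
#' interpolation under an affine offset-plus-scale transform mapping SPRi
#' coordinates into the SIMS field: `sims_um = offset_um + scale *
#' spri_um`. `"identity"` requires the two grids to match exactly (the
#' default path for synthetic pairs simulated on a shared grid, keeping
#' resampling an explicit, separately tested step). SIMS pixels that map
#' outside the SPRi frame are set to 0.
#'
#' @param sims_map A `category_map` (supplies the target grid).
#' @param spri_frame SPRi image matrix, e.g. from [response_image()].
#' @param spri_pixel_um SPRi pixel edge (um).
#' @param transform `"identity"` or a list with `offset_um = c(x, y)` and
#'   `scale`.
#' @return An object of class `aligned_pair`: list with `sims_map`,
#'   `spri_map` (resampled to the SIMS grid) and `transform`.
#' @export
coregister <- function(sims_map, spri_frame, spri_pixel_um,
                       transform = "identity") {
  stopifnot(inherits(sims_map, "category_map"))
  d <- dim(sims_map$image)
  if (identical(transform, "identity")) {
    if (!identical(dim(spri_frame), d) ||
        abs(spri_pixel_um - sims_map$pixel_um) > 1e-9)
      stop("identity transform requires matching grids")
    out <- spri_frame
    tr <- list(offset_um = c(0, 0), scale = 1)
  } else {
    tr <- transform
    # SIMS pixel centers -> SPRi coordinates -> fractional SPRi grid
    sx <- (seq_len(d[2]) - 0.5) * sims_map$pixel_um
    sy <- (seq_len(d[1]) - 0.5) * sims_map$pixel_um
    qx <- (sx - tr$offset_um[1]) / tr$scale
    qy <- (sy - tr$offset_um[2]) / tr$scale
    gx <- (seq_len(ncol(spri_frame)) - 0.5) * spri_pixel_um
    gy <- (seq_len(nrow(spri_frame)) - 0.5) * spri_pixel_um
    XP <- matrix(qx, d[1], d[2], byrow = TRUE)
    YP <- matrix(qy, d[1], d[2])
    inside <- XP >= gx[1] & XP <= gx[length(gx)] &
      YP >= gy[1] & YP <= gy[length(gy)]
    out <- matrix(0, d[1], d[2])
    if (any(inside))
      out[inside] <- pracma::interp2(gx, gy, spri_frame,
                                     XP[inside], YP[inside])
  }
  structure(list(sims_map = sims_map, spri_map = out, transform = tr),
            class = "aligned_pair")
}

#' Threshold an SPRi response image into a binding mask
#'
#' Applies [binarize()] to the min-max-normalized SPRi image, outlining
#' the regions of protein binding within the printed spot.
#'
#' @param spri_map SPRi response image matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param level Threshold for `method = "fixed"` (on the normalized
#'   image).
#' @return Logical mask with attribute `threshold`.
#' @export
binding_contour <- function(spri_map, method = c("otsu", "fixed"),
                            level = NULL) {
  binarize(normalize_image(spri_map), method = match.arg(method),
           level = level)
}

# boundary pixels of a mask: mask minus its 8-neighbour erosion, with
# outside-of-image treated as background
.mask_outline <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  interior <- mask
  for (dr in -1:1) for (dc in -1:1) {
    interior <- interior & pad[(2 + dr):(nr + 1 + dr),
                               (2 + dc):(nc + 1 + dc)]
  }
  mask & !interior
}

#' Overlay a binding-mask outline on a SIMS ion map
#'
#' Renders the (normalized) SIMS glycan map in grayscale and burns the
#' one-pixel outline of the SPRi binding mask into a distinct color
#' channel, the standard visualization for comparing glycan distribution
#' with bioactivity.
#'
#' @param sims_map Normalized `category_map` or matrix in `[0, 1]`.
#' @param binding_mask Logical mask of identical shape.
#' @param color Outline RGB in `[0, 1]` (default yellow).
#' @return A `composite_image` whose `rgb` is grayscale plus the outline.
#' @export
overlay_contour <- function(sims_map, binding_mask,
                            color = c(1, 1, 0)) {
  img <- if (inherits(sims_map, "category_map")) sims_map$image else sims_map
  if (!identical(dim(img), dim(binding_mask))) stop("shape mismatch")
  if (min(img) < 0 || max(img) > 1)
    stop("overlay expects a normalized image in [0, 1]")
  outline <- .mask_outline(binding_mask)
  arr <- array(rep(img, 3), dim = c(dim(img), 3))
  for (ch in 1:3) {
    plane <- arr[, , ch]
    plane[outline] <- color[ch]
    arr[, , ch] <- plane
  }
  structure(list(rgb = arr,
                 channel_categories = rep("overlay", 3)),
            class = "composite_image")
}

#' Spatial agreement between SIMS and SPRi masks/images
#'
#' Overlap and correlation statistics quantifying how well the chemical
#' (SIMS glycan) and biological (SPRi binding) pictures of a printed spot
#' agree: Dice `2|A&B|/(|A|+|B|)`, Jaccard `|A&B|/|A|B|`, and -- when
#' the underlying images are supplied -- the Pearson correlation over all
#' pixels. The statistics are reported together; none is a headline
#' number on its own.
#'
#' @param mask_a,mask_b Logical masks of identical shape.
#' @param image_a,image_b Optional aligned images for the Pearson
#'   correlation; a constant image makes the correlation undefined and is
#'   flagged rather than an error.
#' @return List with `dice`, `jaccard`, `pearson_r` (NA when undefined)
#'   and `pearson_defined`.
#' @export
spatial_agreement <- function(mask_a, mask_b, image_a = NULL,
                              image_b = NULL) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("shape mismatch")
  inter <- sum(mask_a & mask_b)
  uni <- sum(mask_a | mask_b)
  jac <- if (uni == 0) 1 else inter / uni
  out <- list(dice = dice_coefficient(mask_a, mask_b), jaccard = jac,
              pearson_r = NA_real_, pearson_defined = FALSE)
  if (!is.null(image_a) && !is.null(image_b)) {
    if (!identical(dim(image_a), dim(image_b))) stop("shape mismatch")
    if (stats::sd(image_a) > 0 && stats::sd(image_b) > 0) {
      out$pearson_r <- cor(as.vector(image_a), as.vector(image_b))
      out$pearson_defined <- TRUE
    }
  }
  out
}
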