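#' Category ion map
#'
#' Sums per-pixel counts over all channels assigned to one source
#' category, producing the ion map used to visualize where that surface
#' species sits. Hydrocarbon and salt maps -- adventitious contaminants --
#' are refused unless `allow_contaminants = TRUE` (contaminant QC).
#'
#' @param cube A [sims_cube()].
#' @param peaks Peak table with columns `mz` and `category` (e.g. from
#'   [assign_categories()], or an [select_ions()] side carried in a peak
#'   table).
#' @param category Category label to map.
#' @param allow_contaminants Permit Hydrocarbon/Salt maps.
#' @param tol Peak-to-channel matching tolerance (Da).
#' @return An object of class `category_map`: list with `category`,
#'   `image` (rows x cols), `normalized` flag and `pixel_um`.
#' @export
category_image <- function(cube, peaks, category,
                           allow_contaminants = FALSE, tol = 0.02) {
  stopifnot(inherits(cube, "sims_cube"))
  if (category %in% c("Hydrocarbon", "Salt") && !allow_contaminants)
    stop("contaminant categories are excluded from mapping by default; ",
         "set allow_contaminants = TRUE for QC maps")
  sel <- peaks[peaks$category == category, , drop = FALSE]
  if (nrow(sel) == 0) stop("no peaks carry category ", category)
  ch <- match_channels(sel$mz, cube$channel_mz, tol)
  img <- rowSums(cube$counts[, , ch, drop = FALSE], dims = 2)
  structure(list(category = category, image = img, normalized = FALSE,
                 pixel_um = cube$pixel_um), class = "category_map")
}

#' Min-max normalize an ion map to [0, 1]
#'
#' @param map A `category_map` (or plain matrix).
#' @return The map with `image` scaled to `[0, 1]` and `normalized = TRUE`.
#' @export
normalize_image <- function(map) {
  img <- if (inherits(map, "category_map")) map$image else map
  rng <- range(img)
  if (rng[1] == rng[2]) stop("degenerate contrast")
  out <- (img - rng[1]) / (rng[2] - rng[1])
  if (inherits(map, "category_map")) {
    map$image <- out
    map$normalized <- TRUE
    map
  } else out
}

#' Binarize an ion map
#'
#' Thresholds a normalized (values in `[0, 1]`) ion map into a binary
#' mask, `mask = image >= level`. The default level is Otsu's criterion
#' (the 256-bin histogram threshold maximizing between-class variance),
#' which is deterministic and parameter-free; a fixed level can be given
#' instead.
#'
#' @param map A normalized `category_map` or matrix with values in
#'   `[0, 1]`.
#' @param method `"otsu"` or `"fixed"`.
#' @param level Threshold for `method = "fixed"`.
#' @return Logical matrix with attribute `threshold`.
#' @export
binarize <- function(map, method = c("otsu", "fixed"), level = NULL) {
  method <- match.arg(method)
  img <- if (inherits(map, "category_map")) map$image else map
  if (min(img) < 0 || max(img) > 1)
    stop("binarize expects a normalized image in [0, 1]; see normalize_image")
  th <- if (method == "fixed") {
    if (is.null(level)) stop("method \"fixed\" requires a level")
    level
  } else {
    EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  }
  structure(img >= th, dim = dim(img), threshold = th)
}

#' Compose an RGB chemical map from three category maps
#'
#' Stacks three normalized (or binarized) maps into the conventional
#' red = GDAP, green = OEG/SAM, blue = gold composite.
#'
#' @param red,green,blue Normalized `category_map`s, matrices or binary
#'   masks of identical shape.
#' @return An object of class `composite_image`: list with `rgb`
#'   (rows x cols x 3 in `[0, 1]`) and `channel_categories`.
#' @export
composite_rgb <- function(red, green, blue) {
  get_img <- function(x) {
    img <- if (inherits(x, "category_map")) x$image else x
    storage.mode(img) <- "double"
    img
  }
  get_cat <- function(x, dflt)
    if (inherits(x, "category_map")) x$category else dflt
  r <- get_img(red); g <- get_img(green); b <- get_img(blue)
  if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b)))
    stop("shape mismatch")
  if (min(r, g, b) < 0 || max(r, g, b) > 1)
    stop("channels must be in [0, 1]")
  arr <- array(c(r, g, b), dim = c(dim(r), 3))
  structure(list(rgb = arr,
                 channel_categories = c(get_cat(red, "GDAP"),
                                        get_cat(green, "OEG/SAM"),
                                        get_cat(blue, "Gold"))),
            class = "composite_image")
}

#' Write a composite chemical map (or any RGB array) as PNG
#'
#' @param composite A `composite_image` or rows x cols x 3 array in
#'   `[0, 1]`.
#' @param path Output PNG path.
#' @export
write_composite_png <- function(composite, path) {
  arr <- if (inherits(composite, "composite_image")) composite$rgb
         else composite
  png::writePNG(arr, path)
  invisible(path)
}

#' Write an ion map as 16-bit TIFF
#'
#' Counts are scaled by the image maximum into `[0, 1]` and stored at
#' 16-bit depth, adequate for visualization and thresholding.
#'
#' @param map A `category_map` or matrix.
#' @param path Output TIFF path.
#' @export
write_ion_map_tiff <- function(map, path) {
  img <- if (inherits(map, "category_map")) map$image else map
  mx <- max(img)
  if (mx <= 0) mx <- 1
  tiff::writeTIFF(img / mx, path, bits.per.sample = 16L)
  invisible(path)
}

# 8-connected component labeling (conventional for blob analysis).
# Iterative flood fill; adequate for the 128 x 128 fields used here.
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L
      cl <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  lab
}

#' Dice overlap of two binary masks
#'
#' `2|A & B| / (|A| + |B|)`; 1 for identical non-empty masks, 0 for
#' disjoint ones. Defined as 1 when both masks are empty.
#'
#' @param a,b Logical matrices of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Spot morphology metrics from a binary mask
#'
#' Reports the area, equivalent-circle diameter, centroid and
#' eccentricity of the largest 8-connected component of the mask, and --
#' when a ground truth is supplied -- the Dice overlap with the planted
#' spot mask. Eccentricity is computed from the second spatial moments of
#' the component (0 for a disk, approaching 1 for a line).
#'
#' @param mask Logical matrix (e.g. from [binarize()]).
#' @param pixel_um Pixel edge (um).
#' @param truth Optional [make_ground_truth()] object (or logical truth
#'   mask) to score against.
#' @param include_tail Passed to [truth_mask()] when `truth` is a ground
#'   truth.
#' @return List with `area_um2`, `equivalent_diameter_um`, `centroid_um`,
#'   `eccentricity`, `n_components` and (with truth) `dice`. An empty
#'   mask gives `NA` size metrics and Dice 0.
#' @export
spot_metrics <- function(mask, pixel_um, truth = NULL, include_tail = TRUE) {
  tmask <- if (inherits(truth, "ground_truth"))
    truth_mask(truth, include_tail) else truth
  if (!any(mask)) {
    out <- list(area_um2 = NA_real_, equivalent_diameter_um = NA_real_,
                centroid_um = c(NA_real_, NA_real_),
                eccentricity = NA_real_, n_components = 0L)
    if (!is.null(tmask)) out$dice <- 0
    return(out)
  }
  lab <- .label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  comp <- lab == big
  npix <- sizes[big]
  area <- npix * pixel_um^2
  ij <- which(comp, arr.ind = TRUE)
  x <- (ij[, 2] - 0.5) * pixel_um
  y <- (ij[, 1] - 0.5) * pixel_um
  ecc <- if (npix > 1) {
    ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE,
                only.values = TRUE)$values
    sqrt(max(0, 1 - ev[2] / ev[1]))
  } else 0
  out <- list(area_um2 = area,
              equivalent_diameter_um = 2 * sqrt(area / pi),
              centroid_um = c(mean(x), mean(y)),
              eccentricity = ecc,
              n_components = max(lab))
  if (!is.null(tmask)) out$dice <- dice_coefficient(mask, tmask)
  out
}

#' Radial mean-intensity profile of an image
#'
#' Mean pixel intensity in concentric annuli around a center, used to
#' check for rim-enriched ("coffee stain") deposition.
#'
#' @param img Numeric matrix.
#' @param center_um Center `c(x, y)` (um).
#' @param pixel_um Pixel edge (um).
#' @param bin_um Annulus width (um).
#' @return `data.frame` with `r_um` (annulus mid-radius) and `mean`.
#' @export
radial_profile <- function(img, center_um, pixel_um, bin_um = pixel_um) {
  nr <- nrow(img); nc <- ncol(img)
  cx <- matrix((seq_len(nc) - 0.5) * pixel_um, nr, nc, byrow = TRUE)
  cy <- matrix((seq_len(nr) - 0.5) * pixel_um, nr, nc)
  r <- sqrt((cx - center_um[1])^2 + (cy - center_um[2])^2)
  bin <- floor(r / bin_um)
  mu <- tapply(as.vector(img), as.vector(bin), mean)
  data.frame(r_um = (as.numeric(names(mu)) + 0.5) * bin_um,
             mean = as.numeric(mu))
}
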