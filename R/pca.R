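#' Principal component analysis of a centered ROI spectrum matrix
#'
#' Decomposes the column-centered spectrum matrix by singular value
#' decomposition: scores are the data projected on the loadings, loadings
#' have unit-norm (orthonormal) columns, and each component's variance
#' fraction is its squared singular value over the total.
#'
#' @param m Centered spectrum matrix (rows = spectra, columns = peaks),
#'   e.g. the `centered` element of [normalize_spectra()]. Column means
#'   must be zero to within `center_tol`.
#' @param n_components Number of components to retain, between 1 and
#'   `min(nrow(m) - 1, ncol(m))`.
#' @param center_tol Tolerance on column means relative to the matrix
#'   scale.
#' @return An object of class `sims_pca` with `scores`, `loadings`,
#'   `variance_fraction` (over all components, summing to 1), `sdev` and
#'   `peak_mz`/`roi` carried over from the input attributes.
#' @export
fit_pca <- function(m, n_components = NULL, center_tol = 1e-8) {
  m <- as.matrix(m)
  n <- nrow(m); p <- ncol(m)
  kmax <- min(n - 1L, p)
  if (is.null(n_components)) n_components <- kmax
  if (n_components < 1 || n_components > kmax)
    stop("n_components must be in [1, min(n_spectra - 1, n_peaks)]")
  scale_ref <- max(abs(m), 1e-300)
  if (max(abs(colMeans(m))) > center_tol * max(1, scale_ref))
    stop("matrix must be column-centered (see normalize_spectra)")
  s <- svd(m)
  if (max(s$d) <= 1e-300 * max(1, scale_ref)) stop("rank-0 matrix")
  vf <- s$d^2 / sum(s$d^2)
  k <- seq_len(n_components)
  scores <- s$u[, k, drop = FALSE] %*% diag(s$d[k], n_components)
  loadings <- s$v[, k, drop = FALSE]
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  colnames(scores) <- colnames(loadings) <- sprintf("PC%d", k)
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = vf, sdev = s$d / sqrt(max(1, n - 1)),
                 n_components = n_components,
                 peak_mz = attr(m, "peak_mz"), roi = attr(m, "roi")),
            class = "sims_pca")
}

#' @export
print.sims_pca <- function(x, ...) {
  cat(sprintf("sims_pca: %d spectra x %d peaks, %d components\n",
              nrow(x$scores), nrow(x$loadings), x$n_components))
  k <- seq_len(min(3, length(x$variance_fraction)))
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", k, 100 * x$variance_fraction[k]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Orient PC1 so substrate/background scores are positive
#'
#' PCA determines each component only up to sign. The convention for
#' spot-versus-background analysis is that positive PC1 is attributed to
#' substrate/background and negative PC1 to glycan-related species; this
#' helper flips PC1 scores and loadings jointly so the mean PC1 score of
#' the designated background spectra is positive. Other components are
#' untouched.
#'
#' @param pca A [fit_pca()] result.
#' @param background_rows Indices (or row names) of background spectra.
#' @return The oriented `sims_pca`.
#' @export
orient_pc1 <- function(pca, background_rows) {
  stopifnot(inherits(pca, "sims_pca"))
  if (length(background_rows) == 0) stop("background rows must be non-empty")
  mu <- mean(pca$scores[background_rows, 1])
  if (mu == 0) stop("orientation undefined")
  if (mu < 0) {
    pca$scores[, 1] <- -pca$scores[, 1]
    pca$loadings[, 1] <- -pca$loadings[, 1]
  }
  pca
}

#' Select ions by PC1 loading threshold
#'
#' Ions whose PC1 loading is at or above `+threshold` form the positive
#' (substrate/background) list; those at or below `-threshold` form the
#' negative (glycan) list. The boundary is inclusive.
#'
#' @param pca An oriented [fit_pca()] result (see [orient_pc1()]).
#' @param peaks Peak table aligned with the loading rows (same order and
#'   length).
#' @param threshold Positive loading cutoff; 0.03 is the conventional
#'   choice.
#' @return An object of class `ion_selection`: list with data frames
#'   `positive` and `negative` (columns `mz`, `loading`, plus any peak
#'   table columns) and the `threshold`.
#' @export
select_ions <- function(pca, peaks, threshold = 0.03) {
  stopifnot(inherits(pca, "sims_pca"))
  if (threshold <= 0) stop("threshold must be > 0")
  if (nrow(peaks) != nrow(pca$loadings))
    stop("peaks must align with the loading rows")
  l1 <- pca$loadings[, 1]
  mk <- function(idx) {
    out <- cbind(peaks[idx, , drop = FALSE],
                 loading = l1[idx])
    out[order(out$mz), , drop = FALSE]
  }
  structure(list(positive = mk(which(l1 >= threshold)),
                 negative = mk(which(l1 <= -threshold)),
                 threshold = threshold),
            class = "ion_selection")
}

#' @export
print.ion_selection <- function(x, ...) {
  cat(sprintf("ion_selection (|PC1 loading| >= %g):\n", x$threshold))
  cat(sprintf("  positive (substrate/background): %d ions\n",
              nrow(x$positive)))
  cat(sprintf("  negative (glycan): %d ions\n", nrow(x$negative)))
  invisible(x)
}

#' Welch test of PC1 score separation between two ROI groups
#'
#' Two-sided Welch (unequal-variance) two-sample t-test on PC1 scores,
#' used to ask whether the spot region separates from the background
#' regions, or whether two background regions are statistically similar.
#'
#' @param scores_pc1 Numeric vector of PC1 scores.
#' @param labels Group label per score; exactly two groups, each with at
#'   least two values.
#' @return The two-sided p-value.
#' @export
group_separation <- function(scores_pc1, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) != 2) stop("exactly two groups required")
  a <- scores_pc1[labels == groups[1]]
  b <- scores_pc1[labels == groups[2]]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least two values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Persist a PCA result as a CSV triplet
#'
#' Writes `scores.csv`, `loadings.csv` and `variance.csv` into `dir`.
#'
#' @param pca A `sims_pca` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pca <- function(pca, dir) {
  stopifnot(inherits(pca, "sims_pca"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(pca$scores, file.path(dir, "scores.csv"))
  write.csv(pca$loadings, file.path(dir, "loadings.csv"))
  write.csv(data.frame(component = seq_along(pca$variance_fraction),
                       variance_fraction = pca$variance_fraction),
            file.path(dir, "variance.csv"), row.names = FALSE)
  invisible(dir)
}
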