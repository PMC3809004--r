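# Shared fixtures and independent oracles, built in code at test time.

# A small field with a centered spot, cheap enough for per-test simulation.
tiny_truth <- function(field_um = 200, pixel_um = 4, spot_diameter_um = 100,
                       ...) {
  make_ground_truth(field_um = field_um, pixel_um = pixel_um,
                    spot_center_um = c(field_um / 2, field_um / 2),
                    spot_diameter_um = spot_diameter_um, ...)
}

# Exhaustive Otsu oracle: search all 256 candidate bin boundaries for the
# threshold maximizing between-class variance. On bimodal images the
# objective is flat across the empty gap between modes; every threshold
# on the plateau is a maximizer, so the oracle reports the plateau
# midpoint as its tie-break.
otsu_exhaustive <- function(img) {
  breaks <- seq(0, 1, length.out = 257)
  h <- hist(as.vector(img), breaks = breaks, plot = FALSE)$counts
  p <- h / sum(h)
  mids <- (breaks[-257] + breaks[-1]) / 2
  v <- rep(NA_real_, 255)
  for (k in 1:255) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):256] * mids[(k + 1):256]) / w1
    v[k] <- w0 * w1 * (mu0 - mu1)^2
  }
  plateau <- which(v >= max(v, na.rm = TRUE) - 1e-12)
  th_all <- breaks[plateau + 1]
  list(threshold = mean(range(th_all)), plateau = range(th_all),
       objective = function(th) {
    cls <- as.vector(img) >= th
    w1 <- mean(cls)
    if (w1 == 0 || w1 == 1) return(0)
    (1 - w1) * w1 * (mean(img[!cls]) - mean(img[cls]))^2
  })
}

# Welch two-sample statistic computed from first principles.
welch_p_manual <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# PCA oracle: eigendecomposition of the covariance-like cross-product
# matrix of the centered data.
pca_eigen_oracle <- function(X) {
  ev <- eigen(crossprod(X), symmetric = TRUE)
  list(loadings = ev$vectors, scores = X %*% ev$vectors,
       variance_fraction = ev$values / sum(ev$values))
}

# Align column signs of `got` to `ref` before comparison (PCA columns are
# defined only up to sign).
align_signs <- function(got, ref) {
  for (j in seq_len(ncol(got))) {
    if (sum(got[, j] * ref[, j]) < 0) got[, j] <- -got[, j]
  }
  got
}
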