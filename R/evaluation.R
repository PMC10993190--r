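# Quantitative evaluation: ROI-restricted MSE and 3D SSIM on
# reference-anchored normalized magnitudes, and the paired t-test.

#' Cuboid region of interest
#'
#' 0-based half-open voxel intervals, e.g. the heart bounding box.
#'
#' @param x0,x1,y0,y1,z0,z1 interval bounds
#' @return object of class \code{roi_box}
#' @export
roi_box <- function(x0, x1, y0, y1, z0, z1) {
  assert_that(x1 > x0 && y1 > y0 && z1 > z0, "empty ROI")
  structure(list(x0 = x0, x1 = x1, y0 = y0, y1 = y1, z0 = z0, z1 = z1),
            class = "roi_box")
}

roi_crop <- function(vol, roi) {
  vol[(roi$x0 + 1):roi$x1, (roi$y0 + 1):roi$y1, (roi$z0 + 1):roi$z1,
      drop = FALSE]
}

#' ROI MSE and SSIM between a reconstruction and a reference
#'
#' Both magnitudes are normalized by the reference's 99th percentile within
#' the ROI (so the metrics are invariant to global intensity scaling of
#' either volume); MSE is the mean squared difference and SSIM a
#' single-scale 3D structural similarity with a Gaussian window
#' (sigma 1.5, 7-voxel support) and standard constants
#' (K1 = 0.01, K2 = 0.03, data range 1).
#'
#' @param recon,reference complex or numeric volumes on the same grid
#' @param roi a \code{\link{roi_box}} (default: full volume)
#' @return list(mse, ssim)
#' @export
roi_metrics <- function(recon, reference, roi = NULL) {
  assert_that(all(dim(recon) == dim(reference)), "grids must match")
  a <- abs(recon); b <- abs(reference)
  if (!is.null(roi)) { a <- roi_crop(a, roi); b <- roi_crop(b, roi) }
  assert_that(length(a) > 0, "degenerate ROI")
  p99 <- stats::quantile(b, 0.99, names = FALSE)
  assert_that(p99 > 0, "reference is identically zero in the ROI")
  # scale-invariance contract: the recon is normalized by its own 99th
  # percentile onto the reference scale
  a99 <- stats::quantile(a, 0.99, names = FALSE)
  a <- if (a99 > 0) a / a99 else a
  b <- b / p99
  mse <- mean((a - b)^2)
  list(mse = mse, ssim = ssim3d(a, b, data_range = 1))
}

#' Single-scale 3D SSIM
#'
#' Gaussian-window SSIM on 3D arrays (mean over the local SSIM map).
#'
#' @param a,b numeric 3D arrays
#' @param data_range dynamic range L
#' @param sigma Gaussian window standard deviation (voxels)
#' @param radius window half-width (voxels)
#' @param K1,K2 stability constants
#' @return scalar SSIM in [-1, 1]
#' @export
ssim3d <- function(a, b, data_range = 1, sigma = 1.5, radius = 3,
                   K1 = 0.01, K2 = 0.03) {
  kern <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  blur <- function(x) {
    d <- dim(x)
    v <- as.vector(x)
    for (ax in 0:2) v <- sepconv3_cpp(v, kern, as.integer(c(d, 1)), ax)
    array(v, dim = d)
  }
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  mu_a <- blur(a); mu_b <- blur(b)
  va <- blur(a * a) - mu_a^2
  vb <- blur(b * b) - mu_b^2
  cab <- blur(a * b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Paired two-sided t-test on per-case metrics
#'
#' @param a,b equal-length numeric vectors (>= 2 pairs)
#' @return list(t, p); zero-variance differences give t = 0 (or Inf for a
#'   constant nonzero shift is impossible without variance, so \code{p} is
#'   reported as NaN with a warning)
#' @export
paired_ttest <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) >= 2,
              "need equal-length vectors with at least two pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    warning("zero variance of differences; p-value degenerate")
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)), p = NaN))
  }
  r <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(r$statistic), p = r$p.value)
}
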