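# iNAV registration, k-space phase-shift translational correction,
# soft-gated respiratory binning, velocity-field integration by scaling and
# squaring, and the warping operators M / M*.

#' Register a stack of 2D iNAVs
#'
#' Template matching by cross-correlation against the stack-mean template
#' (computed via FFT), with parabolic sub-pixel refinement, optionally
#' restricted to a rectangular ROI. Returned translations are each
#' heartbeat's (FH, LR) position relative to the mean position over all
#' heartbeats, in mm (re-referenced to zero mean).
#'
#' @param inavs numeric array [n_beats, nx, ny]
#' @param roi optional c(x0, x1, y0, y1), 0-based half-open voxel intervals
#' @param voxel_mm iNAV pixel size in mm
#' @param max_shift_px maximum detectable shift (pixels)
#' @return object of class \code{resp_translations} with \code{t_mm}
#'   [n_beats, 2]
#' @export
register_inavs <- function(inavs, roi = NULL, voxel_mm = 1, max_shift_px = NULL) {
  assert_that(length(dim(inavs)) == 3 && dim(inavs)[1] >= 2,
              "need a stack of at least two iNAVs")
  H <- dim(inavs)[1]
  imgs <- lapply(seq_len(H), function(m) inavs[m, , ])
  if (!is.null(roi)) {
    imgs <- lapply(imgs, function(im) im[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4], drop = FALSE])
  }
  tmpl <- Reduce(`+`, imgs) / H
  if (stats::sd(tmpl) == 0) stop("flat iNAVs: correlation undefined", call. = FALSE)
  n <- dim(tmpl)
  if (is.null(max_shift_px)) max_shift_px <- floor(min(n) / 4)
  Ft <- stats::fft(tmpl - mean(tmpl))
  shifts <- matrix(0, H, 2)
  for (m in seq_len(H)) {
    im <- imgs[[m]]
    if (stats::sd(im) == 0) stop("flat iNAVs: correlation undefined", call. = FALSE)
    cc <- Re(stats::fft(Conj(Ft) * stats::fft(im - mean(im)), inverse = TRUE)) / length(tmpl)
    # circular lag grid: lag 0 at index 1
    lag1 <- c(0:(n[1] - 1)); lag1[lag1 > n[1] / 2] <- lag1[lag1 > n[1] / 2] - n[1]
    lag2 <- c(0:(n[2] - 1)); lag2[lag2 > n[2] / 2] <- lag2[lag2 > n[2] / 2] - n[2]
    ok <- outer(abs(lag1) <= max_shift_px, abs(lag2) <= max_shift_px)
    cc_ok <- cc; cc_ok[!ok] <- -Inf
    p <- arrayInd(which.max(cc_ok), n)
    sub <- function(axis) {
      i <- p[axis]
      ip <- i %% n[axis] + 1L; im_ <- (i - 2L) %% n[axis] + 1L
      c0 <- cc[p[1], p[2]]
      cp <- if (axis == 1) cc[ip, p[2]] else cc[p[1], ip]
      cm <- if (axis == 1) cc[im_, p[2]] else cc[p[1], im_]
      den <- cm - 2 * c0 + cp
      if (den >= 0) 0 else 0.5 * (cm - cp) / den
    }
    shifts[m, ] <- c(lag1[p[1]] + sub(1), lag2[p[2]] + sub(2))
  }
  t_mm <- sweep(shifts, 2, colMeans(shifts)) * voxel_mm
  structure(list(t_mm = t_mm), class = "resp_translations")
}

#' @export
print.resp_translations <- function(x, ...) {
  cat(sprintf("<resp_translations> %d heartbeats, FH range [%.2f, %.2f] mm\n",
              nrow(x$t_mm), min(x$t_mm[, 1]), max(x$t_mm[, 1])))
  invisible(x)
}

#' Translational respiratory correction by k-space phase shift
#'
#' Multiplies each k-space sample by \code{exp(2i pi k . T_m)}, where
#' \code{k = (k_x, k_y)} are the sample's coordinates in cycles/mm and
#' \code{T_m} is the heartbeat's 2D (FH, LR) translation in mm relative to
#' the mean position. The factor has unit modulus, so sample magnitudes are
#' preserved exactly; the effect is to align the heart position across
#' heartbeats at the mean respiratory position.
#'
#' @param kdata a \code{kspace_data} object
#' @param translations a \code{resp_translations} or an [H, 2] matrix (mm)
#' @return the corrected \code{kspace_data}
#' @export
phase_correct <- function(kdata, translations) {
  t_mm <- if (inherits(translations, "resp_translations")) translations$t_mm else translations
  traj <- kdata$traj
  H <- traj$n_heartbeats
  assert_that(nrow(t_mm) == H, "translation count must equal heartbeat count")
  n <- kdata$shape
  d <- dim(kdata$kspace)
  kxc <- (0:(n[1] - 1)) - n[1] %/% 2           # centred kx index
  kyc <- traj$readouts[, 1] - traj$grid$center[1]
  fx <- kxc / (n[1] * kdata$voxel_mm)          # cycles/mm
  fy <- kyc / (traj$grid$n_ky * kdata$voxel_mm)
  out <- kdata
  for (j in seq_len(d[2])) {
    m <- traj$heartbeat[j] + 1L
    # sign: a beat at position +T has spectrum F(k) exp(-2pi i k.T); the
    # unit-modulus factor below undoes it, per-sample over the kx line
    ph <- exp(2i * pi * (fx * t_mm[m, 1] + fy[j] * t_mm[m, 2]))
    for (c in seq_len(d[1])) out$kspace[c, j, ] <- kdata$kspace[c, j, ] * ph
  }
  out$phase_corrected <- TRUE
  out
}

#' Soft-gated respiratory binning
#'
#' Heartbeats are sorted by FH position and split into \code{n_bins}
#' equal-count groups (primary assignment; counts differ by at most one).
#' The soft weight of heartbeat i in bin b is 1 for its primary bin and
#' \code{exp(-(d_ib / (softness * w_b))^2)} otherwise, where \code{d_ib} is
#' the FH distance to bin b's centre and \code{w_b} the bin half-width;
#' \code{softness -> 0} recovers hard gating. The end-expiration bin is the
#' one whose centre is extremal in the end-expiration direction (with the
#' phantom's convention, the minimal FH position).
#'
#' @param translations a \code{resp_translations} or [H, 2] matrix (mm)
#' @param n_bins number of respiratory bins (default 4)
#' @param softness soft-gating width parameter (default 0.5); 0 = hard
#' @param end_exp \code{"min"} or \code{"max"}: which FH extreme is
#'   end-expiration
#' @return object of class \code{bin_weights} with matrix \code{W}
#'   [H, n_bins] in [0, 1], \code{primary}, \code{bin_centers},
#'   \code{half_widths} and \code{end_exp_bin}
#' @export
bin_heartbeats <- function(translations, n_bins = 4, softness = 0.5,
                           end_exp = c("min", "max")) {
  end_exp <- match.arg(end_exp)
  t_mm <- if (inherits(translations, "resp_translations")) translations$t_mm else translations
  fh <- t_mm[, 1]
  H <- length(fh)
  assert_that(n_bins >= 1, "need at least one bin")
  assert_that(H >= n_bins, "fewer heartbeats than bins")
  sizes <- rep(H %/% n_bins, n_bins)
  extra <- H %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(fh)
  primary <- integer(H)
  idx <- 1L
  for (b in seq_len(n_bins)) {
    members <- ord[idx:(idx + sizes[b] - 1L)]
    primary[members] <- b
    idx <- idx + sizes[b]
  }
  centers <- vapply(seq_len(n_bins), function(b) mean(fh[primary == b]), 0)
  half_w <- vapply(seq_len(n_bins), function(b) {
    r <- range(fh[primary == b]); max((r[2] - r[1]) / 2, 1e-6)
  }, 0)
  W <- matrix(0, H, n_bins)
  for (b in seq_len(n_bins)) {
    d <- abs(fh - centers[b])
    if (softness > 0) W[, b] <- exp(-(d / (softness * half_w[b]))^2)
  }
  W[cbind(seq_len(H), primary)] <- 1
  end_exp_bin <- if (end_exp == "min") which.min(centers) else which.max(centers)
  structure(list(W = W, primary = primary, bin_centers = centers,
                 half_widths = half_w, end_exp_bin = end_exp_bin,
                 n_bins = as.integer(n_bins), softness = softness),
            class = "bin_weights")
}

#' @export
print.bin_weights <- function(x, ...) {
  cat(sprintf("<bin_weights> %d heartbeats x %d bins (softness %.2f), end-expiration bin %d\n",
              nrow(x$W), x$n_bins, x$softness, x$end_exp_bin))
  cat("  primary counts:", tabulate(x$primary, x$n_bins), "\n")
  invisible(x)
}

#' Integrate a stationary velocity field by scaling and squaring
#'
#' The displacement exp(v) is computed as phi_(1/2^n) = id + v / 2^n followed
#' by n self-compositions; the inverse field is the same procedure applied to
#' -v. For smooth fields the two compose to the identity to within a small
#' fraction of a voxel, and the forward map is diffeomorphic (positive
#' Jacobian).
#'
#' @param v velocity field [nx, ny, nz, 3], voxel units
#' @param n_steps number of squaring steps (default 6)
#' @return list with \code{forward} and \code{inverse} displacement fields
#' @export
integrate_velocity <- function(v, n_steps = 6) {
  assert_that(all(is.finite(v)), "velocity field must be finite")
  assert_that(n_steps >= 1, "n_steps must be >= 1")
  integrate_one <- function(vv) {
    d <- vv / 2^n_steps
    vdim <- dim(d)
    for (i in seq_len(n_steps)) {
      d <- d + array(warp_fwd_cpp(as.vector(d), as.vector(d), as.integer(vdim)),
                     dim = vdim)
    }
    d
  }
  list(forward = integrate_one(v), inverse = integrate_one(-v))
}

#' Warp a volume by a displacement field
#'
#' Trilinear interpolation of the volume at \code{x + disp(x)}, clamping
#' out-of-volume reads to the edge. Linear in the volume argument; complex
#' volumes are warped channel-wise (real and imaginary parts).
#'
#' @param volume 3D numeric or complex array
#' @param disp displacement field [nx, ny, nz, 3], voxel units
#' @return warped volume, same type and shape
#' @export
warp_volume <- function(volume, disp) {
  n <- dim(volume)
  assert_that(all(dim(disp) == c(n, 3)), "displacement grid mismatch")
  if (is.complex(volume)) {
    x <- c2r(volume)
    y <- array(warp_fwd_cpp(as.vector(x), as.vector(disp), as.integer(dim(x))),
               dim = dim(x))
    r2c(y)
  } else {
    x <- array(volume, dim = c(n, 1))
    y <- array(warp_fwd_cpp(as.vector(x), as.vector(disp), as.integer(dim(x))),
               dim = dim(x))
    array(y, dim = n)
  }
}

#' Exact adjoint (transpose) of \code{warp_volume}
#'
#' For a fixed displacement field the warp is a sparse linear map A; this
#' computes \code{A^T y} by splatting each value onto its eight trilinear
#' source voxels, so that \code{<A x, y> == <x, A^T y>} to machine precision.
#'
#' @inheritParams warp_volume
#' @export
warp_adjoint <- function(volume, disp) {
  n <- dim(volume)
  assert_that(all(dim(disp) == c(n, 3)), "displacement grid mismatch")
  if (is.complex(volume)) {
    x <- c2r(volume)
    y <- array(warp_splat_cpp(as.vector(x), as.vector(disp), as.integer(dim(x))),
               dim = dim(x))
    r2c(y)
  } else {
    x <- array(volume, dim = c(n, 1))
    y <- array(warp_splat_cpp(as.vector(x), as.vector(disp), as.integer(dim(x))),
               dim = dim(x))
    array(y, dim = n)
  }
}
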