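# Deforming numerical thorax/heart phantom with multi-coil k-space
# simulation along a CASPR-style trajectory and simulated 2D iNAVs.
#
# Geometry and sign conventions (documented once, used everywhere):
#   axis 1 (x) = foot-head (FH), the fully sampled readout direction;
#   axis 2 (y) = left-right (LR), phase encode ky;
#   axis 3 (z) = anterior-posterior (AP), phase encode kz.
# Motion state s in [0, 1]: s = 0 is end-expiration (the reference frame),
# s = 1 end-inspiration. Respiratory displacement of a material point at
# reference position (x, y, z) (mm, volume-centred):
#   u_x = s * amp_fh * (1 + nonrigid_frac * x/Xh + shear_frac * z/Zh)
#   u_y = s * amp_lr,   u_z = 0,
# i.e. a bulk FH/LR translation plus an FH-graded non-rigid stretch and a
# mild AP-dependent shear, emulating diaphragm-driven motion. The map is
# affine in x and analytically invertible, so renders and ground-truth
# forward/inverse fields are exact.

#' Phantom specification
#'
#' @param shape volume dimensions c(nx, ny, nz) in voxels
#' @param voxel_mm isotropic voxel size in mm
#' @param n_coils number of receive coils
#' @param noise_sd standard deviation of the circular complex Gaussian
#'   k-space noise (per complex sample, on the unitary-FFT scale)
#' @param amp_fh_mm,amp_lr_mm peak respiratory translation amplitudes (mm)
#' @param period_beats respiratory period in heartbeats
#' @param drift_frac fraction of the respiratory range drifting linearly
#'   over the scan (signal drift between start and end)
#' @param nonrigid_frac FH-graded non-rigid stretch coefficient (unitless;
#'   0 gives purely translational motion)
#' @param shear_frac AP-dependent FH shear coefficient
#' @param primitives optional list of primitives; each is a list with
#'   \code{type} ("ellipsoid"), \code{center} (mm), \code{semi_axes} (mm),
#'   \code{intensity} (complex), \code{edge_mm} (soft-edge width). The
#'   default set is a torso, heart, descending vessel and liver.
#' @return object of class \code{phantom_spec}
#' @export
phantom_spec <- function(shape = c(32, 32, 16), voxel_mm = 2,
                         n_coils = 4, noise_sd = 0,
                         amp_fh_mm = 6, amp_lr_mm = 2,
                         period_beats = 8, drift_frac = 0.1,
                         nonrigid_frac = 0.35, shear_frac = 0.15,
                         primitives = NULL) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3 && all(shape >= 4), "shape must be 3 dims >= 4")
  assert_that(n_coils >= 1, "need at least one coil")
  assert_that(amp_fh_mm >= 0 && amp_lr_mm >= 0, "amplitudes must be >= 0")
  fov <- shape * voxel_mm
  if (is.null(primitives)) {
    primitives <- list(
      list(type = "ellipsoid", center = c(0, 0, 0),
           semi_axes = fov * c(0.42, 0.42, 0.40),
           intensity = complex(real = 0.35, imaginary = 0.05), edge_mm = voxel_mm),
      list(type = "ellipsoid", center = fov * c(0.05, -0.04, 0.02),
           semi_axes = fov * c(0.16, 0.17, 0.22),
           intensity = complex(real = 0.65, imaginary = 0.08), edge_mm = voxel_mm),
      list(type = "ellipsoid", center = fov * c(0.05, 0.1, -0.15),
           semi_axes = fov * c(0.07, 0.06, 0.10),
           intensity = complex(real = 0.5, imaginary = -0.03), edge_mm = voxel_mm),
      list(type = "ellipsoid", center = fov * c(-0.18, 0.12, 0.05),
           semi_axes = fov * c(0.12, 0.2, 0.25),
           intensity = complex(real = 0.25, imaginary = 0.02), edge_mm = voxel_mm),
      list(type = "ellipsoid", center = fov * c(0.22, 0.05, 0.1),
           semi_axes = fov * c(0.05, 0.05, 0.16),
           intensity = complex(real = 0.45, imaginary = 0.05), edge_mm = voxel_mm)
    )
  }
  structure(list(shape = shape, voxel_mm = voxel_mm, n_coils = as.integer(n_coils),
                 noise_sd = noise_sd, amp_fh_mm = amp_fh_mm, amp_lr_mm = amp_lr_mm,
                 period_beats = period_beats, drift_frac = drift_frac,
                 nonrigid_frac = nonrigid_frac, shear_frac = shear_frac,
                 primitives = primitives),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d x %d x %d voxels (%.1f mm), %d coils, ",
                     "%d primitives\n  respiration: FH %.1f mm, LR %.1f mm, ",
                     "period %.1f beats, nonrigid %.2f, shear %.2f\n"),
              x$shape[1], x$shape[2], x$shape[3], x$voxel_mm, x$n_coils,
              length(x$primitives), x$amp_fh_mm, x$amp_lr_mm, x$period_beats,
              x$nonrigid_frac, x$shear_frac))
  invisible(x)
}

# mm coordinate of 0-based voxel index along one axis (volume-centred,
# matching the DC-centred k-space convention).
voxel_mm_coord <- function(n, voxel_mm) ((0:(n - 1)) - n %/% 2) * voxel_mm

# Material (reference-frame) coordinates of image-frame points at state s.
inverse_motion_map <- function(spec, px, py, pz, s) {
  Xh <- spec$shape[1] * spec$voxel_mm / 2
  Zh <- spec$shape[3] * spec$voxel_mm / 2
  A <- s * spec$amp_fh_mm
  x0 <- (px - A * (1 + spec$shear_frac * pz / Zh)) / (1 + A * spec$nonrigid_frac / Xh)
  y0 <- py - s * spec$amp_lr_mm
  list(x = x0, y = y0, z = pz)
}

# Forward displacement (mm) of material points at reference coords.
forward_motion_disp <- function(spec, x, y, z, s) {
  Xh <- spec$shape[1] * spec$voxel_mm / 2
  Zh <- spec$shape[3] * spec$voxel_mm / 2
  ux <- s * spec$amp_fh_mm * (1 + spec$nonrigid_frac * x / Xh + spec$shear_frac * z / Zh)
  uy <- rep(s * spec$amp_lr_mm, length.out = length(ux))
  list(ux = ux, uy = uy, uz = rep(0, length(ux)))
}

#' Render the phantom at a motion state
#'
#' Analytic rasterization of the primitives after the state's bulk
#' translation and smooth non-rigid deformation; soft (sigmoid) edges of
#' about one voxel keep the render band-limited. Deterministic.
#'
#' @param spec a \code{\link{phantom_spec}}
#' @param motion_state real in [0, 1]; 0 = end-expiration
#' @return complex array of dimension \code{spec$shape}
#' @export
render_phantom <- function(spec, motion_state = 0) {
  n <- spec$shape
  xs <- voxel_mm_coord(n[1], spec$voxel_mm)
  ys <- voxel_mm_coord(n[2], spec$voxel_mm)
  zs <- voxel_mm_coord(n[3], spec$voxel_mm)
  px <- array(rep(xs, times = n[2] * n[3]), dim = n)
  py <- array(rep(rep(ys, each = n[1]), times = n[3]), dim = n)
  pz <- array(rep(zs, each = n[1] * n[2]), dim = n)
  q <- inverse_motion_map(spec, px, py, pz, motion_state)
  vol <- array(complex(real = 0, imaginary = 0), dim = n)
  for (pr in spec$primitives) {
    d2 <- ((q$x - pr$center[1]) / pr$semi_axes[1])^2 +
          ((q$y - pr$center[2]) / pr$semi_axes[2])^2 +
          ((q$z - pr$center[3]) / pr$semi_axes[3])^2
    # signed distance proxy in mm from the unit-ellipsoid surface
    rmin <- min(pr$semi_axes)
    sd_mm <- (1 - sqrt(d2)) * rmin
    w <- 1 / (1 + exp(-4 * sd_mm / pr$edge_mm))
    vol <- vol + pr$intensity * w
  }
  vol
}

#' Smooth complex coil sensitivity maps
#'
#' Coils are modelled as Gaussian-profile magnitudes centred on points around
#' the torso surface with a low-order (constant + linear) phase. With
#' \code{normalize = TRUE} the maps are scaled so the root-sum-of-squares is
#' exactly 1 everywhere.
#'
#' @param shape volume dimensions
#' @param n_coils number of coils
#' @param normalize RSS-normalize (default TRUE)
#' @param uniform if TRUE (only with \code{n_coils = 1}) return a uniform map
#' @param seed integer seed for the phase offsets
#' @return complex array [shape, n_coils]
#' @export
simulate_coils <- function(shape, n_coils, normalize = TRUE, uniform = FALSE,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (uniform) {
    assert_that(n_coils == 1, "uniform option is single-coil")
    return(array(complex(real = 1), dim = c(shape, 1)))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- shape
  xs <- seq(-1, 1, length.out = n[1])
  ys <- seq(-1, 1, length.out = n[2])
  zs <- seq(-1, 1, length.out = n[3])
  px <- array(rep(xs, times = n[2] * n[3]), dim = n)
  py <- array(rep(rep(ys, each = n[1]), times = n[3]), dim = n)
  pz <- array(rep(zs, each = n[1] * n[2]), dim = n)
  S <- array(complex(real = 0), dim = c(n, n_coils))
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils + stats::runif(1, 0, pi)
  for (c in seq_len(n_coils)) {
    cy <- 1.2 * cos(ang[c]); cz <- 1.2 * sin(ang[c])
    cx <- stats::runif(1, -0.3, 0.3)
    mag <- 0.15 + exp(-(((px - cx) / 1.6)^2 + ((py - cy) / 1.2)^2 +
                        ((pz - cz) / 1.2)^2))
    ph <- stats::runif(1, -pi, pi) + 0.5 * (px * stats::runif(1, -1, 1) +
          py * stats::runif(1, -1, 1) + pz * stats::runif(1, -1, 1))
    S[, , , c] <- mag * exp(1i * ph)
  }
  if (normalize) {
    rss <- sqrt(apply(abs(S)^2, 1:3, sum))
    for (c in seq_len(n_coils)) S[, , , c] <- S[, , , c] / rss
  }
  S
}

#' Respiratory motion-state signal
#'
#' Sinusoid plus linear drift, sampled once per heartbeat, in [0, 1]
#' (0 = end-expiration).
#'
#' @param n_beats number of heartbeats
#' @param period_beats respiratory period in heartbeats
#' @param drift_frac linear drift fraction of the range
#' @param phase starting phase (radians)
#' @return numeric vector of motion states
#' @export
resp_signal <- function(n_beats, period_beats = 8, drift_frac = 0.1,
                        phase = 0) {
  m <- seq_len(n_beats) - 1
  raw <- 0.5 - 0.5 * cos(2 * pi * m / period_beats + phase)
  drift <- if (n_beats > 1) drift_frac * m / (n_beats - 1) else 0
  pmin(1, pmax(0, (1 - drift_frac) * raw + drift))
}

#' Simulate a 2D iNAV
#'
#' Coronal (AP-mean) projection of the volume magnitude, low-pass filtered to
#' about a quarter of the native resolution, then shifted by the heartbeat's
#' (FH, LR) translation via the Fourier shift theorem.
#'
#' @param volume complex or numeric 3D array
#' @param translation_mm length-2 (FH, LR) translation in mm
#' @param voxel_mm voxel size in mm
#' @return numeric matrix [nx, ny]
#' @export
simulate_inav <- function(volume, translation_mm = c(0, 0), voxel_mm = 1) {
  proj <- apply(abs(volume), c(1, 2), mean)
  n <- dim(proj)
  K <- ufft(proj + 0i)
  # quarter-resolution low-pass: keep the central quarter of k-space
  kx <- (0:(n[1] - 1)) - n[1] %/% 2
  ky <- (0:(n[2] - 1)) - n[2] %/% 2
  mask <- outer(abs(kx) <= n[1] / 8, abs(ky) <= n[2] / 8)
  K <- K * mask
  # Fourier shift: a shift by t voxels multiplies k by exp(-2pi i k t / n)
  tx <- translation_mm[1] / voxel_mm; ty <- translation_mm[2] / voxel_mm
  ph <- outer(kx * tx / n[1], ky * ty / n[2], `+`)
  K <- K * exp(-2i * pi * ph)
  Re(ufft_adj(K))
}

#' Simulate a heartbeat-resolved multi-coil acquisition
#'
#' For each heartbeat the phantom is rendered at that beat's motion state,
#' multiplied by the coil maps, transformed with the unitary 3D FFT and
#' sampled along the heartbeat's (ky, kz) readouts over all kx; circular
#' complex Gaussian noise is added. Simulated low-resolution 2D iNAVs and the
#' full ground truth (reference volume, per-beat translations, coil maps,
#' per-state fields) are also returned.
#'
#' @param spec a \code{\link{phantom_spec}}
#' @param traj a \code{\link{generate_caspr}} trajectory; its heartbeat count
#'   must match \code{length(resp)}
#' @param resp motion-state signal per heartbeat (defaults to
#'   \code{resp_signal} with the spec's period/drift)
#' @param seed integer seed for the noise and coils
#' @param coils optional pre-built coil maps [shape, n_coils] (e.g. a
#'   uniform single coil); simulated when NULL
#' @return list with elements \code{kdata} (class \code{kspace_data}) and
#'   \code{truth} (class \code{phantom_truth})
#' @export
simulate_acquisition <- function(spec, traj, resp = NULL, seed = 1L,
                                 coils = NULL) {
  n <- spec$shape
  assert_that(n[2] == traj$grid$n_ky && n[3] == traj$grid$n_kz,
              "trajectory phase-encode grid must match volume (ny, nz)")
  H <- traj$n_heartbeats
  if (is.null(resp)) resp <- resp_signal(H, spec$period_beats, spec$drift_frac)
  assert_that(length(resp) == H, "resp signal length must equal heartbeat count")
  if (is.null(coils)) {
    coils <- simulate_coils(n, spec$n_coils, seed = seed)
  } else {
    assert_that(all(dim(coils) == c(n, spec$n_coils)), "coil map shape mismatch")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)

  n_read <- nrow(traj$readouts)
  kspace <- array(complex(real = 0), dim = c(spec$n_coils, n_read, n[1]))
  inavs <- array(0, dim = c(H, n[1], n[2]))
  trans_mm <- matrix(0, H, 2)
  vol0 <- render_phantom(spec, 0)
  translational_only <- spec$nonrigid_frac == 0 && spec$shear_frac == 0
  for (m in seq_len(H)) {
    s <- resp[m]
    # for purely translational motion the discrete reference render is taken
    # as the (band-limited) object and moved by an exact sub-voxel Fourier
    # shift, so the k-space obeys the shift theorem exactly; non-rigid
    # states are re-rendered analytically
    vol <- if (translational_only) {
      fourier_shift(vol0, c(s * spec$amp_fh_mm, s * spec$amp_lr_mm) / spec$voxel_mm)
    } else {
      render_phantom(spec, s)
    }
    trans_mm[m, ] <- c(s * spec$amp_fh_mm, s * spec$amp_lr_mm)
    inavs[m, , ] <- simulate_inav(vol, c(0, 0), spec$voxel_mm)
    rows <- which(traj$heartbeat == m - 1L)
    if (length(rows) == 0) next
    for (c in seq_len(spec$n_coils)) {
      F <- ufft(vol * coils[, , , c])
      for (j in rows) {
        kspace[c, j, ] <- F[, traj$readouts[j, 1] + 1L, traj$readouts[j, 2] + 1L]
      }
    }
  }
  if (spec$noise_sd > 0) {
    nsd <- spec$noise_sd / sqrt(2)
    kspace <- kspace + complex(real = stats::rnorm(length(kspace), 0, nsd),
                               imaginary = stats::rnorm(length(kspace), 0, nsd))
  }
  kdata <- structure(list(kspace = kspace, traj = traj, inav = inavs,
                          resp_translations_mm = trans_mm,
                          voxel_mm = spec$voxel_mm, shape = n, coils = coils),
                     class = "kspace_data")
  truth <- structure(list(spec = spec, states = resp,
                          translations_mm = trans_mm, coils = coils,
                          reference = render_phantom(spec, 0)),
                     class = "phantom_truth")
  list(kdata = kdata, truth = truth)
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$kspace)
  cat(sprintf("<kspace_data> %d coils x %d readouts x %d kx samples, %d heartbeats\n",
              d[1], d[2], d[3], x$traj$n_heartbeats))
  invisible(x)
}

#' Ground-truth displacement fields between two motion states
#'
#' Returns the exact displacement fields, in voxel units on the volume grid,
#' for the phantom's analytic deformation between a reference state and a
#' target state: \code{d_ref2target} is the field that, used with
#' \code{\link{warp_volume}}, produces the target-state image from the
#' reference-state image (the role of M in the encoding operator), and
#' \code{d_target2ref} is its inverse.
#'
#' @param spec a \code{\link{phantom_spec}}
#' @param s_ref,s_target motion states in [0, 1]
#' @param tau_ref_mm,tau_target_mm optional residual (FH, LR) translations
#'   of the two images in mm: after k-space translational correction each
#'   bin image is shifted by minus its translation relative to the mean
#'   position, and the fields between such corrected images include these
#'   offsets
#' @return list of two [nx, ny, nz, 3] arrays in voxel units
#' @export
ground_truth_fields <- function(spec, s_ref, s_target,
                                tau_ref_mm = c(0, 0), tau_target_mm = c(0, 0)) {
  n <- spec$shape
  xs <- voxel_mm_coord(n[1], spec$voxel_mm)
  ys <- voxel_mm_coord(n[2], spec$voxel_mm)
  zs <- voxel_mm_coord(n[3], spec$voxel_mm)
  px <- array(rep(xs, times = n[2] * n[3]), dim = n)
  py <- array(rep(rep(ys, each = n[1]), times = n[3]), dim = n)
  pz <- array(rep(zs, each = n[1] * n[2]), dim = n)
  # composite map: image point p at target state corresponds to material
  # point q = phi_t^{-1}(p); its position at the reference state is
  # phi_r(q). d_ref2target(p) = phi_r(phi_t^{-1}(p)) - p (pullback field).
  comp_disp <- function(s_from, s_to, tau_from, tau_to) {
    q <- inverse_motion_map(spec, px + tau_to[1], py + tau_to[2], pz, s_to)
    u <- forward_motion_disp(spec, q$x, q$y, q$z, s_from)
    d <- array(0, dim = c(n, 3))
    d[, , , 1] <- (q$x + u$ux - tau_from[1] - px) / spec$voxel_mm
    d[, , , 2] <- (q$y + u$uy - tau_from[2] - py) / spec$voxel_mm
    d[, , , 3] <- (q$z + u$uz - pz) / spec$voxel_mm
    d
  }
  list(d_ref2target = comp_disp(s_ref, s_target, tau_ref_mm, tau_target_mm),
       d_target2ref = comp_disp(s_target, s_ref, tau_target_mm, tau_ref_mm))
}

#' Heart region of interest of a phantom
#'
#' Bounding cuboid (in voxels) of the phantom's heart primitive (the second
#' primitive of the default set) at the reference state, clipped to the
#' volume.
#'
#' @param spec a \code{\link{phantom_spec}}
#' @param which index of the primitive to bound (default 2, the heart)
#' @param margin_mm extra margin around the primitive (mm)
#' @return a \code{\link{roi_box}}
#' @export
heart_roi <- function(spec, which = 2, margin_mm = 2) {
  pr <- spec$primitives[[which]]
  n <- spec$shape
  lo <- pr$center - pr$semi_axes - margin_mm
  hi <- pr$center + pr$semi_axes + margin_mm
  to_idx <- function(mm, ax) mm / spec$voxel_mm + n[ax] %/% 2
  roi_box(max(0, floor(to_idx(lo[1], 1))), min(n[1], ceiling(to_idx(hi[1], 1))),
          max(0, floor(to_idx(lo[2], 2))), min(n[2], ceiling(to_idx(hi[2], 2))),
          max(0, floor(to_idx(lo[3], 3))), min(n[3], ceiling(to_idx(hi[3], 3))))
}
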