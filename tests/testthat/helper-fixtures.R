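# Shared fixtures, built in code at test time.

# Fully sampled rectangular trajectory (bypasses the shutter; used for
# round-trip and operator tests where every grid point must be acquired).
full_rect_traj <- function(n_ky, n_kz, n_beats = 1L) {
  g <- grid_spec(n_ky, n_kz)
  ky <- rep(0:(n_ky - 1), times = n_kz)
  kz <- rep(0:(n_kz - 1), each = n_ky)
  n <- n_ky * n_kz
  beat <- (seq_len(n) - 1L) %% n_beats
  structure(list(grid = g, readouts = cbind(ky = ky, kz = kz),
                 heartbeat = beat, interleaf = beat,
                 shutter = matrix(TRUE, n_ky, n_kz),
                 nominal_accel = 1, n_heartbeats = as.integer(n_beats)),
            class = "caspr_trajectory")
}

# Small static multi-coil acquisition with full sampling and no noise.
static_full_acq <- function(shape = c(16, 16, 8), n_coils = 3, seed = 2L,
                            uniform = FALSE) {
  spec <- phantom_spec(shape = shape, n_coils = n_coils, amp_fh_mm = 0,
                       amp_lr_mm = 0, noise_sd = 0)
  traj <- full_rect_traj(shape[2], shape[3])
  coils <- if (uniform) simulate_coils(shape, 1, uniform = TRUE) else NULL
  acq <- simulate_acquisition(spec, traj, resp = 0, seed = seed, coils = coils)
  list(spec = spec, traj = traj, acq = acq)
}

# Smooth random velocity field (Gaussian-like smoothing by repeated
# box-averaging), peak magnitude about max_mag voxels.
smooth_velocity <- function(shape, max_mag = 3, seed = 1L, n_smooth = 4) {
  set.seed(seed)
  v <- array(rnorm(prod(shape) * 3), dim = c(shape, 3))
  box <- function(a) {
    d <- dim(a)
    for (ax in 1:3) {
      n <- d[ax]
      a <- (a + mocomodl:::slice_index(a, ax, c(1, 1:(n - 1))) +
              mocomodl:::slice_index(a, ax, c(2:n, n))) / 3
    }
    a
  }
  for (i in seq_len(n_smooth)) v <- box(v)
  v * (max_mag / max(abs(v)))
}

rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / max(sum(Mod(b)^2), .Machine$double.eps))
}
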