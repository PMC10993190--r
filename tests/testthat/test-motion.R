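test_that("iNAV registration recovers known translations and re-references", {
  # identical iNAVs: all translations zero
  spec <- phantom_spec(shape = c(32, 32, 16), voxel_mm = 2)
  i0 <- simulate_inav(render_phantom(spec, 0), c(0, 0), 2)
  stack <- array(0, dim = c(3, 32, 32))
  for (m in 1:3) stack[m, , ] <- i0
  tr <- register_inavs(stack, voxel_mm = 2)
  expect_equal(max(abs(tr$t_mm)), 0, tolerance = 1e-8)
  # simulated 3 mm FH shifts recovered within 0.5 mm
  shifts <- c(0, 3, 1.5, -1.5)
  stack2 <- array(0, dim = c(4, 32, 32))
  for (m in 1:4) stack2[m, , ] <- simulate_inav(render_phantom(spec, 0),
                                                c(shifts[m], 0), 2)
  tr2 <- register_inavs(stack2, voxel_mm = 2)
  expect_lt(max(abs(tr2$t_mm[, 1] - (shifts - mean(shifts)))), 0.5)
  # output re-referenced to zero mean
  expect_equal(colMeans(tr2$t_mm), c(0, 0), tolerance = 1e-10)
  # flat iNAVs fail explicitly
  expect_error(register_inavs(array(1, dim = c(2, 8, 8))), "flat")
})

test_that("phase-shift correction is unit-modulus and undoes pure translation", {
  shape <- c(16, 16, 8)
  spec <- phantom_spec(shape = shape, n_coils = 1, amp_fh_mm = 3,
                       amp_lr_mm = 1.5, nonrigid_frac = 0, shear_frac = 0,
                       noise_sd = 0)
  traj <- full_rect_traj(16, 8, n_beats = 8)
  U <- simulate_coils(shape, 1, uniform = TRUE)
  states <- rep(c(0, 1), 4)
  acq <- simulate_acquisition(spec, traj, resp = states, seed = 1, coils = U)
  t_mm <- sweep(acq$truth$translations_mm, 2,
                colMeans(acq$truth$translations_mm))
  kc <- phase_correct(acq$kdata, t_mm)
  # magnitudes preserved exactly
  expect_equal(Mod(kc$kspace), Mod(acq$kdata$kspace), tolerance = 1e-12)
  # zero translations: bitwise identity
  k0 <- phase_correct(acq$kdata, t_mm * 0)
  expect_identical(k0$kspace, acq$kdata$kspace)
  # corrected recon matches the mean-position phantom
  op <- encoding_op(traj, U)
  rec <- apply_E_adjoint(list(kc$kspace), op)
  ref <- mocomodl:::fourier_shift(render_phantom(spec, 0),
                                  colMeans(acq$truth$translations_mm) /
                                    spec$voxel_mm)
  expect_lt(rel_err(rec, ref), 1e-3)
})

test_that("soft-gated binning splits heartbeats into equal primary groups", {
  set.seed(3)
  fh <- rnorm(100)
  tm <- cbind(fh, rnorm(100))
  b <- bin_heartbeats(tm, 4, softness = 0.5)
  expect_equal(unname(tabulate(b$primary, 4)), c(25, 25, 25, 25))
  expect_true(all(b$W >= 0 & b$W <= 1))
  expect_true(all(apply(b$W, 1, max) == 1))
  # counts differ by at most one for any heartbeat count
  for (H in c(10, 11, 13)) {
    bb <- bin_heartbeats(cbind(rnorm(H), 0), 4, 0.5)
    expect_lte(diff(range(tabulate(bb$primary, 4))), 1)
  }
  # hard-gating limit: softness 0 gives one-hot rows
  bh <- bin_heartbeats(tm, 4, softness = 0)
  expect_equal(rowSums(bh$W), rep(1, 100))
  # default bin count is 4
  expect_equal(formals(bin_heartbeats)$n_bins, 4)
  # end-expiration bin has the minimal FH centre under the "min" convention
  expect_equal(b$end_exp_bin, which.min(b$bin_centers))
  # fewer heartbeats than bins errors
  expect_error(bin_heartbeats(cbind(rnorm(3), 0), 4), "fewer")
})

test_that("scaling-and-squaring integration is diffeomorphic and invertible", {
  n <- c(16, 16, 8)
  # zero velocity: identity
  f0 <- integrate_velocity(array(0, dim = c(n, 3)), 6)
  expect_equal(max(abs(f0$forward)), 0)
  # constant velocity: exact translation flow in the interior
  v <- array(0, dim = c(n, 3)); v[, , , 1] <- 1.5
  f <- integrate_velocity(v, 6)
  expect_equal(f$forward[8, 8, 4, 1], 1.5, tolerance = 1e-9)
  expect_equal(f$inverse[8, 8, 4, 1], -1.5, tolerance = 1e-9)
  # smooth random field: inverse consistency and positive Jacobian
  v2 <- smooth_velocity(n, max_mag = 3, seed = 5)
  f2 <- integrate_velocity(v2, 6)
  comp <- f2$forward + array(
    mocomodl:::warp_fwd_cpp(as.vector(f2$inverse), as.vector(f2$forward),
                            as.integer(c(n, 3))), dim = c(n, 3))
  expect_lt(mean(sqrt(apply(comp^2, 1:3, sum))), 0.1)
  detJ <- local({
    phi <- f2$forward
    phi[, , , 1] <- phi[, , , 1] + array(rep(0:(n[1] - 1), prod(n[2:3])), dim = n)
    phi[, , , 2] <- phi[, , , 2] +
      array(rep(rep(0:(n[2] - 1), each = n[1]), n[3]), dim = n)
    phi[, , , 3] <- phi[, , , 3] + array(rep(0:(n[3] - 1), each = n[1] * n[2]), dim = n)
    J <- array(0, dim = c(n, 3, 3))
    for (a in 1:3) for (bb in 1:3) {
      hi <- mocomodl:::slice_index(phi[, , , a, drop = FALSE], bb, c(2:n[bb], n[bb]))
      lo <- mocomodl:::slice_index(phi[, , , a, drop = FALSE], bb, c(1, 1:(n[bb] - 1)))
      J[, , , a, bb] <- (hi - lo) / 2
    }
    J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 2]) -
    J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 1]) +
    J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] - J[, , , 2, 2] * J[, , , 3, 1])
  })
  expect_gt(min(detJ[3:14, 3:14, 3:6]), 0)
  # non-finite velocities rejected
  vbad <- v; vbad[1] <- NaN
  expect_error(integrate_velocity(vbad), "finite")
})

test_that("warping is exact for identity and integer shifts and invertible", {
  n <- c(12, 10, 8)
  set.seed(2)
  vol <- array(rnorm(prod(n)), dim = n)
  id <- array(0, dim = c(n, 3))
  expect_equal(warp_volume(vol, id), vol)
  # integer shift along x equals an index shift in the interior
  d <- id; d[, , , 1] <- 2
  w <- warp_volume(vol, d)
  expect_equal(w[1:10, , ], vol[3:12, , ])
  # forward/inverse round trip on a smooth phantom
  spec <- phantom_spec(shape = c(16, 16, 8))
  ph <- Re(render_phantom(spec, 0))
  v2 <- smooth_velocity(c(16, 16, 8), max_mag = 2, seed = 7)
  f <- integrate_velocity(v2, 6)
  back <- warp_volume(warp_volume(ph, f$forward), f$inverse)
  expect_lt(mean(abs(back - ph)) / diff(range(ph)), 0.02)
  # complex volumes warp channel-wise
  vc <- ph + 1i * ph / 2
  wc <- warp_volume(vc, f$forward)
  expect_equal(Re(wc), warp_volume(Re(vc), f$forward))
  expect_equal(Im(wc), warp_volume(Im(vc), f$forward))
})

test_that("warp_adjoint is the exact transpose of warp_volume", {
  n <- c(10, 9, 7)
  f <- integrate_velocity(smooth_velocity(n, 2, seed = 3), 5)
  # identity displacement: output equals input
  x1 <- array(rnorm(prod(n)), dim = n)
  expect_equal(warp_adjoint(x1, array(0, dim = c(n, 3))), x1)
  # inner-product identity on 10 random pairs
  set.seed(11)
  for (t in 1:10) {
    x <- array(complex(real = rnorm(prod(n)), imaginary = rnorm(prod(n))), dim = n)
    y <- array(complex(real = rnorm(prod(n)), imaginary = rnorm(prod(n))), dim = n)
    lhs <- sum(Conj(warp_volume(x, f$forward)) * y)
    rhs <- sum(Conj(x) * warp_adjoint(y, f$forward))
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-8)
  }
  # the implied matrix transpose on a small grid: column sums of the warp
  # matrix equal the interpolation weight sums obtained by splatting ones
  n2 <- c(4, 4, 3)
  f2 <- integrate_velocity(smooth_velocity(n2, 0.8, seed = 4), 4)
  N <- prod(n2)
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    e <- array(0, dim = n2); e[i] <- 1
    A[, i] <- as.vector(warp_volume(e, f2$forward))
  }
  ones <- array(1, dim = n2)
  expect_equal(as.vector(warp_adjoint(ones, f2$forward)), colSums(A),
               tolerance = 1e-12)
})
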