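test_that("patch plans cover the axis and recombine exactly", {
  # full-scale defaults
  cfg <- recon_config()
  expect_equal(cfg$edge_discard, 5)
  expect_equal(cfg$overlap, 4)
  expect_equal(cfg$n_modl_iter, 5)
  expect_equal(cfg$n_cg, 3)
  expect_equal(cfg$n_sense, 10)
  expect_equal(cfg$n_bins, 4)
  plan <- plan_patches(272, 48, 5, 4)
  expect_true(all(plan$coverage >= 1))
  # retained regions overlap by the configured amount (the final patch,
  # pinned to the volume edge, may overlap more)
  r <- do.call(rbind, plan$retained)
  ovl <- r[-nrow(r), 2] - r[-1, 1]
  expect_true(all(ovl >= 4))
  expect_true(all(ovl[-length(ovl)] == 4))
  # single patch: no discard at outer borders
  p1 <- plan_patches(32, 32, 5, 4)
  expect_equal(length(p1$starts), 1L)
  expect_equal(p1$retained[[1]], c(0, 32))
  # recombining a split constant volume is exact
  const <- array(1 + 2i, dim = c(29, 6, 4))
  plan2 <- plan_patches(29, 12, 2, 3)
  patches <- lapply(plan2$starts, function(s) const[(s + 1):(s + 12), , ])
  expect_identical(recombine_patches(patches, plan2), const)
  # recombination weights sum to one everywhere (partition of unity)
  expect_true(all(abs(recombine_patches(
    lapply(plan2$starts, function(s) array(1 + 0i, dim = c(12, 6, 4))),
    plan2) - 1) < 1e-15))
  # patching a volume produced by a patch-independent (x-diagonal) operator
  # recombines to machine precision
  set.seed(1)
  vol <- array(complex(real = rnorm(29 * 6 * 4), imaginary = rnorm(29 * 6 * 4)),
               dim = c(29, 6, 4))
  patches3 <- lapply(plan2$starts, function(s) vol[(s + 1):(s + 12), , ])
  expect_equal(recombine_patches(patches3, plan2), vol, tolerance = 1e-15)
  # infeasible geometry errors
  expect_error(plan_patches(20, 10, 4, 4), "stride")
})

test_that("hybrid-space patching is consistent with the full k-space", {
  set.seed(2)
  k <- array(complex(real = rnorm(2 * 5 * 16), imaginary = rnorm(2 * 5 * 16)),
             dim = c(2, 5, 16))
  h <- mocomodl:::kspace_to_hybrid(k)
  # full-extent patch returns the original k-space
  k2 <- mocomodl:::hybrid_to_patch_kspace(h, 0, 16)
  expect_equal(k2, k, tolerance = 1e-12)
})

test_that("with no motion and identity denoiser the pipeline equals iterative SENSE", {
  shape <- c(16, 16, 8)
  spec <- phantom_spec(shape = shape, n_coils = 2, amp_fh_mm = 0,
                       amp_lr_mm = 0, noise_sd = 0)
  g <- grid_spec(16, 8)
  traj <- generate_caspr(g, 3, 8, rng_seed = 5)
  acq <- simulate_acquisition(spec, traj, resp = rep(0, 8), seed = 3)
  tm <- cbind(rep(0, 8), rep(0, 8))
  # single bin, single patch, one DC block of 10 CG iterations, no nets
  cfg <- recon_config(n_modl_iter = 1, n_cg = 10, n_bins = 1, patch_x = 16,
                      use_motion = FALSE)
  rec <- reconstruct_mocomodl(acq$kdata, acq$truth$coils, cfg,
                              translations = tm)
  bins <- bin_heartbeats(tm, 1)
  sr <- sense_recon(phase_correct(acq$kdata, tm), bins, 1, acq$truth$coils,
                    n_iter = 10)
  expect_lt(rel_err(rec$volume, sr$x), 1e-6)
})

test_that("the unrolled iteration runs the configured DC and denoiser counts", {
  shape <- c(16, 16, 8)
  spec <- phantom_spec(shape = shape, n_coils = 2, amp_fh_mm = 4,
                       amp_lr_mm = 1, noise_sd = 0.005)
  g <- grid_spec(16, 8)
  traj <- generate_caspr(g, 3, 12, rng_seed = 6)
  acq <- simulate_acquisition(spec, traj, seed = 4)
  mn <- dirrespme_net(ch = c(4, 8), seed = 1)
  dn <- denoiser_net(ch = c(4, 8), seed = 2)
  cfg <- recon_config(n_bins = 4, patch_x = 16, softness = 0.5)
  rec <- reconstruct_mocomodl(acq$kdata, acq$truth$coils, cfg,
                              motion_net = mn, denoiser = dn)
  # 5 DC solves and 4 denoiser passes per patch (single patch here)
  expect_equal(rec$ledger$n_dc, 5L)
  expect_equal(rec$ledger$n_denoise, 4L)
  expect_equal(length(rec$ledger$cg_reports), 5L)
  # data-consistency residual never increases across a DC step
  for (d in rec$ledger$dc_residuals) expect_lte(d["after"], d["before"] + 1e-10)
  # deterministic given data and weights
  rec2 <- reconstruct_mocomodl(acq$kdata, acq$truth$coils, cfg,
                               motion_net = mn, denoiser = dn)
  expect_identical(rec$volume, rec2$volume)
})

test_that("motion-corrected DC with ground-truth fields beats no correction", {
  shape <- c(24, 24, 16)
  spec <- phantom_spec(shape = shape, voxel_mm = 2, n_coils = 2,
                       amp_fh_mm = 6, amp_lr_mm = 2, nonrigid_frac = 0.5,
                       shear_frac = 0.2, noise_sd = 0.005)
  g <- grid_spec(24, 16)
  traj <- generate_caspr(g, 4, 20, rng_seed = 7)
  resp <- resp_signal(20, 8, 0.1)
  acq <- simulate_acquisition(spec, traj, resp = resp, seed = 5)
  tmm <- sweep(acq$truth$translations_mm, 2,
               colMeans(acq$truth$translations_mm))
  bins <- bin_heartbeats(tmm, 4)
  # analytic ground-truth fields per bin (corrected frame)
  t_bar <- colMeans(acq$truth$translations_mm)
  tau <- function(s) c(s * spec$amp_fh_mm, s * spec$amp_lr_mm) - t_bar
  s_ref <- mean(resp[bins$primary == bins$end_exp_bin])
  motion <- lapply(seq_len(4), function(b) {
    if (b == bins$end_exp_bin) return(NULL)
    s_b <- mean(resp[bins$primary == b])
    f <- ground_truth_fields(spec, s_ref, s_b, tau(s_ref), tau(s_b))
    list(d_ref2bin = f$d_ref2target, d_bin2ref = f$d_target2ref)
  })
  cfg <- recon_config(n_bins = 4, patch_x = 24)
  rec_mc <- reconstruct_mocomodl(acq$kdata, acq$truth$coils, cfg,
                                 translations = tmm, motion_override = motion)
  cfg0 <- recon_config(n_bins = 4, patch_x = 24, use_motion = FALSE)
  rec_0 <- reconstruct_mocomodl(acq$kdata, acq$truth$coils, cfg0,
                                translations = tmm)
  ref <- mocomodl:::fourier_shift(render_phantom(spec, s_ref),
                                  -tau(s_ref) / spec$voxel_mm)
  roi <- heart_roi(spec)
  m_mc <- roi_metrics(rec_mc$volume, ref, roi)
  m_0 <- roi_metrics(rec_0$volume, ref, roi)
  expect_gt(m_mc$ssim, m_0$ssim)
})
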