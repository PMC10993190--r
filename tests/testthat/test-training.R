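make_tiny_sample <- function(seed = 1L, shape = c(16, 16, 8), beats = 12) {
  spec <- phantom_spec(shape = shape, n_coils = 2, amp_fh_mm = 4,
                       amp_lr_mm = 1, nonrigid_frac = 0.4, shear_frac = 0.2,
                       noise_sd = 0.005)
  g <- grid_spec(shape[2], shape[3])
  traj <- generate_caspr(g, 2, beats, rng_seed = seed)
  acq <- simulate_acquisition(spec, traj,
                              resp = resp_signal(beats, 6, 0.1), seed = seed)
  prof <- mean_annulus_profile(lapply(1:3, function(i)
    measure_annulus_profile(generate_caspr(g, 4, beats,
                                           rng_seed = 50 + i), 8)))
  make_training_sample(acq, prof, n_bins = 4, n_sense = 5,
                       seed = seed + 10L, clip = TRUE)
}

test_that("training configuration carries the published defaults", {
  cfg <- train_config()
  expect_equal(c(cfg$lambda1, cfg$lambda2, cfg$lambda3), c(100, 10, 1))
  expect_equal(cfg$epochs, 1600L)
  expect_equal(cfg$lr, 3e-4)
  expect_equal(cfg$lr_halve_every, 400L)
  expect_equal(cfg$patch_x, 48L)
  # LR schedule: epoch 401 runs at half the initial rate
  lr_at <- function(ep) cfg$lr * 0.5^((ep - 1) %/% cfg$lr_halve_every)
  expect_equal(lr_at(401), cfg$lr / 2)
  expect_equal(lr_at(1), cfg$lr)
})

test_that("the Charbonnier penalty has the documented limits", {
  # -> |x| as eps -> 0
  x <- c(-2, -0.5, 0.3, 1.7)
  expect_equal(charbonnier(x, 1e-12), mean(abs(x)), tolerance = 1e-9)
  # -> x^2 / (2 eps) for |x| << eps
  eps <- 0.1
  xs <- 1e-4
  expect_equal(charbonnier(xs, eps), xs^2 / (2 * eps), tolerance = 1e-4)
})

test_that("training samples are subsets with ground-truth-aligned references", {
  smp <- make_tiny_sample(2)
  src <- smp$truth  # original acquisition truth
  # every retained readout exists in the source trajectory
  expect_true(!is.null(attr(smp$kdata$traj, "kept_rows")))
  expect_lt(nrow(smp$kdata$traj$readouts), 200)
  # same seed reproduces the sample exactly
  smp2 <- make_tiny_sample(2)
  expect_identical(smp$kdata$kspace, smp2$kdata$kspace)
  expect_identical(smp$ref_bins, smp2$ref_bins)
  # references: 4 complex bin volumes on the acquisition grid
  expect_length(smp$ref_bins, 4)
  expect_true(all(vapply(smp$ref_bins, function(v)
    all(dim(v) == smp$kdata$shape), TRUE)))
})

test_that("the composite loss reduces to its parts in degenerate settings", {
  smp <- make_tiny_sample(3)
  cfg <- train_config(epochs = 1)
  ref_bin <- smp$bins$end_exp_bin
  params <- list(unet_init(2, 2, ch = c(2, 4), seed = 1))
  # perfect recon + identity fields on identical bins + zero data weights
  # leaves only the kernel regularization
  same_bins <- rep(list(smp$ref_bins[[ref_bin]]), 4)
  cfg0 <- train_config(lambda1 = 0, lambda2 = 0, lambda3 = 1)
  l <- total_loss(smp$ref_bins[[ref_bin]], same_bins, ref_bin,
                  vector("list", 4), params, cfg0)
  w_norm <- sum(vapply(names(params[[1]])[endsWith(names(params[[1]]), "_w")],
                       function(k) sum(params[[1]][[k]]^2), 0))
  expect_equal(l$total, w_norm)
  expect_equal(l$L_mot, 0)
  expect_equal(l$L_recon, 0)
  # default weights are (100, 10, 1)
  l2 <- total_loss(smp$ref_bins[[ref_bin]], same_bins, ref_bin,
                   vector("list", 4), params, train_config())
  expect_equal(l2$total, 100 * l2$L_mot + 10 * l2$L_recon + 1 * l2$L_reg)
})

test_that("backpropagated end-to-end gradients match finite differences", {
  smp <- make_tiny_sample(4)
  mn <- dirrespme_net(ch = c(2, 4), seed = 5)
  dn <- denoiser_net(ch = c(2, 4), seed = 6)
  # small nonzero heads so all paths carry gradient
  mn$params$out_w[] <- rnorm(length(mn$params$out_w), 0, 0.01)
  dn$params$out_w[] <- rnorm(length(dn$params$out_w), 0, 0.01)
  cfg <- train_config(epochs = 1, patch_x = 16, n_modl_iter = 2, n_cg = 2)
  res <- loss_and_gradients(smp, mn, dn, cfg, 0L)
  fd <- function(which, name, i, h = 1e-4) {
    mp <- mn; dp <- dn
    if (which == "m") mp$params[[name]][i] <- mp$params[[name]][i] + h
    else dp$params[[name]][i] <- dp$params[[name]][i] + h
    lp <- loss_and_gradients(smp, mp, dp, cfg, 0L)$total
    if (which == "m") mp$params[[name]][i] <- mp$params[[name]][i] - 2 * h
    else dp$params[[name]][i] <- dp$params[[name]][i] - 2 * h
    lm <- loss_and_gradients(smp, mp, dp, cfg, 0L)$total
    (lp - lm) / (2 * h)
  }
  checks <- list(c("m", "enc1_w", 7), c("m", "out_w", 11),
                 c("d", "enc1_w", 3), c("d", "out_w", 5))
  for (ck in checks) {
    num <- fd(ck[1], ck[2], as.integer(ck[3]))
    an <- if (ck[1] == "m") res$grad_motion[[ck[2]]][as.integer(ck[3])]
          else res$grad_denoiser[[ck[2]]][as.integer(ck[3])]
    expect_lt(abs(num - an) / max(abs(num), 1e-6), 1e-3)
  }
})

test_that("a short seeded training run decreases the loss reproducibly", {
  samples <- lapply(1:2, make_tiny_sample)
  mn <- dirrespme_net(ch = c(2, 4), seed = 7)
  dn <- denoiser_net(ch = c(2, 4), seed = 8)
  cfg <- train_config(epochs = 6, lr = 2e-3, lr_halve_every = 4,
                      patch_x = 16, n_modl_iter = 2, n_cg = 2, seed = 3)
  fit <- train_mocomodl(samples, mn, dn, cfg)
  expect_false(fit$aborted)
  h <- fit$history
  expect_equal(nrow(h), 12)
  expect_lt(mean(h$total[h$epoch == 6]), mean(h$total[h$epoch == 1]))
  # the learning-rate halving is applied
  expect_equal(unique(h$lr[h$epoch == 5]), cfg$lr / 2)
  # bit-reproducible under the same seed
  fit2 <- train_mocomodl(samples, dirrespme_net(ch = c(2, 4), seed = 7),
                         denoiser_net(ch = c(2, 4), seed = 8), cfg)
  expect_equal(fit$history$total, fit2$history$total, tolerance = 1e-12)
})
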