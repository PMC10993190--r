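# End-to-end training: retrospective k-space subsetting into training
# samples, the composite loss L = lambda1 L_mot + lambda2 L_recon +
# lambda3 L_reg, and the optimization loop differentiating through the
# unrolled CG data-consistency solves and the scaling-and-squaring layers.

#' Training configuration
#'
#' Full-scale defaults: loss weights (100, 10, 1), 1600 epochs, initial
#' learning rate 3e-4 halved every 400 epochs, 48-voxel readout-direction
#' patches. Scaled-down phantom runs shrink epochs/patches, not the loss
#' weights.
#'
#' @param lambda1,lambda2,lambda3 weights of the motion, reconstruction and
#'   kernel-regularization losses
#' @param epochs training epochs (one step per sample per epoch)
#' @param lr initial learning rate
#' @param lr_halve_every halve the learning rate every this many epochs
#' @param charbonnier_eps Charbonnier smoothing epsilon (on unit-normalized
#'   images)
#' @param smooth_weight weight of the velocity smoothness penalty inside the
#'   motion loss
#' @param patch_x training patch size along x
#' @param n_modl_iter,n_cg unrolled iteration counts (defaults 5 and 3)
#' @param seed integer seed
#' @return list of class \code{train_config}
#' @export
train_config <- function(lambda1 = 100, lambda2 = 10, lambda3 = 1,
                         epochs = 1600, lr = 3e-4, lr_halve_every = 400,
                         charbonnier_eps = 1e-3, smooth_weight = 0.01,
                         patch_x = 48, n_modl_iter = 5, n_cg = 3,
                         seed = 1L) {
  assert_that(all(c(lambda1, lambda2, lambda3) >= 0), "loss weights must be >= 0")
  assert_that(epochs >= 1, "epochs must be >= 1")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 epochs = as.integer(epochs), lr = lr,
                 lr_halve_every = as.integer(lr_halve_every),
                 charbonnier_eps = charbonnier_eps,
                 smooth_weight = smooth_weight, patch_x = as.integer(patch_x),
                 n_modl_iter = as.integer(n_modl_iter),
                 n_cg = as.integer(n_cg), seed = as.integer(seed)),
            class = "train_config")
}

#' Charbonnier (smooth absolute-error) penalty
#'
#' \code{mean(sqrt(x^2 + eps^2) - eps)}: tends to \code{mean(|x|)} as
#' \code{eps -> 0} and to \code{x^2 / (2 eps)} for \code{|x| << eps}.
#'
#' @param x numeric or complex array (complex values contribute their real
#'   and imaginary parts as separate channels)
#' @param eps smoothing epsilon
#' @return scalar
#' @export
charbonnier <- function(x, eps = 1e-3) {
  if (is.complex(x)) x <- c(Re(x), Im(x))
  mean(sqrt(x^2 + eps^2) - eps)
}

# Fourier sub-voxel shift of a complex volume (x, y axes).
fourier_shift <- function(vol, shift_vox) {
  n <- dim(vol)
  K <- ufft(vol)
  kx <- (0:(n[1] - 1)) - n[1] %/% 2
  ky <- (0:(n[2] - 1)) - n[2] %/% 2
  phx <- exp(-2i * pi * kx * shift_vox[1] / n[1])
  phy <- exp(-2i * pi * ky * shift_vox[2] / n[2])
  K <- K * array(outer(phx, phy), dim = n)
  ufft_adj(K)
}

#' Build a training sample by retrospective undersampling
#'
#' Applies the density-preserving annulus subsetting to a low-acceleration
#' acquisition, registers its iNAVs, bins heartbeats, and constructs
#' reference bin images from the phantom ground truth: each bin's reference
#' is the phantom rendered at the bin's mean motion state, translationally
#' aligned to the mean respiratory position (the frame of the
#' phase-corrected data). Per-bin SENSE images for motion-estimation input
#' are precomputed from the subset data.
#'
#' @param acq result of \code{\link{simulate_acquisition}}
#' @param target_profile an \code{annulus_profile} measured from a
#'   higher-acceleration (e.g. seven-fold) trajectory
#' @param n_bins,softness binning parameters
#' @param n_sense SENSE iterations for the motion-input images
#' @param seed integer seed for the readout subsetting
#' @param clip passed to \code{\link{retrospective_undersample}}
#' @return object of class \code{training_sample}
#' @export
make_training_sample <- function(acq, target_profile, n_bins = 4,
                                 softness = 0.5, n_sense = 10, seed = 1L,
                                 clip = FALSE) {
  kdata <- acq$kdata; truth <- acq$truth
  traj_sub <- retrospective_undersample(kdata$traj, target_profile, seed,
                                        clip = clip)
  kept <- attr(traj_sub, "kept_rows")
  ks <- kdata
  ks$kspace <- kdata$kspace[, kept, , drop = FALSE]
  ks$traj <- traj_sub
  translations <- register_inavs(kdata$inav, voxel_mm = kdata$voxel_mm)
  bins <- bin_heartbeats(translations, n_bins, softness)
  spec <- truth$spec
  t_bar <- colMeans(truth$translations_mm)
  ref_bins <- vector("list", n_bins)
  bin_states <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    s_b <- mean(truth$states[bins$primary == b])
    bin_states[b] <- s_b
    vol <- render_phantom(spec, s_b)
    shift_mm <- c(s_b * spec$amp_fh_mm, s_b * spec$amp_lr_mm) - t_bar
    ref_bins[[b]] <- fourier_shift(vol, -shift_mm / spec$voxel_mm)
  }
  kc <- phase_correct(ks, translations)
  sense_mag <- lapply(seq_len(n_bins), function(b)
    abs(sense_recon(kc, bins, b, truth$coils, n_iter = n_sense)$x))
  structure(list(kdata = ks, kdata_corrected = kc,
                 hybrid = kspace_to_hybrid(kc$kspace),
                 translations = translations, bins = bins,
                 ref_bins = ref_bins, bin_states = bin_states,
                 sense_mag = sense_mag, coils = truth$coils,
                 truth = truth, seed = as.integer(seed)),
            class = "training_sample")
}

#' @export
print.training_sample <- function(x, ...) {
  cat(sprintf("<training_sample> %d readouts (subset), %d bins, volume %s\n",
              nrow(x$kdata$traj$readouts), x$bins$n_bins,
              paste(x$kdata$shape, collapse = "x")))
  invisible(x)
}

#' Composite training loss (plain evaluation)
#'
#' \code{L = lambda1 L_mot + lambda2 L_recon + lambda3 L_reg} where L_mot is
#' the Charbonnier distance between the end-expiration reference and each
#' remaining reference bin warped to end-expiration, plus a squared-gradient
#' smoothness penalty on the velocity fields; L_recon the Charbonnier
#' distance between reference and reconstruction; L_reg the squared l2 norm
#' of all convolution kernel weights.
#'
#' @param recon reconstructed complex volume
#' @param ref_bins list of reference bin volumes
#' @param end_exp_bin index of the end-expiration bin
#' @param fields per-bin motion fields (NULL for the reference bin), each a
#'   list with \code{d_bin2ref} and \code{velocity}
#' @param param_sets list of parameter lists (both networks)
#' @param cfg a \code{\link{train_config}}
#' @return list with \code{total}, \code{L_mot}, \code{L_recon}, \code{L_reg}
#' @export
total_loss <- function(recon, ref_bins, end_exp_bin, fields, param_sets,
                       cfg = train_config()) {
  ref <- ref_bins[[end_exp_bin]]
  L_mot <- 0
  for (b in seq_along(ref_bins)) {
    if (b == end_exp_bin) next
    f <- fields[[b]]
    warped <- if (is.null(f)) ref_bins[[b]] else
      warp_volume(ref_bins[[b]], f$d_bin2ref)
    L_mot <- L_mot + charbonnier(ref - warped, cfg$charbonnier_eps)
    if (!is.null(f) && !is.null(f$velocity)) {
      L_mot <- L_mot + cfg$smooth_weight * gradsq_penalty(f$velocity)
    }
  }
  L_recon <- charbonnier(ref - recon, cfg$charbonnier_eps)
  L_reg <- sum(vapply(param_sets, function(ps) {
    sum(vapply(names(ps)[endsWith(names(ps), "_w")],
               function(k) sum(ps[[k]]^2), 0))
  }, 0))
  total <- cfg$lambda1 * L_mot + cfg$lambda2 * L_recon + cfg$lambda3 * L_reg
  assert_that(is.finite(total), "non-finite loss")
  list(total = total, L_mot = L_mot, L_recon = L_recon, L_reg = L_reg)
}

gradsq_penalty <- function(v) {
  d <- dim(v)
  val <- 0
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) next
    val <- val + sum((slice_index(v, ax, 2:n) - slice_index(v, ax, 1:(n - 1)))^2)
  }
  val / length(v)
}

# --- tape-side encoding pieces --------------------------------------------

# Per-bin squared-weight k-plane masks (UtU diagonal, duplicates summed),
# replicated over kx and both channels.
bin_k_masks <- function(traj, bins, npx, weight_thresh = 1e-8) {
  nky <- traj$grid$n_ky; nkz <- traj$grid$n_kz
  lapply(seq_len(bins$n_bins), function(b) {
    w_j <- bins$W[traj$heartbeat + 1L, b]
    sel <- which(w_j > weight_thresh)
    m <- numeric(nky * nkz)
    cols <- (traj$readouts[sel, 2]) * nky + traj$readouts[sel, 1] + 1L
    for (i in seq_along(sel)) m[cols[i]] <- m[cols[i]] + w_j[sel[i]]^2
    arr <- array(rep(m, each = npx), dim = c(npx, nky, nkz, 1))
    array(rep(arr, 2), dim = c(npx, nky, nkz, 2))
  })
}

tp_kmask <- function(x, mask, tape) {
  tp_node(tape, x$value * mask, list(x), function(g) list(g * mask))
}

# E*E x on the tape: for each bin warp to the bin frame, coil-multiply, FFT,
# apply the squared-weight mask, inverse FFT, conjugate coil combine, warp
# back (paper-mode M*), sum bins.
tp_normal_apply <- function(x, ctx, tape) {
  acc <- NULL
  for (b in seq_along(ctx$masks)) {
    d <- ctx$disp[[b]]
    rb <- if (is.null(d)) x else tp_warp(x, d$d_ref2bin, tape)
    vb <- NULL
    for (c in seq_len(ctx$n_coils)) {
      f <- tp_fft(tp_cmul_const(rb, ctx$coils[[c]], tape), tape)
      u <- tp_ifft(tp_kmask(f, ctx$masks[[b]], tape), tape)
      u <- tp_cmul_const(u, Conj(ctx$coils[[c]]), tape)
      vb <- if (is.null(vb)) u else tp_add(vb, u, tape)
    }
    wb <- if (is.null(d)) vb else tp_warp(vb, d$d_bin2ref, tape)
    acc <- if (is.null(acc)) wb else tp_add(acc, wb, tape)
  }
  acc
}

# CG on the tape (fixed iteration count, differentiated through).
tp_cg <- function(Afun, rhs, x0, n_iter, tape) {
  x <- x0
  r <- tp_sub(rhs, Afun(x), tape)
  p <- r
  rr <- tp_dot(r, r, tape)
  for (i in seq_len(n_iter)) {
    Ap <- Afun(p)
    pAp <- tp_dot(p, Ap, tape)
    if (as.numeric(pAp$value) <= 1e-300) break
    alpha <- tp_div(rr, pAp, tape)
    x <- tp_add(x, tp_scalar_mul(p, alpha, tape), tape)
    r <- tp_sub(r, tp_scalar_mul(Ap, alpha, tape), tape)
    rr_new <- tp_dot(r, r, tape)
    beta <- tp_div(rr_new, rr, tape)
    p <- tp_add(r, tp_scalar_mul(p, beta, tape), tape)
    rr <- rr_new
  }
  x
}

# Build the full differentiable graph for one training step on one x-patch.
# Returns the loss nodes plus the parameter node lists.
training_step_graph <- function(sample, motion_net, denoiser, cfg,
                                patch_start) {
  tape <- tape_new()
  n <- sample$kdata$shape
  npx <- min(cfg$patch_x, n[1])
  x0i <- patch_start
  xr <- (x0i + 1):(x0i + npx)
  bins <- sample$bins
  ref_bin <- bins$end_exp_bin
  n_bins <- bins$n_bins
  coils_p <- lapply(seq_len(dim(sample$coils)[4]),
                    function(c) sample$coils[xr, , , c])
  pk <- hybrid_to_patch_kspace(sample$hybrid, x0i, x0i + npx)

  pm <- params_to_nodes(motion_net$params, tape)
  pd <- params_to_nodes(denoiser$params, tape)

  # motion fields per bin (tape nodes); identity for the reference bin
  disp <- vector("list", n_bins)
  vel_nodes <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    if (b == ref_bin) next
    r <- tp_estimate_motion(sample$sense_mag[[ref_bin]][xr, , ],
                            sample$sense_mag[[b]][xr, , ],
                            pm, motion_net, tape)
    disp[[b]] <- r
    vel_nodes[[b]] <- r$velocity
  }

  # constants: per-bin zero-filled adjoint volumes (M-free part of E*b)
  op <- encoding_op(sample$kdata$traj, array(unlist(coils_p),
                    dim = c(npx, n[2], n[3], length(coils_p))), bins)
  pk_data <- list(kspace = pk, traj = sample$kdata$traj,
                  shape = c(npx, n[2], n[3]), voxel_mm = sample$kdata$voxel_mm)
  zf <- lapply(seq_len(n_bins), function(b) {
    yb <- pk[, op$rows[[b]], , drop = FALSE]
    tp_const(tape, c2r(adjoint_bin_volume(yb, op, b)))
  })
  rhs <- NULL
  for (b in seq_len(n_bins)) {
    term <- if (is.null(disp[[b]])) zf[[b]] else
      tp_warp(zf[[b]], disp[[b]]$d_bin2ref, tape)
    rhs <- if (is.null(rhs)) term else tp_add(rhs, term, tape)
  }

  ctx <- list(masks = bin_k_masks(sample$kdata$traj, bins, npx),
              coils = coils_p, n_coils = length(coils_p), disp = disp)
  Afun <- function(xn) tp_normal_apply(xn, ctx, tape)

  x <- rhs
  for (i in seq_len(cfg$n_modl_iter)) {
    x <- tp_cg(Afun, rhs, x, cfg$n_cg, tape)
    if (i < cfg$n_modl_iter) x <- tp_denoise(x, pd, tape)
  }

  # losses
  ref_end <- c2r(sample$ref_bins[[ref_bin]][xr, , ])
  L_mot <- NULL
  for (b in seq_len(n_bins)) {
    if (b == ref_bin) next
    refb <- tp_const(tape, c2r(sample$ref_bins[[b]][xr, , ]))
    warped <- tp_warp(refb, disp[[b]]$d_bin2ref, tape)
    diffb <- tp_sub(tp_const(tape, ref_end), warped, tape)
    term <- tp_charbonnier(diffb, tape, cfg$charbonnier_eps)
    sm <- tp_scale(tp_gradsq(vel_nodes[[b]], tape), cfg$smooth_weight, tape)
    term <- tp_add(term, sm, tape)
    L_mot <- if (is.null(L_mot)) term else tp_add(L_mot, term, tape)
  }
  L_recon <- tp_charbonnier(tp_sub(tp_const(tape, ref_end), x, tape), tape,
                            cfg$charbonnier_eps)
  L_reg <- NULL
  for (ps in list(pm, pd)) {
    for (k in names(ps)) {
      if (!endsWith(k, "_w")) next
      t <- tp_sumsq(ps[[k]], tape)
      L_reg <- if (is.null(L_reg)) t else tp_add(L_reg, t, tape)
    }
  }
  total <- tp_add(tp_add(tp_scale(L_mot, cfg$lambda1, tape),
                         tp_scale(L_recon, cfg$lambda2, tape), tape),
                  tp_scale(L_reg, cfg$lambda3, tape), tape)
  list(tape = tape, total = total, L_mot = L_mot, L_recon = L_recon,
       L_reg = L_reg, pm = pm, pd = pd, recon = x)
}

#' One-step loss and gradients (differentiable end to end)
#'
#' Builds the full unrolled graph for one training patch — motion network,
#' scaling-and-squaring, CG data consistency, denoiser — evaluates the
#' composite loss and backpropagates to all network parameters.
#'
#' @param sample a \code{\link{make_training_sample}} result
#' @param motion_net,denoiser the two networks
#' @param cfg a \code{\link{train_config}}
#' @param patch_start 0-based patch start along x
#' @return list with loss components and per-network gradient lists
#' @export
loss_and_gradients <- function(sample, motion_net, denoiser, cfg,
                               patch_start = 0L) {
  g <- training_step_graph(sample, motion_net, denoiser, cfg, patch_start)
  tp_backward(g$tape, g$total)
  grads_of <- function(pn) lapply(pn, function(nd) nd$grad)
  list(total = as.numeric(g$total$value),
       L_mot = as.numeric(g$L_mot$value),
       L_recon = as.numeric(g$L_recon$value),
       L_reg = as.numeric(g$L_reg$value),
       grad_motion = grads_of(g$pm),
       grad_denoiser = grads_of(g$pd))
}

#' Train both networks end to end
#'
#' One optimization step per sample per epoch on a randomly selected
#' readout-direction patch; Adam with the configured learning-rate halving
#' schedule. Gradients flow through the CG solves and the
#' scaling-and-squaring integration. Aborts (returning the last finite
#' state) if the loss becomes non-finite.
#'
#' @param samples list of \code{training_sample}
#' @param motion_net,denoiser initialized networks
#' @param cfg a \code{\link{train_config}}
#' @param verbose print a line per epoch
#' @return list with trained \code{motion_net}, \code{denoiser} and a
#'   per-step \code{history} data frame
#' @export
train_mocomodl <- function(samples, motion_net = dirrespme_net(),
                           denoiser = denoiser_net(), cfg = train_config(),
                           verbose = FALSE) {
  assert_that(length(samples) >= 1, "need at least one sample")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  opt_m <- adam_new(motion_net$params, lr = cfg$lr)
  opt_d <- adam_new(denoiser$params, lr = cfg$lr)
  hist <- list()
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr * 0.5^((epoch - 1) %/% cfg$lr_halve_every)
    for (si in seq_along(samples)) {
      smp <- samples[[si]]
      nx <- smp$kdata$shape[1]
      npx <- min(cfg$patch_x, nx)
      patch_start <- if (nx > npx) sample.int(nx - npx + 1L, 1L) - 1L else 0L
      res <- loss_and_gradients(smp, motion_net, denoiser, cfg, patch_start)
      if (!is.finite(res$total)) {
        warning("non-finite loss; aborting with last finite parameters")
        return(list(motion_net = motion_net, denoiser = denoiser,
                    history = do.call(rbind, hist), aborted = TRUE))
      }
      st <- adam_step(opt_m, motion_net$params, res$grad_motion, lr = lr)
      opt_m <- st$opt; motion_net$params <- st$params
      st <- adam_step(opt_d, denoiser$params, res$grad_denoiser, lr = lr)
      opt_d <- st$opt; denoiser$params <- st$params
      hist[[length(hist) + 1L]] <- data.frame(
        epoch = epoch, sample = si, lr = lr, total = res$total,
        L_mot = res$L_mot, L_recon = res$L_recon, L_reg = res$L_reg)
    }
    if (verbose) {
      h <- hist[[length(hist)]]
      message(sprintf("epoch %d/%d lr %.2e total %.4f mot %.4f recon %.4f",
                      epoch, cfg$epochs, lr, h$total, h$L_mot, h$L_recon))
    }
  }
  list(motion_net = motion_net, denoiser = denoiser,
       history = do.call(rbind, hist), aborted = FALSE)
}
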