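# Autodiff engine and network-contract tests.

test_that("tape gradients of compiled kernels match finite differences", {
  set.seed(7)
  fd_max_err <- function(fval, x, gx, h = 1e-5, k = 4) {
    idx <- sample(length(x), min(k, length(x)))
    max(sapply(idx, function(i) {
      xp <- x; xp[i] <- xp[i] + h
      xm <- x; xm[i] <- xm[i] - h
      num <- (fval(xp) - fval(xm)) / (2 * h)
      abs(num - gx[i]) / max(abs(num), 1e-8)
    }))
  }
  # conv3d w.r.t. input, weights, bias through a nonlinear head
  xd <- c(6, 6, 4, 2)
  x <- array(rnorm(prod(xd)), dim = xd)
  w <- array(rnorm(27 * 2 * 3, 0, 0.3), dim = c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  run <- function(xx, ww, bb) {
    tp <- mocomodl:::tape_new()
    xn <- mocomodl:::tp_param(tp, array(xx, dim = xd))
    wn <- mocomodl:::tp_param(tp, array(ww, dim = dim(w)))
    bn <- mocomodl:::tp_param(tp, bb)
    y <- mocomodl:::tp_leaky_relu(mocomodl:::tp_conv3d(xn, wn, bn, tp), tp)
    loss <- mocomodl:::tp_sumsq(y, tp)
    list(tp = tp, loss = loss, xn = xn, wn = wn, bn = bn)
  }
  g <- run(x, w, b)
  mocomodl:::tp_backward(g$tp, g$loss)
  expect_lt(fd_max_err(function(v) run(v, w, b)$loss$value, x, g$xn$grad), 1e-4)
  expect_lt(fd_max_err(function(v) run(x, v, b)$loss$value, w, g$wn$grad), 1e-4)
  expect_lt(fd_max_err(function(v) run(x, w, v)$loss$value, b, g$bn$grad), 1e-4)
  # warp w.r.t. both volume and displacement
  vd <- c(6, 6, 4, 2)
  vol <- array(rnorm(prod(vd)), dim = vd)
  disp <- array(rnorm(prod(c(vd[1:3], 3)), 0, 0.4), dim = c(vd[1:3], 3))
  runw <- function(vv, dd) {
    tp <- mocomodl:::tape_new()
    vn <- mocomodl:::tp_param(tp, array(vv, dim = vd))
    dn <- mocomodl:::tp_param(tp, array(dd, dim = dim(disp)))
    loss <- mocomodl:::tp_sumsq(mocomodl:::tp_warp(vn, dn, tp), tp)
    list(tp = tp, loss = loss, vn = vn, dn = dn)
  }
  gw <- runw(vol, disp)
  mocomodl:::tp_backward(gw$tp, gw$loss)
  expect_lt(fd_max_err(function(v) runw(v, disp)$loss$value, vol, gw$vn$grad), 1e-4)
  expect_lt(fd_max_err(function(v) runw(vol, v)$loss$value, disp, gw$dn$grad), 1e-4)
})

test_that("tape FFT pair is mutually adjoint (complex 2-channel convention)", {
  set.seed(8)
  d <- c(8, 6, 4, 2)
  tp <- mocomodl:::tape_new()
  x <- array(rnorm(prod(d)), dim = d)
  y <- array(rnorm(prod(d)), dim = d)
  xn <- mocomodl:::tp_param(tp, x)
  f <- mocomodl:::tp_fft(xn, tp)
  loss <- mocomodl:::tp_dot(f, mocomodl:::tp_const(tp, y), tp)
  mocomodl:::tp_backward(tp, loss)
  # <F x, y> = <x, F^H y>: the gradient of the linear functional is F^H y
  fhy <- mocomodl:::c2r(ufft_adj(mocomodl:::r2c(y)))
  expect_lt(max(abs(xn$grad - fhy)), 1e-12)
})

test_that("zero-initialized heads give exact identity behaviour", {
  set.seed(9)
  n <- c(8, 8, 8)
  # motion net: identity field at initialization
  net <- dirrespme_net(ch = c(4, 8), seed = 1)
  a <- array(abs(rnorm(prod(n))), dim = n)
  b <- array(abs(rnorm(prod(n))), dim = n)
  mf <- estimate_motion(a, b, net)
  expect_equal(max(abs(mf$d_ref2bin)), 0)
  expect_equal(max(abs(mf$d_bin2ref)), 0)
  # denoiser: exact identity at initialization
  dn <- denoiser_net(ch = c(4, 8), seed = 2)
  v <- array(complex(real = rnorm(prod(n)), imaginary = rnorm(prod(n))), dim = n)
  expect_equal(denoise(v, dn), v)
  # finite-in/finite-out with random weights of training scale
  dn$params$out_w[] <- rnorm(length(dn$params$out_w), 0, 0.05)
  out <- denoise(v, dn)
  expect_true(all(is.finite(Re(out)) & all(is.finite(Im(out)))))
  expect_equal(dim(out), n)
})

test_that("networks are translation-covariant up to border effects", {
  set.seed(10)
  n <- c(24, 16, 8)
  dnet <- denoiser_net(ch = c(4, 8), seed = 3)
  for (k in names(dnet$params)) {
    dnet$params[[k]][] <- rnorm(length(dnet$params[[k]]), 0, 0.08)
  }
  spec <- phantom_spec(shape = n)
  vol <- render_phantom(spec, 0)
  out <- denoise(vol, dnet)
  # shift the input by 4 voxels along x (circular); in the interior, far
  # from borders and pooling misalignment, the output shifts along
  sh <- c(5:24, 1:4)
  out_sh <- denoise(vol[sh, , ], dnet)
  rng <- diff(range(Mod(out)))
  interior <- 9:16
  dev <- max(Mod(out_sh[interior, 5:12, 3:6] - out[sh, , ][interior, 5:12, 3:6]))
  expect_lt(dev / rng, 0.05)
})

test_that("a trained-free motion net recovers a known translation direction", {
  # behavioural contract on a tiny registration problem: fitting the motion
  # net on a single pair by gradient descent on the warping loss drives the
  # field toward the true shift
  set.seed(11)
  n <- c(16, 16, 8)
  spec <- phantom_spec(shape = n, voxel_mm = 2, amp_fh_mm = 4, amp_lr_mm = 0,
                       nonrigid_frac = 0, shear_frac = 0)
  ref <- abs(render_phantom(spec, 0))
  mov <- abs(render_phantom(spec, 1))  # ~2 voxel FH shift
  net <- dirrespme_net(ch = c(4, 8), seed = 4)
  opt <- mocomodl:::adam_new(net$params, lr = 8e-3)
  for (it in 1:150) {
    tp <- mocomodl:::tape_new()
    pn <- mocomodl:::params_to_nodes(net$params, tp)
    r <- mocomodl:::tp_estimate_motion(ref, mov, pn, net, tp)
    movn <- mocomodl:::tp_const(tp, array(mov, dim = c(n, 1)))
    warped <- mocomodl:::tp_warp(movn, r$d_bin2ref, tp)
    diffn <- mocomodl:::tp_sub(mocomodl:::tp_const(tp, array(ref, dim = c(n, 1))),
                               warped, tp)
    loss <- mocomodl:::tp_add(
      mocomodl:::tp_charbonnier(diffn, tp, 1e-3),
      mocomodl:::tp_scale(mocomodl:::tp_gradsq(r$velocity, tp), 0.01, tp), tp)
    mocomodl:::tp_backward(tp, loss)
    st <- mocomodl:::adam_step(opt, net$params,
                               lapply(pn, function(nd) nd$grad))
    opt <- st$opt; net$params <- st$params
  }
  mf <- estimate_motion(ref, mov, net)
  # moving image content sits +2 voxels FH of the reference, so the pullback
  # field that generates it from the reference is about -2 voxels
  core <- mf$d_ref2bin[6:11, 6:11, 3:6, 1]
  expect_lt(mean(core), -1)
  expect_lt(mean(abs(core + 2)), 1)
})
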