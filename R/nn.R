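# Small 3D convolutional U-Nets built on the autodiff tape, plus the Adam
# optimizer used for end-to-end training. Parameters live as plain arrays in
# the network object; each training step registers them on a fresh tape.

he_init <- function(ksz, cin, cout, rng) {
  sd <- sqrt(2 / (ksz^3 * cin))
  array(stats::rnorm(ksz^3 * cin * cout, 0, sd), dim = c(ksz, ksz, ksz, cin, cout))
}

#' Initialize a two-level 3D U-Net parameter set
#'
#' Encoder (two convs), 2x average-pool, bottleneck (two convs), trilinear
#' 2x upsample with skip concatenation, decoder conv and a final 1-group
#' projection whose weights are zero-initialized so the network output is
#' exactly zero at initialization (identity behaviour for residual heads).
#'
#' @param cin,cout input/output channel counts
#' @param ch channels per level, length 2 (default c(8, 16))
#' @param ksz kernel size (odd, default 3)
#' @param seed integer seed
#' @return list of parameter arrays with attribute \code{config}
#' @export
unet_init <- function(cin, cout, ch = c(8, 16), ksz = 3, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p <- list(
    enc1_w = he_init(ksz, cin, ch[1]),   enc1_b = numeric(ch[1]),
    enc2_w = he_init(ksz, ch[1], ch[1]), enc2_b = numeric(ch[1]),
    mid1_w = he_init(ksz, ch[1], ch[2]), mid1_b = numeric(ch[2]),
    mid2_w = he_init(ksz, ch[2], ch[2]), mid2_b = numeric(ch[2]),
    dec1_w = he_init(ksz, ch[2] + ch[1], ch[1]), dec1_b = numeric(ch[1]),
    out_w = array(0, dim = c(ksz, ksz, ksz, ch[1], cout)), out_b = numeric(cout)
  )
  attr(p, "config") <- list(cin = cin, cout = cout, ch = ch, ksz = ksz)
  p
}

# Register parameters on a tape; returns list of nodes (same names).
params_to_nodes <- function(params, tape) {
  lapply(params, function(v) tp_param(tape, v))
}

# U-Net forward pass on the tape. x: [nx,ny,nz,cin] node, pn: param nodes.
unet_forward <- function(x, pn, tape) {
  lr <- function(n) tp_leaky_relu(n, tape)
  e1 <- lr(tp_conv3d(x, pn$enc1_w, pn$enc1_b, tape))
  e2 <- lr(tp_conv3d(e1, pn$enc2_w, pn$enc2_b, tape))
  dn <- tp_avgpool2(e2, tape)
  m1 <- lr(tp_conv3d(dn, pn$mid1_w, pn$mid1_b, tape))
  m2 <- lr(tp_conv3d(m1, pn$mid2_w, pn$mid2_b, tape))
  up <- tp_upsample2(m2, tape)
  cc <- tp_cat_ch(up, e2, tape)
  d1 <- lr(tp_conv3d(cc, pn$dec1_w, pn$dec1_b, tape))
  tp_conv3d(d1, pn$out_w, pn$out_b, tape)
}

# Plain (inference) forward: builds a throwaway tape.
unet_apply <- function(x, params) {
  tape <- tape_new()
  xn <- tp_const(tape, x)
  pn <- params_to_nodes(params, tape)
  unet_forward(xn, pn, tape)$value
}

# --- Adam ------------------------------------------------------------------

adam_new <- function(params, lr = 3e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads, lr = NULL) {
  opt$t <- opt$t + 1
  lr <- lr %||% opt$lr
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * g
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[k]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[k]] / (1 - opt$beta2^opt$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}
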