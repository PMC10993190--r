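# Minimal reverse-mode automatic differentiation tape.
#
# Values are plain numeric arrays. Complex quantities are carried as arrays
# with a trailing channel dimension of 2 (real, imaginary); for a complex-
# linear unitary map A in that representation, the transpose of the real
# Jacobian corresponds to applying A^H, which for the unitary FFT is its
# inverse. Nodes are environments holding the value, accumulated gradient,
# parent references and a backward function; backward() sweeps the tape in
# reverse creation order.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

tp_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

tp_const <- function(tape, value) tp_node(tape, value)
tp_param <- function(tape, value) tp_node(tape, value)

acc_grad <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Reverse sweep from a scalar loss node.
tp_backward <- function(tape, loss) {
  loss$grad <- array(1, dim = dim(loss$value) %||% 1)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents)) {
      if (!is.null(gs[[k]])) acc_grad(nd$parents[[k]], gs[[k]])
    }
  }
  invisible(NULL)
}

# --- elementwise arithmetic ------------------------------------------------

tp_add <- function(a, b, tape) {
  tp_node(tape, a$value + b$value, list(a, b),
          function(g) list(g, g))
}

tp_sub <- function(a, b, tape) {
  tp_node(tape, a$value - b$value, list(a, b),
          function(g) list(g, -g))
}

tp_mul <- function(a, b, tape) {
  av <- a$value; bv <- b$value
  tp_node(tape, av * bv, list(a, b),
          function(g) list(g * bv, g * av))
}

tp_scale <- function(a, s, tape) {       # s plain numeric scalar
  tp_node(tape, a$value * s, list(a), function(g) list(g * s))
}

# volume * scalar-node (broadcast)
tp_scalar_mul <- function(vol, sc, tape) {
  vv <- vol$value; sv <- as.numeric(sc$value)
  tp_node(tape, vv * sv, list(vol, sc),
          function(g) list(g * sv, sum(g * vv)))
}

tp_dot <- function(a, b, tape) {         # scalar node sum(a * b)
  av <- a$value; bv <- b$value
  tp_node(tape, sum(av * bv), list(a, b),
          function(g) { g <- as.numeric(g); list(g * bv, g * av) })
}

tp_div <- function(a, b, tape) {         # scalar nodes a / b
  av <- as.numeric(a$value); bv <- as.numeric(b$value)
  tp_node(tape, av / bv, list(a, b),
          function(g) { g <- as.numeric(g); list(g / bv, -g * av / bv^2) })
}

# --- activations, losses ---------------------------------------------------

tp_leaky_relu <- function(x, tape, slope = 0.1) {
  xv <- x$value
  m <- ifelse(xv >= 0, 1, slope)
  tp_node(tape, xv * m, list(x), function(g) list(g * m))
}

# mean(sqrt(x^2 + eps^2) - eps): smooth absolute-error (Charbonnier) loss
tp_charbonnier <- function(x, tape, eps = 1e-3) {
  xv <- x$value
  s <- sqrt(xv^2 + eps^2)
  n <- length(xv)
  tp_node(tape, sum(s - eps) / n, list(x),
          function(g) list(as.numeric(g) * xv / s / n))
}

tp_sumsq <- function(x, tape) {
  xv <- x$value
  tp_node(tape, sum(xv^2), list(x), function(g) list(2 * as.numeric(g) * xv))
}

# squared forward-difference spatial gradient of a [nx,ny,nz,C] field
tp_gradsq <- function(x, tape) {
  xv <- x$value
  d <- dim(xv)
  val <- 0
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) next
    hi <- slice_index(xv, ax, 2:n)
    lo <- slice_index(xv, ax, 1:(n - 1))
    val <- val + sum((hi - lo)^2)
  }
  val <- val / length(xv)
  tp_node(tape, val, list(x), function(g) {
    g <- as.numeric(g)
    gx <- array(0, dim = d)
    for (ax in 1:3) {
      n <- d[ax]
      if (n < 2) next
      hi <- slice_index(xv, ax, 2:n)
      lo <- slice_index(xv, ax, 1:(n - 1))
      dd <- 2 * (hi - lo) / length(xv)
      idx_hi <- as.list(rep(TRUE, 4)); idx_lo <- idx_hi
      ghi <- array(0, dim = d); glo <- array(0, dim = d)
      ghi <- assign_slice(ghi, ax, 2:n, dd)
      glo <- assign_slice(glo, ax, 1:(n - 1), dd)
      gx <- gx + ghi - glo
    }
    list(g * gx)
  })
}

# assign values into one axis slice of an array
assign_slice <- function(x, axis, idx, value) {
  d <- dim(x)
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[<-`, c(list(x), args, list(value = value)))
}

# --- structural ops --------------------------------------------------------

tp_cat_ch <- function(a, b, tape) {      # concat along trailing channel dim
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  nd <- length(da)
  val <- array(c(av, bv), dim = c(da[-nd], da[nd] + db[nd]))
  tp_node(tape, val, list(a, b), function(g) {
    list(array(slice_index(g, nd, seq_len(da[nd])), dim = da),
         array(slice_index(g, nd, da[nd] + seq_len(db[nd])), dim = db))
  })
}

# --- compiled-kernel ops ---------------------------------------------------

tp_conv3d <- function(x, w, b, tape) {
  xd <- dim(x$value)
  wd <- dim(w$value)
  ksz <- wd[1]; cout <- wd[5]
  xv <- x$value; wv <- w$value
  val <- array(conv3d_fwd_cpp(as.vector(xv), as.vector(wv),
                              as.vector(b$value), as.integer(xd),
                              as.integer(ksz), as.integer(cout)),
               dim = c(xd[1:3], cout))
  tp_node(tape, val, list(x, w, b), function(g) {
    r <- conv3d_bwd_cpp(as.vector(xv), as.vector(wv), as.vector(g),
                        as.integer(xd), as.integer(ksz), as.integer(cout))
    list(array(r$gx, dim = xd), array(r$gw, dim = wd), as.numeric(r$gb))
  })
}

tp_avgpool2 <- function(x, tape) {
  xd <- dim(x$value)
  val <- array(avgpool2_fwd_cpp(as.vector(x$value), as.integer(xd)),
               dim = c(xd[1:3] %/% 2L, xd[4]))
  tp_node(tape, val, list(x), function(g) {
    list(array(avgpool2_bwd_cpp(as.vector(g), as.integer(xd)), dim = xd))
  })
}

tp_upsample2 <- function(x, tape) {
  xd <- dim(x$value)
  val <- array(upsample2_fwd_cpp(as.vector(x$value), as.integer(xd)),
               dim = c(xd[1:3] * 2L, xd[4]))
  tp_node(tape, val, list(x), function(g) {
    list(array(upsample2_bwd_cpp(as.vector(g), as.integer(xd)), dim = xd))
  })
}

# warp of a [nx,ny,nz,C] node by a [nx,ny,nz,3] displacement node
tp_warp <- function(vol, disp, tape) {
  vd <- dim(vol$value)
  vv <- vol$value; dv <- disp$value
  val <- array(warp_fwd_cpp(as.vector(vv), as.vector(dv), as.integer(vd)),
               dim = vd)
  tp_node(tape, val, list(vol, disp), function(g) {
    gvol <- array(warp_splat_cpp(as.vector(g), as.vector(dv), as.integer(vd)),
                  dim = vd)
    gdisp <- array(warp_bwd_disp_cpp(as.vector(vv), as.vector(dv),
                                     as.vector(g), as.integer(vd)),
                   dim = c(vd[1:3], 3L))
    list(gvol, gdisp)
  })
}

# --- complex (2-channel) ops ----------------------------------------------

# unitary centred 3D FFT of a [nx,ny,nz,2] node; adjoint = inverse
tp_fft <- function(x, tape) {
  xd <- dim(x$value)
  val <- c2r(ufft(r2c(x$value)))
  tp_node(tape, val, list(x), function(g) list(c2r(ufft_adj(r2c(g)))))
}

tp_ifft <- function(x, tape) {
  xd <- dim(x$value)
  val <- c2r(ufft_adj(r2c(x$value)))
  tp_node(tape, val, list(x), function(g) list(c2r(ufft(r2c(g)))))
}

# multiply a [dims,2] node by a constant complex array (e.g. a coil map);
# backward multiplies by the conjugate
tp_cmul_const <- function(x, S, tape) {
  val <- c2r(r2c(x$value) * S)
  tp_node(tape, val, list(x), function(g) list(c2r(r2c(g) * Conj(S))))
}

# gather k-space readout columns with weights: x is [nx,ny,nz,2], cols are
# 1-based column indices into the flattened (ky,kz) plane, w per-column
# weights; output [nx, n_cols, 2]
tp_gather <- function(x, cols, w, tape) {
  xd <- dim(x$value)
  nx <- xd[1]
  gather_val <- function(v) {
    M <- array(v, dim = c(nx, xd[2] * xd[3], 2))
    out <- M[, cols, , drop = FALSE]
    out[, , 1] <- sweep(out[, , 1, drop = FALSE], 2, w, `*`)
    out[, , 2] <- sweep(out[, , 2, drop = FALSE], 2, w, `*`)
    out
  }
  val <- gather_val(x$value)
  tp_node(tape, val, list(x), function(g) {
    G <- array(0, dim = c(nx, xd[2] * xd[3], 2))
    for (j in seq_along(cols)) {
      G[, cols[j], ] <- G[, cols[j], ] + g[, j, ] * w[j]
    }
    list(array(G, dim = xd))
  })
}

# scatter (adjoint of tp_gather): y is [nx, n_cols, 2] -> [nx,ny,nz,2]
tp_scatter <- function(y, cols, w, ny, nz, tape) {
  yd <- dim(y$value)
  nx <- yd[1]
  G <- array(0, dim = c(nx, ny * nz, 2))
  yv <- y$value
  for (j in seq_along(cols)) {
    G[, cols[j], ] <- G[, cols[j], ] + yv[, j, ] * w[j]
  }
  val <- array(G, dim = c(nx, ny, nz, 2))
  tp_node(tape, val, list(y), function(g) {
    M <- array(g, dim = c(nx, ny * nz, 2))
    out <- M[, cols, , drop = FALSE]
    out[, , 1] <- sweep(out[, , 1, drop = FALSE], 2, w, `*`)
    out[, , 2] <- sweep(out[, , 2, drop = FALSE], 2, w, `*`)
    list(out)
  })
}

# complex conjugate of a 2-channel node (flip imaginary sign)
tp_conj <- function(x, tape) {
  d <- dim(x$value)
  nd <- length(d)
  flip <- function(v) {
    v2 <- v
    v2 <- assign_slice(v2, nd, 2L, -slice_index(v, nd, 2L))
    v2
  }
  tp_node(tape, flip(x$value), list(x), function(g) list(flip(g)))
}
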