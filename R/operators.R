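# The linear-algebra core: soft-gated sampling (U), unitary FFT (F), coil
# sensitivities (S) and motion warping (M) composed into the encoding
# operator E = U F S M, its adjoint, the zero-filled per-bin reconstruction,
# iterative SENSE and the conjugate-gradient solver for E*E rho = E*b.
#
# FFT convention: unitary and DC-centred (see ufft), so F* = F^{-1} and the
# adjoint of sampling is zero-filled scattering. Soft-gating weights are
# applied in both E and E*, i.e. they appear squared in E*E (least-squares
# weighting). Samples acquired multiple times are kept as separate rows, so
# re-acquisition density weighting emerges naturally in E*.

#' Build a motion-corrected encoding operator
#'
#' @param traj a \code{caspr_trajectory}
#' @param coils complex coil maps [nx, ny, nz, n_coils]
#' @param bins a \code{\link{bin_heartbeats}} result (or NULL for a single
#'   all-heartbeats bin with unit weights)
#' @param motion list (one per bin) of motion fields, each a list with
#'   \code{d_ref2bin} and \code{d_bin2ref} displacement arrays
#'   [nx, ny, nz, 3] (voxel units), or NULL for identity motion
#' @param adjoint_mode \code{"paper"} (M* realized by warping with the
#'   inverse field, as used inside the reconstruction) or \code{"exact"}
#'   (true transpose by splatting, used by operator tests)
#' @param weight_thresh readouts with soft weight below this are dropped
#'   from a bin
#' @return object of class \code{encoding_op}
#' @export
encoding_op <- function(traj, coils, bins = NULL, motion = NULL,
                        adjoint_mode = c("paper", "exact"),
                        weight_thresh = 1e-8) {
  adjoint_mode <- match.arg(adjoint_mode)
  shape <- dim(coils)[1:3]
  assert_that(shape[2] == traj$grid$n_ky && shape[3] == traj$grid$n_kz,
              "coil grid must match trajectory phase-encode grid")
  H <- traj$n_heartbeats
  if (is.null(bins)) {
    W <- matrix(1, H, 1)
    n_bins <- 1L
  } else {
    W <- bins$W
    n_bins <- bins$n_bins
  }
  rows <- list(); wts <- list()
  for (b in seq_len(n_bins)) {
    w_j <- W[traj$heartbeat + 1L, b]
    sel <- which(w_j > weight_thresh)
    rows[[b]] <- sel
    wts[[b]] <- w_j[sel]
  }
  structure(list(traj = traj, coils = coils, shape = shape,
                 n_bins = n_bins, rows = rows, weights = wts,
                 motion = motion, adjoint_mode = adjoint_mode,
                 n_coils = dim(coils)[4]),
            class = "encoding_op")
}

#' @export
print.encoding_op <- function(x, ...) {
  cat(sprintf("<encoding_op> %d bins x %d coils, volume %s, motion %s, adjoint '%s'\n",
              x$n_bins, x$n_coils, paste(x$shape, collapse = "x"),
              if (is.null(x$motion)) "identity" else "non-rigid",
              x$adjoint_mode))
  invisible(x)
}

bin_disp <- function(op, b, which = c("ref2bin", "bin2ref")) {
  which <- match.arg(which)
  if (is.null(op$motion)) return(NULL)
  m <- op$motion[[b]]
  if (is.null(m)) return(NULL)
  if (which == "ref2bin") m$d_ref2bin else m$d_bin2ref
}

#' Apply the encoding operator E = U F S M
#'
#' For each respiratory bin: warp the reference-frame volume to the bin (M),
#' multiply by each coil map (S), take the unitary 3D FFT (F) and sample the
#' bin's (ky, kz) readouts over all kx with soft-gating weights (U).
#'
#' @param rho complex volume [nx, ny, nz]
#' @param op an \code{\link{encoding_op}}
#' @return list over bins of complex arrays [n_coils, n_rows_b, nx]
#' @export
apply_E <- function(rho, op) {
  assert_that(all(dim(rho) == op$shape), "volume shape mismatch")
  n <- op$shape
  out <- vector("list", op$n_bins)
  for (b in seq_len(op$n_bins)) {
    d <- bin_disp(op, b, "ref2bin")
    rb <- if (is.null(d)) rho else warp_volume(rho, d)
    sel <- op$rows[[b]]
    y <- array(complex(real = 0), dim = c(op$n_coils, length(sel), n[1]))
    if (length(sel) > 0) {
      ky <- op$traj$readouts[sel, 1] + 1L
      kz <- op$traj$readouts[sel, 2] + 1L
      for (c in seq_len(op$n_coils)) {
        F <- ufft(rb * op$coils[, , , c])
        Fm <- matrix(F, nrow = n[1])   # [nx, nky*nkz]
        cols <- (kz - 1L) * n[2] + ky
        y[c, , ] <- t(Fm[, cols, drop = FALSE]) * op$weights[[b]]
      }
    }
    out[[b]] <- y
  }
  out
}

#' Apply the adjoint encoding operator E*
#'
#' Per bin: scatter the weighted samples back onto the k-space grid (U^T,
#' summing re-acquired locations), inverse unitary FFT, coil-combine with the
#' conjugate maps (S*) and map back to the reference frame with M* (inverse-
#' field warp in \code{"paper"} mode, exact splatting transpose in
#' \code{"exact"} mode); results are summed over bins.
#'
#' @param y sample list as produced by \code{\link{apply_E}}
#' @param op an \code{\link{encoding_op}}
#' @return complex volume [nx, ny, nz]
#' @export
apply_E_adjoint <- function(y, op) {
  n <- op$shape
  acc <- array(complex(real = 0), dim = n)
  for (b in seq_len(op$n_bins)) {
    vb <- adjoint_bin_volume(y[[b]], op, b)
    d_inv <- bin_disp(op, b, "bin2ref")
    if (!is.null(d_inv)) {
      if (op$adjoint_mode == "exact") {
        vb <- warp_adjoint(vb, bin_disp(op, b, "ref2bin"))
      } else {
        vb <- warp_volume(vb, d_inv)
      }
    }
    acc <- acc + vb
  }
  acc
}

# S* F^{-1} U^T for one bin (no motion term).
adjoint_bin_volume <- function(yb, op, b) {
  n <- op$shape
  sel <- op$rows[[b]]
  vb <- array(complex(real = 0), dim = n)
  if (length(sel) == 0) return(vb)
  ky <- op$traj$readouts[sel, 1] + 1L
  kz <- op$traj$readouts[sel, 2] + 1L
  cols <- (kz - 1L) * n[2] + ky
  w <- op$weights[[b]]
  for (c in seq_len(op$n_coils)) {
    G <- matrix(complex(real = 0), nrow = n[1], ncol = n[2] * n[3])
    for (j in seq_along(sel)) {       # accumulate: duplicates must sum
      G[, cols[j]] <- G[, cols[j]] + w[j] * yb[c, j, ]
    }
    img <- ufft_adj(array(G, dim = n))
    vb <- vb + Conj(op$coils[, , , c]) * img
  }
  vb
}

#' Zero-filled per-bin reconstruction
#'
#' The motion-free adjoint S* F^{-1} U^T b applied bin by bin to
#' (translationally corrected) k-space data; these per-bin images are the
#' inputs for motion estimation.
#'
#' @param kdata a \code{kspace_data} (after \code{\link{phase_correct}})
#' @param bins a \code{\link{bin_heartbeats}} result
#' @param coils complex coil maps [nx, ny, nz, n_coils]
#' @return list of \code{bins$n_bins} complex volumes
#' @export
zero_filled_recon <- function(kdata, bins, coils) {
  op <- encoding_op(kdata$traj, coils, bins)
  lapply(seq_len(op$n_bins), function(b) {
    # U^T applies the soft weight once (inside adjoint_bin_volume)
    yb <- kdata$kspace[, op$rows[[b]], , drop = FALSE]
    adjoint_bin_volume(yb, op, b)
  })
}

# Restrict acquired k-space to the rows of each bin of an operator,
# returning the raw sample list expected by apply_E_adjoint (which applies
# the single U^T weight factor itself).
bin_samples <- function(kdata, op) {
  lapply(seq_len(op$n_bins), function(b) {
    kdata$kspace[, op$rows[[b]], , drop = FALSE]
  })
}

#' Conjugate-gradient solve of a Hermitian system
#'
#' Standard CG on \code{A x = rhs} from a warm start, recording residual
#' norms per iteration. Inside the unrolled reconstruction the default is
#' 3 iterations; the prior enters through the warm start.
#'
#' @param A function taking and returning a complex volume (Hermitian PSD)
#' @param rhs right-hand side volume
#' @param x0 warm start (default zero)
#' @param n_iter maximum iterations (default 3)
#' @param tol stop when relative residual falls below this (default 0)
#' @return list(x, report) where report has \code{residuals} (residual norm
#'   per iterate, starting with the warm-start residual), \code{energy}
#'   (the CG objective 0.5 <x, Ax> - <x, rhs> per iterate, non-increasing
#'   by construction — for A = E*E this tracks the data-space residual
#'   \code{||E rho - b||}, which plain residual norms do not monotonically
#'   follow), \code{n_iter} and \code{final_relres}
#' @export
cg_solve <- function(A, rhs, x0 = NULL, n_iter = 3, tol = 0) {
  assert_that(all(is.finite(Re(rhs))) && all(is.finite(Im(rhs))),
              "non-finite right-hand side")
  x <- if (is.null(x0)) rhs * 0 else x0
  r <- rhs - A(x)
  p <- r
  rr <- re_inner(r, r)
  b_norm <- sqrt(re_inner(rhs, rhs))
  res <- sqrt(rr)
  # phi(x) = 0.5 <x, Ax> - <x, rhs> = -0.5 <x, rhs + r>
  en <- -0.5 * re_inner(x, rhs + r)
  it <- 0
  while (it < n_iter && sqrt(rr) > tol * max(b_norm, .Machine$double.eps)) {
    Ap <- A(p)
    pAp <- re_inner(p, Ap)
    if (pAp <= 0) break
    alpha <- rr / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rr_new <- re_inner(r, r)
    beta <- rr_new / rr
    p <- r + beta * p
    rr <- rr_new
    res <- c(res, sqrt(rr))
    en <- c(en, -0.5 * re_inner(x, rhs + r))
    it <- it + 1
  }
  report <- list(residuals = res, energy = en, n_iter = it,
                 final_relres = sqrt(rr) / max(b_norm, .Machine$double.eps))
  list(x = x, report = report)
}

#' Iterative SENSE reconstruction of one respiratory bin
#'
#' CG on the single-bin normal equations (identity motion), 10 iterations by
#' default, warm-started at the zero-filled adjoint; used to create bin
#' images for motion estimation only.
#'
#' @param kdata a \code{kspace_data}
#' @param bins a \code{\link{bin_heartbeats}} result
#' @param bin bin index
#' @param coils coil maps
#' @param n_iter CG iterations (default 10)
#' @return list(x, report)
#' @export
sense_recon <- function(kdata, bins, bin, coils, n_iter = 10) {
  Wb <- matrix(bins$W[, bin], ncol = 1)
  sub_bins <- list(W = Wb, n_bins = 1L)
  op <- encoding_op(kdata$traj, coils, sub_bins)
  y <- bin_samples(kdata, op)
  rhs <- apply_E_adjoint(y, op)
  A <- function(x) apply_E_adjoint(apply_E(x, op), op)
  cg_solve(A, rhs, x0 = rhs, n_iter = n_iter)
}
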