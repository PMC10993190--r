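# The two learnable components: the diffeomorphic respiratory motion
# estimation network (pairwise bin magnitudes -> stationary velocity field,
# integrated by scaling and squaring) and the residual denoising U-Net
# (complex volume as two real channels -> complex volume).

#' Create a motion-estimation network
#'
#' A small 3D U-Net taking two magnitude channels (reference bin, moving
#' bin) on the x2-downsampled grid and returning a 3-channel stationary
#' velocity field on that grid. The velocity head is zero-initialized, so an
#' untrained network yields exactly the identity motion field and the whole
#' framework reduces to translational-only correction.
#'
#' @param ch channels per U-Net level (default c(8, 16))
#' @param n_squaring scaling-and-squaring steps (default 6)
#' @param seed integer seed for the weight initialization
#' @return object of class \code{dirrespme_net}
#' @export
dirrespme_net <- function(ch = c(8, 16), n_squaring = 6, seed = 1L) {
  structure(list(params = unet_init(2, 3, ch = ch, seed = seed),
                 n_squaring = as.integer(n_squaring), ch = ch),
            class = "dirrespme_net")
}

#' @export
print.dirrespme_net <- function(x, ...) {
  cat(sprintf("<dirrespme_net> 2 -> 3 channels, levels %s, %d squaring steps, %d parameters\n",
              paste(x$ch, collapse = "/"), x$n_squaring,
              sum(vapply(x$params, length, 0L))))
  invisible(x)
}

#' Create a residual denoising network
#'
#' A small 3D U-Net acting on the real and imaginary channels of a complex
#' volume; the output is input + correction, with the correction head
#' zero-initialized (exact identity at initialization).
#'
#' @inheritParams dirrespme_net
#' @return object of class \code{denoiser_net}
#' @export
denoiser_net <- function(ch = c(8, 16), seed = 2L) {
  structure(list(params = unet_init(2, 2, ch = ch, seed = seed), ch = ch,
                 residual = TRUE),
            class = "denoiser_net")
}

#' @export
print.denoiser_net <- function(x, ...) {
  cat(sprintf("<denoiser_net> residual 2 -> 2 channels, levels %s, %d parameters\n",
              paste(x$ch, collapse = "/"), sum(vapply(x$params, length, 0L))))
  invisible(x)
}

# Joint max-normalization of an image pair (shared scale keeps relative
# intensities meaningful for registration).
pair_normalize <- function(a, b) {
  m <- max(max(abs(a)), max(abs(b)), .Machine$double.eps)
  list(a = a / m, b = b / m)
}

# Tape-side motion estimation from constant magnitude inputs; returns nodes.
# ref_mag, mov_mag: full-resolution magnitude arrays (even dims).
tp_estimate_motion <- function(ref_mag, mov_mag, pn, net, tape) {
  nrm <- pair_normalize(ref_mag, mov_mag)
  n <- dim(ref_mag)
  x <- array(0, dim = c(n, 2))
  x[, , , 1] <- nrm$a; x[, , , 2] <- nrm$b
  xd <- tp_avgpool2(tp_const(tape, x), tape)    # x2 downsampling
  v <- unet_forward(xd, pn, tape)               # velocity on the down grid
  # scaling and squaring on the tape
  int_one <- function(vel) {
    d <- tp_scale(vel, 1 / 2^net$n_squaring, tape)
    for (i in seq_len(net$n_squaring)) d <- tp_add(d, tp_warp(d, d, tape), tape)
    d
  }
  fwd <- int_one(v)
  inv <- int_one(tp_scale(v, -1, tape))
  # upsample x2 and rescale displacement values to full-resolution voxels
  up <- function(d) tp_scale(tp_upsample2(d, tape), 2, tape)
  list(velocity = v, d_ref2bin = up(fwd), d_bin2ref = up(inv))
}

#' Estimate a non-rigid motion field between two bin images
#'
#' Downsamples the magnitude pair by 2x (average pooling), runs the motion
#' network to get a stationary velocity field, integrates it by scaling and
#' squaring into diffeomorphic forward/inverse displacements, and upsamples
#' the fields by 2x (trilinear, displacement values doubled) back to the
#' full grid.
#'
#' @param ref_mag,mov_mag magnitude volumes on the same grid (even dims)
#' @param net a \code{\link{dirrespme_net}}
#' @return list with \code{d_ref2bin}, \code{d_bin2ref} ([nx,ny,nz,3], voxel
#'   units) and \code{velocity} (down-grid)
#' @export
estimate_motion <- function(ref_mag, mov_mag, net) {
  assert_that(all(dim(ref_mag) == dim(mov_mag)), "grid mismatch")
  tape <- tape_new()
  pn <- params_to_nodes(net$params, tape)
  r <- tp_estimate_motion(ref_mag, mov_mag, pn, net, tape)
  list(d_ref2bin = r$d_ref2bin$value, d_bin2ref = r$d_bin2ref$value,
       velocity = r$velocity$value)
}

# Tape-side denoiser on a [nx,ny,nz,2] node.
tp_denoise <- function(x, pn, tape) {
  tp_add(x, unet_forward(x, pn, tape), tape)
}

#' Apply the denoising network to a complex volume
#'
#' Splits the volume into real and imaginary channels, applies the residual
#' U-Net, and recombines; shape preserving.
#'
#' @param volume complex 3D array (even dims)
#' @param net a \code{\link{denoiser_net}}
#' @return denoised complex volume
#' @export
denoise <- function(volume, net) {
  assert_that(all(is.finite(Re(volume))) && all(is.finite(Im(volume))),
              "non-finite input")
  x <- c2r(volume)
  tape <- tape_new()
  pn <- params_to_nodes(net$params, tape)
  y <- tp_denoise(tp_const(tape, x), pn, tape)
  r2c(y$value)
}
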