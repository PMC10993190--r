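# The unrolled inference pipeline: readout-direction patching, per-bin SENSE
# images, motion estimation, the alternating data-consistency / denoiser
# iteration, and patch recombination.

#' Reconstruction configuration
#'
#' Defaults follow the full-scale protocol: 5 MoDL iterations (4 denoiser
#' passes), 3 CG iterations per data-consistency step, 10 SENSE iterations
#' for the motion-estimation bin images, 4 respiratory bins, patch size 48
#' along the fully sampled readout direction with a 5-voxel edge discard and
#' 4-voxel overlap. \code{dc_mode = "paper"} solves E*E rho = E*b with the
#' denoiser output entering only through the CG warm start; \code{"modl"}
#' solves the damped system (E*E + lambda I) rho = E*b + lambda z.
#'
#' @param n_modl_iter number of unrolled iterations (default 5)
#' @param n_cg CG iterations per DC step (default 3)
#' @param n_sense SENSE iterations for bin images (default 10)
#' @param n_bins respiratory bins (default 4)
#' @param patch_x patch size along x (default 48; use the volume size for a
#'   single patch); must be even when networks are used
#' @param edge_discard voxels removed from interior patch edges (default 5)
#' @param overlap retained-region overlap after discard (default 4)
#' @param softness soft-gating width (default 0.5)
#' @param n_squaring scaling-and-squaring steps (default 6)
#' @param dc_mode \code{"paper"} or \code{"modl"}
#' @param lambda damping for \code{dc_mode = "modl"}
#' @param use_motion include non-rigid motion in the encoding operator
#' @param adjoint_mode \code{"paper"} or \code{"exact"} M* (see
#'   \code{\link{encoding_op}})
#' @return list of class \code{recon_config}
#' @export
recon_config <- function(n_modl_iter = 5, n_cg = 3, n_sense = 10, n_bins = 4,
                         patch_x = 48, edge_discard = 5, overlap = 4,
                         softness = 0.5, n_squaring = 6,
                         dc_mode = c("paper", "modl"), lambda = 0.05,
                         use_motion = TRUE,
                         adjoint_mode = c("paper", "exact")) {
  dc_mode <- match.arg(dc_mode)
  adjoint_mode <- match.arg(adjoint_mode)
  assert_that(n_modl_iter >= 1, "need at least one unrolled iteration")
  structure(list(n_modl_iter = n_modl_iter, n_cg = n_cg, n_sense = n_sense,
                 n_bins = n_bins, patch_x = patch_x,
                 edge_discard = edge_discard, overlap = overlap,
                 softness = softness, n_squaring = n_squaring,
                 dc_mode = dc_mode, lambda = lambda, use_motion = use_motion,
                 adjoint_mode = adjoint_mode),
            class = "recon_config")
}

#' Plan overlapping readout-direction patches
#'
#' Deterministic tiling of the x axis into patches of \code{patch_x} voxels.
#' An \code{edge_discard}-voxel layer is removed from interior patch edges
#' (outer volume borders keep their edges), leaving retained regions that
#' overlap by \code{overlap} voxels; overlapping voxels are averaged at
#' recombination, and the averaging weights sum to 1 at every voxel.
#'
#' @param n_x volume extent along x
#' @param patch_x patch size (<= n_x)
#' @param edge_discard edge layer width
#' @param overlap retained overlap
#' @return object of class \code{patch_plan}
#' @export
plan_patches <- function(n_x, patch_x, edge_discard = 5, overlap = 4) {
  assert_that(patch_x <= n_x, "patch larger than volume")
  if (patch_x == n_x) {
    starts <- 0L
  } else {
    stride <- patch_x - 2 * edge_discard - overlap
    assert_that(stride >= 1, "infeasible patch geometry: non-positive stride")
    starts <- seq(0L, n_x - patch_x, by = stride)
    if (tail(starts, 1) < n_x - patch_x) starts <- c(starts, n_x - patch_x)
  }
  np <- length(starts)
  retained <- vector("list", np)
  for (p in seq_len(np)) {
    lo <- starts[p] + if (p == 1) 0L else edge_discard
    hi <- starts[p] + patch_x - if (p == np) 0L else edge_discard
    retained[[p]] <- c(lo, hi)   # 0-based half-open
  }
  cover <- integer(n_x)
  for (p in seq_len(np)) {
    r <- retained[[p]]
    cover[(r[1] + 1):r[2]] <- cover[(r[1] + 1):r[2]] + 1L
  }
  assert_that(all(cover >= 1), "patch plan does not cover the volume")
  structure(list(n_x = as.integer(n_x), patch_x = as.integer(patch_x),
                 edge_discard = as.integer(edge_discard),
                 overlap = as.integer(overlap), starts = as.integer(starts),
                 retained = retained, coverage = cover),
            class = "patch_plan")
}

#' @export
print.patch_plan <- function(x, ...) {
  cat(sprintf("<patch_plan> %d patches of %d voxels over %d (discard %d, overlap %d)\n",
              length(x$starts), x$patch_x, x$n_x, x$edge_discard, x$overlap))
  invisible(x)
}

#' Recombine per-patch volumes
#'
#' @param patches list of complex volumes, one per patch of \code{plan}
#' @param plan a \code{\link{plan_patches}} result
#' @return full complex volume
#' @export
recombine_patches <- function(patches, plan) {
  d <- dim(patches[[1]])
  out <- array(complex(real = 0), dim = c(plan$n_x, d[2], d[3]))
  for (p in seq_along(plan$starts)) {
    r <- plan$retained[[p]]
    loc <- (r[1] - plan$starts[p] + 1):(r[2] - plan$starts[p])
    out[(r[1] + 1):r[2], , ] <- out[(r[1] + 1):r[2], , ] +
      patches[[p]][loc, , , drop = FALSE]
  }
  sweep(out, 1, plan$coverage, `/`)
}

# --- hybrid-space helpers --------------------------------------------------

# centred unitary 1D FFT along the columns of a matrix
ufft1_mat <- function(M, inverse = FALSE) {
  n <- nrow(M)
  sh_in <- c(seq_len(n %/% 2) + (n - n %/% 2), seq_len(n - n %/% 2))   # ifftshift
  sh_out <- c(seq_len(n - n %/% 2) + n %/% 2, seq_len(n %/% 2))       # fftshift
  Y <- stats::mvfft(M[sh_in, , drop = FALSE], inverse = inverse)
  Y[sh_out, , drop = FALSE] / sqrt(n)
}

# k-space [nc, nread, nx] -> hybrid (image domain along x)
kspace_to_hybrid <- function(kspace) {
  d <- dim(kspace)
  M <- matrix(aperm(kspace, c(3, 1, 2)), nrow = d[3])
  H <- ufft1_mat(M, inverse = TRUE)
  aperm(array(H, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
}

# hybrid slab (0-based half-open x interval) -> patch k-space [nc,nread,npx]
hybrid_to_patch_kspace <- function(hybrid, x0, x1) {
  d <- dim(hybrid)
  slab <- hybrid[, , (x0 + 1):x1, drop = FALSE]
  npx <- x1 - x0
  M <- matrix(aperm(slab, c(3, 1, 2)), nrow = npx)
  K <- ufft1_mat(M, inverse = FALSE)
  aperm(array(K, dim = c(npx, d[1], d[2])), c(2, 3, 1))
}

# --- the pipeline ----------------------------------------------------------

#' Motion-corrected unrolled reconstruction
#'
#' Full inference pipeline: iNAV-derived translational phase correction,
#' soft-gated binning, per-patch SENSE bin images and motion estimation,
#' then the unrolled alternation of conjugate-gradient data-consistency
#' solves and denoiser passes, with the zero-filled adjoint (inverse motion
#' fields applied per bin and summed) as right-hand side and initial guess.
#' The output is the end-expiration-frame volume.
#'
#' @param kdata a \code{kspace_data}
#' @param coils coil maps [nx, ny, nz, n_coils]
#' @param config a \code{\link{recon_config}}
#' @param motion_net a \code{\link{dirrespme_net}} or NULL (identity motion)
#' @param denoiser a \code{\link{denoiser_net}} or NULL (identity denoiser)
#' @param translations optional \code{resp_translations}; registered from
#'   the stored iNAVs when NULL
#' @param motion_override optional list (one per bin) of full-volume motion
#'   fields to use instead of network estimates
#' @return object of class \code{mocomodl_recon} with \code{volume},
#'   \code{bins}, \code{plan}, \code{translations} and an iteration
#'   \code{ledger} (CG reports, data-consistency residuals, call counts)
#' @export
reconstruct_mocomodl <- function(kdata, coils, config = recon_config(),
                                 motion_net = NULL, denoiser = NULL,
                                 translations = NULL, motion_override = NULL) {
  n <- kdata$shape
  if (is.null(translations)) {
    assert_that(!is.null(kdata$inav), "no iNAVs stored and no translations given")
    translations <- register_inavs(kdata$inav, voxel_mm = kdata$voxel_mm)
  }
  kc <- phase_correct(kdata, translations)
  bins <- bin_heartbeats(translations, config$n_bins, config$softness)
  plan <- plan_patches(n[1], min(config$patch_x, n[1]), config$edge_discard,
                       config$overlap)
  hybrid <- kspace_to_hybrid(kc$kspace)
  ref_bin <- bins$end_exp_bin

  patches <- vector("list", length(plan$starts))
  ledger <- list(n_dc = 0L, n_denoise = 0L, cg_reports = list(),
                 dc_residuals = list())
  for (p in seq_along(plan$starts)) {
    x0 <- plan$starts[p]; x1 <- x0 + plan$patch_x
    pk <- list(kspace = hybrid_to_patch_kspace(hybrid, x0, x1),
               traj = kc$traj, shape = c(plan$patch_x, n[2], n[3]),
               voxel_mm = kdata$voxel_mm)
    class(pk) <- "kspace_data"
    coils_p <- coils[(x0 + 1):x1, , , , drop = FALSE]

    motion <- NULL
    if (config$use_motion && (!is.null(motion_net) || !is.null(motion_override))) {
      if (!is.null(motion_override)) {
        motion <- lapply(motion_override, function(m) {
          if (is.null(m)) return(NULL)
          list(d_ref2bin = m$d_ref2bin[(x0 + 1):x1, , , , drop = FALSE],
               d_bin2ref = m$d_bin2ref[(x0 + 1):x1, , , , drop = FALSE])
        })
      } else {
        sense_mag <- lapply(seq_len(config$n_bins), function(b)
          abs(sense_recon(pk, bins, b, coils_p, n_iter = config$n_sense)$x))
        motion <- vector("list", config$n_bins)
        for (b in seq_len(config$n_bins)) {
          if (b == ref_bin) next
          mf <- estimate_motion(sense_mag[[ref_bin]], sense_mag[[b]], motion_net)
          motion[[b]] <- mf[c("d_ref2bin", "d_bin2ref")]
        }
      }
    }

    op <- encoding_op(pk$traj, coils_p, bins, motion,
                      adjoint_mode = config$adjoint_mode)
    y <- bin_samples(pk, op)
    rhs <- apply_E_adjoint(y, op)
    y_norm <- sqrt(sum(vapply(y, function(v) sum(Mod(v)^2), 0)))
    A <- if (config$dc_mode == "modl") {
      function(x) apply_E_adjoint(apply_E(x, op), op) + config$lambda * x
    } else {
      function(x) apply_E_adjoint(apply_E(x, op), op)
    }
    data_residual <- function(x) {
      ex <- apply_E(x, op)
      sqrt(sum(vapply(seq_along(ex), function(b) sum(Mod(ex[[b]] - y[[b]] *
        rep(op$weights[[b]], each = op$n_coils))^2), 0)))
    }
    x <- rhs
    for (i in seq_len(config$n_modl_iter)) {
      rhs_i <- if (config$dc_mode == "modl") rhs + config$lambda * x else rhs
      r0 <- data_residual(x)
      sol <- cg_solve(A, rhs_i, x0 = x, n_iter = config$n_cg)
      x <- sol$x
      ledger$n_dc <- ledger$n_dc + 1L
      ledger$cg_reports[[length(ledger$cg_reports) + 1L]] <- sol$report
      ledger$dc_residuals[[length(ledger$dc_residuals) + 1L]] <-
        c(before = r0, after = data_residual(x))
      if (i < config$n_modl_iter && !is.null(denoiser)) {
        x <- denoise(x, denoiser)
        ledger$n_denoise <- ledger$n_denoise + 1L
      } else if (i < config$n_modl_iter) {
        ledger$n_denoise <- ledger$n_denoise + 1L  # identity denoiser pass
      }
    }
    patches[[p]] <- x
  }
  vol <- recombine_patches(patches, plan)
  structure(list(volume = vol, bins = bins, plan = plan,
                 translations = translations, config = config,
                 ledger = ledger),
            class = "mocomodl_recon")
}

#' @export
print.mocomodl_recon <- function(x, ...) {
  cat(sprintf(paste0("<mocomodl_recon> volume %s, %d patches, %d DC solves, ",
                     "%d denoiser passes\n"),
              paste(dim(x$volume), collapse = "x"), length(x$plan$starts),
              x$ledger$n_dc, x$ledger$n_denoise))
  invisible(x)
}
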