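# Raw-data container and volume I/O. The container keeps the group layout
# /kspace, /inav, /resp, /trajectory/*, /ground_truth as a structured,
# serialized R list; volumes and displacement fields go to NIfTI via RNifti
# (fields as 4D with the vector component in the 4th dimension, voxel
# units).

#' Write a raw acquisition container
#'
#' @param kdata a \code{kspace_data}
#' @param path output file path
#' @param truth optional \code{phantom_truth} stored under ground_truth
#' @export
write_raw_container <- function(kdata, path, truth = NULL) {
  traj <- kdata$traj
  container <- list(
    kspace = kdata$kspace,
    inav = kdata$inav,
    resp = kdata$resp_translations_mm,
    trajectory = list(
      readouts = traj$readouts,
      heartbeat = traj$heartbeat,
      grid = c(n_ky = traj$grid$n_ky, n_kz = traj$grid$n_kz),
      nominal_accel = traj$nominal_accel,
      r_center = traj$r_center %||% NA_real_,
      n_heartbeats = traj$n_heartbeats
    ),
    shape = kdata$shape,
    voxel_mm = kdata$voxel_mm,
    coils = kdata$coils,
    ground_truth = truth
  )
  saveRDS(container, path)
  invisible(path)
}

#' Read a raw acquisition container
#'
#' @param path file written by \code{\link{write_raw_container}}
#' @return list with \code{kdata} (class \code{kspace_data}) and
#'   \code{truth} (possibly NULL)
#' @export
read_raw_container <- function(path) {
  x <- readRDS(path)
  grid <- grid_spec(x$trajectory$grid["n_ky"], x$trajectory$grid["n_kz"])
  traj <- structure(list(
    grid = grid, readouts = x$trajectory$readouts,
    heartbeat = x$trajectory$heartbeat, interleaf = x$trajectory$heartbeat,
    shutter = make_shutter(grid), nominal_accel = x$trajectory$nominal_accel,
    r_center = x$trajectory$r_center,
    n_heartbeats = x$trajectory$n_heartbeats), class = "caspr_trajectory")
  kdata <- structure(list(kspace = x$kspace, traj = traj, inav = x$inav,
                          resp_translations_mm = x$resp,
                          voxel_mm = x$voxel_mm, shape = x$shape,
                          coils = x$coils),
                     class = "kspace_data")
  list(kdata = kdata, truth = x$ground_truth)
}

#' Write a (complex) volume as NIfTI magnitude
#'
#' @param vol 3D array (complex volumes are written as magnitude)
#' @param path output .nii or .nii.gz path
#' @param voxel_mm isotropic voxel size
#' @export
write_volume_nifti <- function(vol, path, voxel_mm = 1) {
  v <- if (is.complex(vol)) abs(vol) else vol
  img <- RNifti::asNifti(v, pixdim = rep(voxel_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a displacement field as 4D NIfTI
#'
#' The vector component lies along the 4th dimension; values are in voxel
#' units with the convention that \code{warp_volume(vol, disp)} samples
#' \code{vol} at \code{x + disp(x)}.
#'
#' @param disp [nx, ny, nz, 3] array
#' @param path output path
#' @param voxel_mm isotropic voxel size
#' @export
write_field_nifti <- function(disp, path, voxel_mm = 1) {
  img <- RNifti::asNifti(disp, pixdim = c(rep(voxel_mm, 3), 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume or field
#'
#' @param path NIfTI file path
#' @return numeric array
#' @export
read_nifti <- function(path) {
  x <- as.array(RNifti::readNifti(path))
  array(as.vector(x), dim = dim(x))
}
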