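# Variable-density spiral-profile Cartesian (CASPR-style) trajectory design
# on the ky-kz phase-encode plane, with elliptical shutter, fully sampled
# centre, acceleration accounting and annulus-based density-preserving
# retrospective undersampling.

#' Phase-encode grid specification
#'
#' Defines the ky-kz Cartesian phase-encode plane. Indices are 0-based and the
#' DC point sits at \code{(n_ky %/% 2, n_kz %/% 2)}.
#'
#' @param n_ky,n_kz number of phase encodes along ky and kz (>= 8)
#' @return an object of class \code{grid_spec}
#' @export
grid_spec <- function(n_ky, n_kz) {
  assert_that(n_ky >= 4 && n_kz >= 4, "grid must be at least 4x4")
  structure(list(n_ky = as.integer(n_ky), n_kz = as.integer(n_kz),
                 center = c(n_ky %/% 2, n_kz %/% 2)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d phase encodes, DC at (%d, %d) [0-based]\n",
              x$n_ky, x$n_kz, x$center[1], x$center[2]))
  invisible(x)
}

# Normalized elliptical coordinates of 0-based (ky, kz) indices:
# u = (ky - cy)/(n_ky/2), v = (kz - cz)/(n_kz/2); radius sqrt(u^2 + v^2).
norm_coords <- function(grid, ky, kz) {
  u <- (ky - grid$center[1]) / (grid$n_ky / 2)
  v <- (kz - grid$center[2]) / (grid$n_kz / 2)
  list(u = u, v = v, r = sqrt(u^2 + v^2), theta = atan2(v, u))
}

#' Elliptical shutter mask
#'
#' Corner phase encodes outside the ellipse inscribed in the rectangular
#' ky-kz plane are never acquired; this saves a factor of 4/pi of samples.
#'
#' @param grid a \code{\link{grid_spec}}
#' @return logical matrix \code{n_ky x n_kz}, \code{TRUE} inside the ellipse
#' @export
make_shutter <- function(grid) {
  ky <- rep(0:(grid$n_ky - 1), times = grid$n_kz)
  kz <- rep(0:(grid$n_kz - 1), each = grid$n_ky)
  r <- norm_coords(grid, ky, kz)$r
  matrix(r <= 1, nrow = grid$n_ky, ncol = grid$n_kz)
}

#' Generate a variable-density spiral-profile Cartesian trajectory
#'
#' Phase encodes inside the elliptical shutter are selected with a density
#' that is 1 inside a central disc (fully sampled k-space centre) and decays
#' with the normalized elliptical radius as \code{(1 + beta*r)^(-gamma)}
#' outside it. Selected encodes are grouped into per-heartbeat spiral-like
#' interleaves: each heartbeat's arm follows an Archimedean spiral in
#' normalized coordinates, successive arms rotated by the golden angle
#' (about 111.25 degrees), with readouts ordered centre-out so the azimuth
#' increases with radius along the arm.
#'
#' The number of unique acquired locations is exactly
#' \code{round(count(shutter) / nominal_accel)}; the acquisition budget is
#' spread over heartbeats as evenly as possible.
#'
#' @param grid a \code{\link{grid_spec}}
#' @param nominal_accel nominal undersampling factor relative to the full
#'   elliptical-shutter acquisition (>= 1)
#' @param n_heartbeats number of heartbeats (interleaves)
#' @param readouts_per_beat optional expected interleaf size; checked against
#'   the budget (within one beat's worth) when supplied
#' @param r_center radius (normalized units) of the fully sampled centre disc
#' @param beta,gamma variable-density law parameters
#' @param rng_seed integer seed; the same seed reproduces the trajectory
#' @return an object of class \code{caspr_trajectory} with fields
#'   \code{grid}, \code{readouts} (N x 2 integer, 0-based), \code{heartbeat}
#'   (N, 0-based), \code{interleaf}, \code{shutter}, \code{nominal_accel}
#' @export
generate_caspr <- function(grid, nominal_accel, n_heartbeats,
                           readouts_per_beat = NULL, r_center = 0.1,
                           beta = 4, gamma = 2, rng_seed = 1L) {
  assert_that(nominal_accel >= 1, "nominal_accel must be >= 1")
  assert_that(n_heartbeats >= 1, "need at least one heartbeat")
  shutter <- make_shutter(grid)
  ky <- rep(0:(grid$n_ky - 1), times = grid$n_kz)
  kz <- rep(0:(grid$n_kz - 1), each = grid$n_ky)
  inside <- as.vector(shutter)
  ky <- ky[inside]; kz <- kz[inside]
  nc <- norm_coords(grid, ky, kz)
  n_shutter <- length(ky)
  budget <- max(1L, as.integer(round(n_shutter / nominal_accel)))
  if (!is.null(readouts_per_beat)) {
    assert_that(abs(n_heartbeats * readouts_per_beat - budget) <= readouts_per_beat,
                "n_heartbeats x readouts_per_beat inconsistent with acquisition budget")
  }
  in_center <- nc$r <= r_center
  n_center <- sum(in_center)
  assert_that(n_center <= budget,
              sprintf("fully sampled centre disc (%d points) exceeds the budget (%d)",
                      n_center, budget))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)

  sel <- which(in_center)
  n_out <- budget - n_center
  if (n_out > 0) {
    cand <- which(!in_center)
    w <- (1 + beta * nc$r[cand])^(-gamma)
    # weighted sampling without replacement (exponential-race keys)
    keys <- stats::rexp(length(cand)) / w
    sel <- c(sel, cand[order(keys)][seq_len(n_out)])
  }

  r <- nc$r[sel]; theta <- nc$theta[sel]
  # balanced greedy assignment to spiral arms
  golden <- pi / ((1 + sqrt(5)) / 2)  # 180/phi degrees ~ 111.25
  phi <- (seq_len(n_heartbeats) - 1) * golden
  pitch <- 2 * pi  # one winding per arm over r in [0, 1]
  sizes <- rep(budget %/% n_heartbeats, n_heartbeats)
  extra <- budget %% n_heartbeats
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(r)
  beat <- integer(budget)
  remaining <- sizes
  for (p in ord) {
    d <- (theta[p] - phi - pitch * r[p]) %% (2 * pi)
    d <- pmin(d, 2 * pi - d)
    d[remaining == 0] <- Inf
    h <- which.min(d)
    beat[p] <- h - 1L
    remaining[h] <- remaining[h] - 1L
  }
  # centre-out ordering inside each arm
  ord2 <- order(beat, r, theta)
  traj <- structure(list(
    grid = grid,
    readouts = cbind(ky = ky[sel][ord2], kz = kz[sel][ord2]),
    heartbeat = beat[ord2],
    interleaf = beat[ord2],
    shutter = shutter,
    nominal_accel = nominal_accel,
    r_center = r_center,
    n_heartbeats = as.integer(n_heartbeats)
  ), class = "caspr_trajectory")
  traj
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' @export
print.caspr_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<caspr_trajectory> %d readouts over %d heartbeats on a ",
                     "%d x %d grid\n  nominal accel %.2f (shutter), effective ",
                     "%.2f (rectangular)\n"),
              nrow(x$readouts), x$n_heartbeats, x$grid$n_ky, x$grid$n_kz,
              x$nominal_accel, effective_accel_rectangular(x)))
  invisible(x)
}

unique_readout_key <- function(traj) {
  unique(traj$readouts[, 1] * traj$grid$n_kz + traj$readouts[, 2])
}

#' Effective acceleration relative to the rectangular grid
#'
#' The nominal factor is defined against the elliptical-shutter interior;
#' relative to the fully sampled rectangular ky-kz plane the factor is larger
#' by about 4/pi (e.g. nominal 3, 4, 7 become 3.8, 5.1, 8.9).
#'
#' @param traj a \code{caspr_trajectory}
#' @return numeric: (n_ky * n_kz) / number of unique acquired locations
#' @export
effective_accel_rectangular <- function(traj) {
  n_unique <- length(unique_readout_key(traj))
  assert_that(n_unique > 0, "empty trajectory")
  (traj$grid$n_ky * traj$grid$n_kz) / n_unique
}

#' Measure the per-annulus acquisition profile
#'
#' Segments the shutter interior into concentric elliptic annuli with
#' boundaries equally spaced in the normalized elliptical radius and reports,
#' for each annulus, the fraction of its phase encodes that were acquired
#' (unique locations).
#'
#' @param traj a \code{caspr_trajectory}
#' @param n_annuli number of annuli (default 20)
#' @return an object of class \code{annulus_profile} with \code{boundaries}
#'   (length \code{n_annuli + 1}) and \code{acquired_fraction}; annuli that
#'   contain no grid points report \code{NaN}
#' @export
measure_annulus_profile <- function(traj, n_annuli = 20) {
  assert_that(n_annuli >= 2, "need at least two annuli")
  grid <- traj$grid
  bounds <- seq(0, 1, length.out = n_annuli + 1)
  ky <- rep(0:(grid$n_ky - 1), times = grid$n_kz)
  kz <- rep(0:(grid$n_kz - 1), each = grid$n_ky)
  r_all <- norm_coords(grid, ky, kz)$r
  r_all <- r_all[r_all <= 1]
  ann_all <- annulus_of(r_all, bounds)
  key <- unique_readout_key(traj)
  uky <- key %/% grid$n_kz; ukz <- key %% grid$n_kz
  r_acq <- norm_coords(grid, uky, ukz)$r
  ann_acq <- annulus_of(r_acq, bounds)
  n_tot <- tabulate(ann_all, nbins = n_annuli)
  n_acq <- tabulate(ann_acq, nbins = n_annuli)
  frac <- ifelse(n_tot > 0, n_acq / n_tot, NaN)
  structure(list(n_annuli = as.integer(n_annuli), boundaries = bounds,
                 acquired_fraction = frac, n_total = n_tot, n_acquired = n_acq),
            class = "annulus_profile")
}

# Annulus index (1-based) of normalized radii; r = 0 belongs to annulus 1,
# upper boundaries inclusive.
annulus_of <- function(r, bounds) {
  a <- findInterval(r, bounds, left.open = TRUE, rightmost.closed = TRUE)
  a[r <= bounds[1]] <- 1L
  pmin(a, length(bounds) - 1L)
}

#' @export
print.annulus_profile <- function(x, ...) {
  cat(sprintf("<annulus_profile> %d elliptic annuli\n", x$n_annuli))
  cat("  acquired fraction:", paste(sprintf("%.2f", x$acquired_fraction),
                                    collapse = " "), "\n")
  invisible(x)
}

#' Average several annulus profiles
#'
#' Per-annulus mean of the acquired fractions (NaN-aware), mirroring the
#' averaging of prospectively undersampled datasets used to define the
#' retrospective target profile.
#'
#' @param profiles list of \code{annulus_profile} objects on identical
#'   boundaries
#' @return an \code{annulus_profile}
#' @export
mean_annulus_profile <- function(profiles) {
  assert_that(length(profiles) >= 1, "need at least one profile")
  b <- profiles[[1]]$boundaries
  for (p in profiles) assert_that(all(p$boundaries == b), "boundary mismatch")
  fr <- rowMeans(sapply(profiles, `[[`, "acquired_fraction"), na.rm = TRUE)
  out <- profiles[[1]]
  out$acquired_fraction <- fr
  out$n_acquired <- round(fr * out$n_total)
  out
}

#' Density-preserving retrospective undersampling
#'
#' Forms a higher-acceleration trajectory as a strict subset of the readouts
#' of a lower-acceleration one while matching a target per-annulus
#' acquisition profile: within each elliptic annulus a random subset of the
#' acquired readouts is retained so that the acquired fraction matches the
#' target (within one readout). Annuli whose target fraction is 1 are left
#' untouched, so the fully sampled centre is preserved. Heartbeat assignments
#' of retained readouts are unchanged.
#'
#' @param traj source \code{caspr_trajectory}
#' @param target_profile an \code{annulus_profile} (e.g. measured from a
#'   prospectively higher-accelerated trajectory, or an average of several)
#' @param rng_seed integer seed
#' @param clip if FALSE (default) an annulus whose target exceeds the
#'   source's acquired count raises an error naming the annulus; if TRUE
#'   such annuli keep all their acquired readouts (useful on small grids
#'   where single-annulus counts fluctuate)
#' @return a \code{caspr_trajectory} whose readouts are a subset of
#'   \code{traj}'s
#' @export
retrospective_undersample <- function(traj, target_profile, rng_seed = 1L,
                                      clip = FALSE) {
  grid <- traj$grid
  bounds <- target_profile$boundaries
  n_ann <- target_profile$n_annuli
  src <- measure_annulus_profile(traj, n_ann)
  nc <- norm_coords(grid, traj$readouts[, 1], traj$readouts[, 2])
  ann <- annulus_of(nc$r, bounds)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)

  keep <- logical(nrow(traj$readouts))
  for (a in seq_len(n_ann)) {
    rows <- which(ann == a)
    m <- length(rows)
    if (m == 0) next
    tf <- target_profile$acquired_fraction[a]
    if (is.nan(tf)) tf <- src$acquired_fraction[a]
    target_n <- round(tf * src$n_total[a])
    if (target_n > m) {
      if (!clip) {
        stop(sprintf(paste0("infeasible target in annulus %d: target %d readouts",
                            " but only %d acquired"), a, target_n, m),
             call. = FALSE)
      }
      target_n <- m
    }
    if (tf >= 1 || target_n == m) {
      keep[rows] <- TRUE
    } else {
      keep[sample(rows, target_n)] <- TRUE
    }
  }
  out <- traj
  out$readouts <- traj$readouts[keep, , drop = FALSE]
  out$heartbeat <- traj$heartbeat[keep]
  out$interleaf <- traj$interleaf[keep]
  out$nominal_accel <- sum(traj$shutter) / nrow(out$readouts)
  attr(out, "kept_rows") <- which(keep)
  out
}
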