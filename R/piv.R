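# Coarse-grained 3D particle image velocimetry.
#
# Interrogation windows from frame A are matched against margin-extended
# search regions of frame B by zero-mean normalized cross-correlation
# (robust to background offsets in fluorescence), with per-axis 3-point
# Gaussian sub-voxel peak refinement. Components are reported as (u, v, w)
# in (x, y, z) image order, px/frame, on a coarse node grid.

#' PIV interrogation parameters
#'
#' Defaults follow the standard configuration for ~50-micron epithelial
#' stacks sampled at 1 micron in z: window `(32, 32, 7)`, overlap
#' `(8, 8, 3)`, search margin `(10, 10, 3)`, all in `(x, y, z)` voxels.
#'
#' @param window interrogation window size `(x, y, z)` in voxels.
#' @param overlap tiling overlap `(x, y, z)`; step is `window - overlap`.
#' @param margin extra search extent `(x, y, z)` allowed in frame B.
#' @param min_signal_variance window-validity floor, as a fraction of the
#'   whole-frame intensity variance.
#' @param peak_ratio_threshold minimum ratio of the first to the second
#'   correlation peak (second peak excludes the 3x3x3 neighbourhood of the
#'   first) for a window to be considered valid.
#' @return a `piv_params` object.
#' @export
piv_params <- function(window = c(32, 32, 7), overlap = c(8, 8, 3),
                       margin = c(10, 10, 3), min_signal_variance = 0.01,
                       peak_ratio_threshold = 1.2) {
  assert_that(length(window) == 3 && all(window >= 2), "window must be 3 sizes >= 2")
  assert_that(length(overlap) == 3 && all(overlap >= 0) && all(overlap < window),
              "each overlap must satisfy 0 <= overlap < window")
  assert_that(length(margin) == 3 && all(margin >= 0), "margin components must be >= 0")
  assert_that(min_signal_variance >= 0, "min_signal_variance must be >= 0")
  assert_that(peak_ratio_threshold >= 1, "peak_ratio_threshold must be >= 1")
  structure(list(window = as.integer(window), overlap = as.integer(overlap),
                 margin = as.integer(margin),
                 min_signal_variance = min_signal_variance,
                 peak_ratio_threshold = peak_ratio_threshold),
            class = "piv_params")
}

# Interrogation grid for a (ny, nx, nz) volume: 0-based window starts and
# node centres per axis. Boundary windows whose search region does not fit
# are dropped. Returns NULL if no window fits.
piv_grid <- function(dims, params) {
  w <- params$window; m <- params$margin
  step <- params$window - params$overlap
  starts <- function(N, wi, mi, st) {
    hi <- N - wi - mi
    if (mi > hi) return(NULL)
    seq(mi, hi, by = st)
  }
  sx <- starts(dims[2], w[1], m[1], step[1])
  sy <- starts(dims[1], w[2], m[2], step[2])
  sz <- starts(dims[3], w[3], m[3], step[3])
  if (is.null(sx) || is.null(sy) || is.null(sz)) return(NULL)
  list(sx = sx, sy = sy, sz = sz,
       cx = sx + (w[1] - 1) / 2, cy = sy + (w[2] - 1) / 2,
       cz = sz + (w[3] - 1) / 2)
}

new_velocity_field <- function(u, v, w, valid, grid, pair, dt, params,
                               peak = NULL) {
  structure(list(u = u, v = v, w = w, valid = valid, grid = grid,
                 pair = pair, dt = dt, params = params, peak = peak),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d x %d x %d nodes (y,x,z), %d valid\n",
              dim(x$u)[1], dim(x$u)[2], dim(x$u)[3], sum(x$valid)))
  invisible(x)
}

# 3-point sub-voxel peak refinement along one axis. Gaussian fit when all
# three correlations are positive; parabolic fallback otherwise.
refine_peak_1d <- function(rm, r0, rp) {
  if (is.na(rm) || is.na(rp)) return(0)
  if (rm > 0 && r0 > 0 && rp > 0) {
    den <- log(rm) - 2 * log(r0) + log(rp)
    if (den < 0) return(max(-1, min(1, 0.5 * (log(rm) - log(rp)) / den)))
  }
  den <- rm - 2 * r0 + rp
  if (den < 0) return(max(-1, min(1, 0.5 * (rm - rp) / den)))
  0
}

#' Compute a coarse-grained 3D velocity field between two frames
#'
#' @param frame_a,frame_b 3D numeric arrays `[y, x, z]` of identical shape;
#'   every axis must accommodate `window + 2 * margin`.
#' @param params a [piv_params()].
#' @return a `velocity_field`: arrays `u`, `v`, `w` (px/frame, `(x, y, z)`
#'   components), a `valid` mask, node-centre grid (0-based voxel coords),
#'   and the peak correlation per node. Windows failing the signal-variance
#'   or peak-ratio checks are marked invalid.
#' @export
compute_piv <- function(frame_a, frame_b, params = piv_params()) {
  assert_that(length(dim(frame_a)) == 3 && identical(dim(frame_a), dim(frame_b)),
              "frames must be 3D arrays of identical shape")
  dims <- dim(frame_a)
  w <- params$window; m <- params$margin
  assert_that(dims[2] >= w[1] + 2 * m[1] && dims[1] >= w[2] + 2 * m[2] &&
              dims[3] >= w[3] + 2 * m[3],
              "volume too small for one window plus search margin")
  grid <- piv_grid(dims, params)
  gd <- c(length(grid$sy), length(grid$sx), length(grid$sz))
  u <- v <- wz <- pk <- array(NA_real_, dim = gd)
  valid <- array(FALSE, dim = gd)
  frame_var <- var(as.vector(frame_a))
  var_floor <- params$min_signal_variance * frame_var
  ly <- 2 * m[2] + 1; lx <- 2 * m[1] + 1; lz <- 2 * m[3] + 1

  for (iz in seq_along(grid$sz)) for (ix in seq_along(grid$sx))
    for (iy in seq_along(grid$sy)) {
      ys <- grid$sy[iy]; xs <- grid$sx[ix]; zs <- grid$sz[iz]
      a <- frame_a[(ys + 1):(ys + w[2]), (xs + 1):(xs + w[1]),
                   (zs + 1):(zs + w[3]), drop = FALSE]
      if (var(as.vector(a)) < var_floor) next
      b <- frame_b[(ys - m[2] + 1):(ys + w[2] + m[2]),
                   (xs - m[1] + 1):(xs + w[1] + m[1]),
                   (zs - m[3] + 1):(zs + w[3] + m[3]), drop = FALSE]
      cc <- cpp_zncc_cube(as.numeric(a), as.numeric(b),
                          w[2], w[1], w[3], m[2], m[1], m[3])
      p <- arrayInd(which.max(cc), dim(cc))
      r0 <- cc[p[1], p[2], p[3]]
      # second peak outside the 3x3x3 neighbourhood of the first
      cc2 <- cc
      cc2[max(1, p[1] - 1):min(ly, p[1] + 1),
          max(1, p[2] - 1):min(lx, p[2] + 1),
          max(1, p[3] - 1):min(lz, p[3] + 1)] <- -Inf
      r2 <- suppressWarnings(max(cc2))
      if (is.finite(r2) && r2 > 0 && r0 / r2 < params$peak_ratio_threshold) next
      dy <- dx <- dz <- 0
      if (r0 < 1 - 1e-9) {  # perfect matches are exact; skip refinement
        if (p[1] > 1 && p[1] < ly)
          dy <- refine_peak_1d(cc[p[1] - 1, p[2], p[3]], r0, cc[p[1] + 1, p[2], p[3]])
        if (p[2] > 1 && p[2] < lx)
          dx <- refine_peak_1d(cc[p[1], p[2] - 1, p[3]], r0, cc[p[1], p[2] + 1, p[3]])
        if (p[3] > 1 && p[3] < lz)
          dz <- refine_peak_1d(cc[p[1], p[2], p[3] - 1], r0, cc[p[1], p[2], p[3] + 1])
      }
      u[iy, ix, iz] <- (p[2] - m[1] - 1) + dx
      v[iy, ix, iz] <- (p[1] - m[2] - 1) + dy
      wz[iy, ix, iz] <- (p[3] - m[3] - 1) + dz
      pk[iy, ix, iz] <- r0
      valid[iy, ix, iz] <- TRUE
    }
  new_velocity_field(u, v, wz, valid, grid, pair = 1, dt = NA_real_,
                     params = params, peak = pk)
}

#' Mean speed of a velocity field
#'
#' Arithmetic mean of the Euclidean vector norms over valid nodes.
#'
#' @param field a `velocity_field`.
#' @param pixel_size optional voxel size in micrometres; with `dt`, converts
#'   the result from px/frame to micrometres/min.
#' @param dt optional frame interval in minutes.
#' @return scalar mean speed.
#' @export
mean_speed <- function(field, pixel_size = NULL, dt = NULL) {
  assert_that(inherits(field, "velocity_field"), "field must be a velocity_field")
  ok <- field$valid
  assert_that(any(ok), "no valid nodes in velocity field")
  sp <- sqrt(field$u[ok]^2 + field$v[ok]^2 + field$w[ok]^2)
  out <- mean(sp)
  if (!is.null(pixel_size) && !is.null(dt)) out <- out * pixel_size / dt
  out
}

#' RMS vector error between a velocity field and a reference
#'
#' @param field,truth `velocity_field`s on the same grid.
#' @return root-mean-square Euclidean error over nodes valid in `field`.
#' @export
field_rms_error <- function(field, truth) {
  ok <- field$valid
  assert_that(any(ok), "no valid nodes")
  assert_that(identical(dim(field$u), dim(truth$u)), "grids differ")
  e2 <- (field$u[ok] - truth$u[ok])^2 + (field$v[ok] - truth$v[ok])^2 +
        (field$w[ok] - truth$w[ok])^2
  sqrt(mean(e2))
}
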