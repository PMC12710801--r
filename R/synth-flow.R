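# Synthetic advected particle movies with known velocity fields.
#
# Frames are rendered analytically: Gaussian particles are seeded at
# Poisson-random positions and re-rendered after advecting their positions
# through the prescribed field each frame. This supports exact sub-voxel
# displacements with no cumulative interpolation blur; frame t+1 is frame t
# advected by the field, up to the independent per-frame noise.

FLOW_KINDS <- c("uniform", "rotation", "shear", "split", "random-jitter")

#' Specify a synthetic flow movie
#'
#' @param kind one of `"uniform"`, `"rotation"`, `"shear"`, `"split"`,
#'   `"random-jitter"`.
#' @param displacement length-3 `(x, y, z)` displacement in px/frame
#'   (uniform and split kinds).
#' @param angular_rate rotation rate in rad/frame about the z axis through
#'   the volume centre (rotation kind).
#' @param shear_rate simple-shear rate: `u = shear_rate * (y - cy)` px/frame.
#' @param jitter_sigma per-particle isotropic jitter SD in px
#'   (random-jitter kind; the coarse ground-truth field is zero).
#' @param shape volume shape as `(z, y, x)` voxel counts.
#' @param n_frames number of frames (>= 2).
#' @param density particle density in particles/voxel.
#' @param particle_sigma Gaussian particle radius (px).
#' @param noise_sigma SD of additive Gaussian intensity noise (particle
#'   peak intensity is 1).
#' @param boundary `"periodic"` (particles wrap) or `"pad"` (particles leave).
#' @param dt frame interval (min), metadata only.
#' @param seed integer seed; all randomness in the generator derives from it.
#' @return a `flow_spec` object.
#' @export
flow_spec <- function(kind = "uniform", displacement = c(0, 0, 0),
                      angular_rate = 0.02, shear_rate = 0.05,
                      jitter_sigma = 1, shape = c(13, 64, 64), n_frames = 2,
                      density = 0.01, particle_sigma = 1.5, noise_sigma = 0,
                      boundary = "periodic", dt = 10, seed = 1) {
  kind <- match.arg(kind, FLOW_KINDS)
  boundary <- match.arg(boundary, c("periodic", "pad"))
  assert_that(n_frames >= 2, "n_frames must be >= 2")
  assert_that(density > 0, "density must be > 0")
  assert_that(length(shape) == 3 && all(shape >= 1), "shape must be (z,y,x)")
  assert_that(length(displacement) == 3, "displacement must be (x,y,z)")
  assert_that(particle_sigma > 0, "particle_sigma must be > 0")
  structure(list(kind = kind, displacement = as.numeric(displacement),
                 angular_rate = angular_rate, shear_rate = shear_rate,
                 jitter_sigma = jitter_sigma, shape = as.integer(shape),
                 n_frames = as.integer(n_frames), density = density,
                 particle_sigma = particle_sigma, noise_sigma = noise_sigma,
                 boundary = boundary, dt = dt, seed = as.integer(seed)),
            class = "flow_spec")
}

#' Evaluate a flow spec's deterministic displacement field
#'
#' @param spec a [flow_spec()].
#' @return function mapping an `n x 3` matrix of `(x, y, z)` positions to an
#'   `n x 3` matrix of `(u, v, w)` displacements in px/frame.
#' @export
flow_field_function <- function(spec) {
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  d <- spec$displacement
  switch(spec$kind,
    uniform = function(p) matrix(d, nrow = nrow(p), ncol = 3, byrow = TRUE),
    rotation = function(p) {
      cbind(-spec$angular_rate * (p[, 2] - cy),
             spec$angular_rate * (p[, 1] - cx),
             0)
    },
    shear = function(p) cbind(spec$shear_rate * (p[, 2] - cy), 0, 0),
    split = function(p) {
      s <- sign(p[, 1] - cx)
      cbind(d[1] * s, d[2] * s, d[3] * s)
    },
    `random-jitter` = function(p) matrix(0, nrow = nrow(p), ncol = 3)
  )
}

# Render Gaussian particles into a (ny, nx, nz) array.
# pos: n x 3 matrix of 0-based (x, y, z) centres.
render_particles <- function(pos, dims, sigma, periodic = TRUE) {
  ny <- dims[1]; nx <- dims[2]; nz <- dims[3]
  vol <- array(0, dim = dims)
  if (nrow(pos) == 0) return(vol)
  R <- ceiling(3 * sigma)
  offs <- -R:R
  for (i in seq_len(nrow(pos))) {
    x <- pos[i, 1]; y <- pos[i, 2]; z <- pos[i, 3]
    ix <- round(x) + offs; iy <- round(y) + offs; iz <- round(z) + offs
    wx <- exp(-((ix - x)^2) / (2 * sigma^2))
    wy <- exp(-((iy - y)^2) / (2 * sigma^2))
    wz <- exp(-((iz - z)^2) / (2 * sigma^2))
    if (periodic) {
      jx <- (ix %% nx) + 1; jy <- (iy %% ny) + 1; jz <- (iz %% nz) + 1
    } else {
      kx <- ix >= 0 & ix < nx; ky <- iy >= 0 & iy < ny; kz <- iz >= 0 & iz < nz
      if (!any(kx) || !any(ky) || !any(kz)) next
      jx <- ix[kx] + 1; jy <- iy[ky] + 1; jz <- iz[kz] + 1
      wx <- wx[kx]; wy <- wy[ky]; wz <- wz[kz]
    }
    patch <- outer(outer(wy, wx), wz)
    vol[jy, jx, jz] <- vol[jy, jx, jz] + patch
  }
  vol
}

#' Generate an advected particle movie with ground-truth velocity fields
#'
#' Particles are seeded uniformly at a Poisson-distributed count, rendered
#' as Gaussian blobs, advected by the prescribed field between frames
#' (periodic wrap or loss at the boundary per the spec), and independent
#' Gaussian noise is added per frame. The ground-truth displacement field is
#' evaluated at the interrogation-grid node centres the PIV stage will use.
#'
#' @param spec a [flow_spec()].
#' @param piv a [piv_params()]; defines the coarse grid for the returned
#'   ground truth.
#' @return list with `volumes` (a [volume_series()]), `truth` (list of
#'   ground-truth `velocity_field` objects, one per frame pair), `field`
#'   (the displacement-field function), `particles` (per-frame positions),
#'   `spec`, and `warnings` (provenance notes, e.g. displacement exceeding
#'   the PIV search margin).
#' @export
generate_flow_movie <- function(spec, piv = piv_params()) {
  assert_that(inherits(spec, "flow_spec"), "spec must be a flow_spec")
  dims <- c(spec$shape[2], spec$shape[3], spec$shape[1])  # (ny, nx, nz)
  nvox <- prod(dims)
  fieldf <- flow_field_function(spec)
  warnings <- character(0)

  res <- with_seed(spec$seed, {
    n <- max(1, rpois(1, spec$density * nvox))
    pos <- cbind(runif(n, 0, dims[2]), runif(n, 0, dims[1]), runif(n, 0, dims[3]))
    frames <- vector("list", spec$n_frames)
    particles <- vector("list", spec$n_frames)
    for (t in seq_len(spec$n_frames)) {
      particles[[t]] <- pos
      fr <- render_particles(pos, dims, spec$particle_sigma,
                             periodic = spec$boundary == "periodic")
      if (spec$noise_sigma > 0)
        fr <- fr + array(rnorm(nvox, 0, spec$noise_sigma), dim = dims)
      frames[[t]] <- fr
      if (t < spec$n_frames) {
        disp <- fieldf(pos)
        if (spec$kind == "random-jitter" && spec$jitter_sigma > 0)
          disp <- disp + matrix(rnorm(3 * nrow(pos), 0, spec$jitter_sigma),
                                ncol = 3)
        pos <- pos + disp
        if (spec$boundary == "periodic") {
          pos[, 1] <- pos[, 1] %% dims[2]
          pos[, 2] <- pos[, 2] %% dims[1]
          pos[, 3] <- pos[, 3] %% dims[3]
        }
      }
    }
    list(frames = frames, particles = particles)
  })

  vs <- volume_series(res$frames, dt = spec$dt)
  grid <- piv_grid(dims, piv)
  truth <- list()
  if (!is.null(grid)) {
    nodes <- expand.grid(y = grid$cy, x = grid$cx, z = grid$cz)
    P <- cbind(nodes$x, nodes$y, nodes$z)
    gd <- c(length(grid$cy), length(grid$cx), length(grid$cz))
    for (t in seq_len(spec$n_frames - 1)) {
      disp <- fieldf(P)
      mx <- apply(abs(disp), 2, max)
      lim <- piv$margin  # (x, y, z)
      if (any(mx > lim)) {
        w <- sprintf(
          "frame pair %d: max |displacement| (%.2f, %.2f, %.2f) exceeds search margin (%d, %d, %d); PIV cannot recover it",
          t, mx[1], mx[2], mx[3], lim[1], lim[2], lim[3])
        warnings <- c(warnings, w)
        warning(w)
      }
      truth[[t]] <- new_velocity_field(
        u = array(disp[, 1], dim = gd), v = array(disp[, 2], dim = gd),
        w = array(disp[, 3], dim = gd),
        valid = array(TRUE, dim = gd), grid = grid, pair = t, dt = spec$dt,
        params = piv)
    }
  }
  list(volumes = vs, truth = truth, field = fieldf,
       particles = res$particles, spec = spec, warnings = warnings)
}
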