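# Synthetic clustered cell trajectories with prescribed dispersal dynamics.
#
# Each cluster's cells sit equally spaced on a circle of radius r(t) equal
# to the target standard distance, about a (possibly drifting) centroid,
# then receive isotropic Gaussian jitter. Equally spaced points on a circle
# of radius r have x-variance + y-variance = r^2 about their centroid, so
# with zero jitter the measured standard distance reproduces the target
# exactly at every frame — a closed-form acceptance surface.

#' Specify synthetic cluster dynamics
#'
#' @param n_clusters number of clusters.
#' @param cells_per_cluster cells per cluster, in `[4, 8]`.
#' @param model target standard-distance curve: `list(type = "linear",
#'   a, b)` for `SD(t) = a t + b` or `list(type = "quadratic", a, b, c)`
#'   for `SD(t) = a t^2 + b t + c`, with t in minutes.
#' @param jitter_sigma per-cell isotropic positional noise SD (px).
#' @param dt frame interval (min).
#' @param n_frames frames per cluster.
#' @param drift common centroid drift `(x, y)` in px/frame (default none).
#' @param field_size arena size `(x, y)` px for centroid placement.
#' @param seed integer seed.
#' @return a `cluster_dynamics_spec`.
#' @export
cluster_dynamics_spec <- function(n_clusters = 10, cells_per_cluster = 6,
                                  model = list(type = "linear", a = 2, b = 1),
                                  jitter_sigma = 0.5, dt = 10, n_frames = 13,
                                  drift = c(0, 0), field_size = c(512, 512),
                                  seed = 1) {
  assert_that(n_clusters >= 1, "n_clusters must be >= 1")
  assert_that(cells_per_cluster >= 4 && cells_per_cluster <= 8,
              "cells_per_cluster must lie in [4, 8]")
  assert_that(model$type %in% c("linear", "quadratic"),
              "model type must be linear or quadratic")
  assert_that(n_frames >= 2, "n_frames must be >= 2")
  assert_that(jitter_sigma >= 0, "jitter_sigma must be >= 0")
  t <- (seq_len(n_frames) - 1) * dt
  target <- target_sd(model, t)
  assert_that(all(target > 0),
              "target SD(t) must be > 0 at every generated frame")
  structure(list(n_clusters = as.integer(n_clusters),
                 cells_per_cluster = as.integer(cells_per_cluster),
                 model = model, jitter_sigma = jitter_sigma, dt = dt,
                 n_frames = as.integer(n_frames), drift = as.numeric(drift),
                 field_size = as.numeric(field_size), seed = as.integer(seed)),
            class = "cluster_dynamics_spec")
}

target_sd <- function(model, t) {
  if (model$type == "linear") model$a * t + model$b
  else model$a * t^2 + model$b * t + model$c
}

#' Generate clustered trajectories with known dispersal dynamics
#'
#' @param spec a [cluster_dynamics_spec()].
#' @return list with `tracks` (a [trajectory_set()] including a
#'   `cluster_id` column), `clusters` (list of `cell_cluster` objects with
#'   the true membership), and `truth` (the model, per-cluster phases and
#'   centroids, and the seed).
#' @export
generate_cluster_trajectories <- function(spec) {
  assert_that(inherits(spec, "cluster_dynamics_spec"),
              "spec must be a cluster_dynamics_spec")
  m <- spec$cells_per_cluster
  t_min <- (seq_len(spec$n_frames) - 1) * spec$dt
  r <- target_sd(spec$model, t_min)
  margin <- max(r) + 10 * (spec$jitter_sigma + 1)
  with_seed(spec$seed, {
    rows <- vector("list", spec$n_clusters)
    clusters <- vector("list", spec$n_clusters)
    phases <- runif(spec$n_clusters, 0, 2 * pi)
    cent0 <- cbind(runif(spec$n_clusters, margin, spec$field_size[1] - margin),
                   runif(spec$n_clusters, margin, spec$field_size[2] - margin))
    for (j in seq_len(spec$n_clusters)) {
      theta <- phases[j] + 2 * pi * (seq_len(m) - 1) / m
      ids <- (j - 1) * m + seq_len(m)
      per_frame <- vector("list", spec$n_frames)
      for (k in seq_len(spec$n_frames)) {
        cen <- cent0[j, ] + spec$drift * (k - 1)
        x <- cen[1] + r[k] * cos(theta)
        y <- cen[2] + r[k] * sin(theta)
        if (spec$jitter_sigma > 0) {
          x <- x + rnorm(m, 0, spec$jitter_sigma)
          y <- y + rnorm(m, 0, spec$jitter_sigma)
        }
        per_frame[[k]] <- data.frame(track_id = ids, cluster_id = j,
                                     frame = k - 1, x = x, y = y, z = 0)
      }
      rows[[j]] <- do.call(rbind, per_frame)
      clusters[[j]] <- structure(
        list(members = ids, t0 = 0,
             convergent_point = c(x = cent0[j, 1], y = cent0[j, 2])),
        class = "cell_cluster")
    }
    tracks <- trajectory_set(do.call(rbind, rows), dt = spec$dt)
    list(tracks = tracks, clusters = clusters,
         truth = list(model = spec$model, phases = phases, centroids = cent0,
                      seed = spec$seed))
  })
}

#' Write / read trajectory CSV
#'
#' The plain dialect has columns `track_id`, `cluster_id` (optional),
#' `frame`, `x`, `y`, `z` (optional).
#'
#' @param tracks a [trajectory_set()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}
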