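# Cell-cluster dispersal: trajectory container, cluster identification,
# the standard-distance statistic, dispersal series and track speed.

#' Construct a trajectory set
#'
#' @param df data.frame with columns `track_id`, `frame`, `x`, `y` and
#'   optional `z`, `cluster_id`; one row per cell per frame, pixel units,
#'   0-based frames.
#' @param dt frame interval in minutes.
#' @return a `trajectory_set` (data.frame, frame-sorted within track, with
#'   `dt` attribute).
#' @export
trajectory_set <- function(df, dt = 10) {
  req <- c("track_id", "frame", "x", "y")
  assert_that(all(req %in% names(df)),
              "missing column(s): ", paste(setdiff(req, names(df)), collapse = ", "))
  assert_that(dt > 0, "dt must be positive")
  assert_that(all(is.finite(df$x)) && all(is.finite(df$y)),
              "coordinates must be finite")
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  dup <- duplicated(df[, c("track_id", "frame")])
  assert_that(!any(dup), "duplicate (track_id, frame) rows: frames must be strictly increasing within a track")
  rownames(df) <- NULL
  structure(df, class = c("trajectory_set", "data.frame"), dt = dt)
}

ts_dt <- function(tracks) attr(tracks, "dt") %||% 10

# positions of all tracks alive (sampled) at a frame
positions_at <- function(tracks, frame) {
  sub <- tracks[tracks$frame == frame, , drop = FALSE]
  sub[, c("track_id", "x", "y"), drop = FALSE]
}

#' Identify cell clusters around convergent points
#'
#' A convergent point is a cell position at `t0` whose `radius`
#' neighbourhood contains at least `min_size` cells (itself included).
#' Candidate points are enumerated deterministically; clusters are then
#' drawn in seeded random order without track reuse, and membership above
#' `max_size` is reduced by seeded random subsampling.
#'
#' @param tracks a [trajectory_set()].
#' @param t0 reference frame (0-based).
#' @param radius convergence radius in px (default 15).
#' @param min_size,max_size cluster size bounds (defaults 4 and 8).
#' @param seed integer seed controlling candidate order and subsampling.
#' @param allow_overlap if `FALSE` (default), a track joins at most one
#'   cluster.
#' @return list of `cell_cluster` objects (fields `members`, `t0`,
#'   `convergent_point`); empty list when no candidate exists.
#' @export
identify_clusters <- function(tracks, t0, radius = 15, min_size = 4,
                              max_size = 8, seed = 1, allow_overlap = FALSE) {
  assert_that(min_size >= 2 && max_size >= min_size, "bad size bounds")
  pos <- positions_at(tracks, t0)
  if (nrow(pos) < min_size) return(list())
  D <- as.matrix(dist(pos[, c("x", "y")]))
  n_near <- rowSums(D <= radius)  # includes self
  cand <- which(n_near >= min_size)
  if (!length(cand)) return(list())
  with_seed(seed, {
    ord <- sample(cand)
    used <- rep(FALSE, nrow(pos))
    clusters <- list()
    for (ci in ord) {
      memb <- which(D[ci, ] <= radius)
      if (!allow_overlap) memb <- memb[!used[memb]]
      if (length(memb) < min_size) next
      if (length(memb) > max_size) memb <- sort(sample(memb, max_size))
      if (!allow_overlap) used[memb] <- TRUE
      clusters[[length(clusters) + 1]] <- structure(
        list(members = pos$track_id[memb], t0 = t0,
             convergent_point = c(x = pos$x[ci], y = pos$y[ci])),
        class = "cell_cluster")
    }
    clusters
  })
}

#' Standard distance of a 2D point set
#'
#' The dispersion statistic
#' \deqn{SD = \sqrt{\sum_i (x_i - \bar X)^2 / n + \sum_i (y_i - \bar Y)^2 / n}}
#' i.e. the square root of the summed per-axis mean squared deviations from
#' the centroid (the root of the trace of the covariance computed with
#' denominator n).
#'
#' @param points two-column matrix or data.frame of `(x, y)` positions,
#'   n >= 2 rows.
#' @return scalar standard distance in the units of the coordinates.
#' @export
standard_distance <- function(points) {
  points <- as.matrix(points)
  assert_that(nrow(points) >= 2, "standard distance needs at least 2 points")
  assert_that(ncol(points) >= 2 && all(is.finite(points[, 1:2])),
              "points must be finite (x, y)")
  x <- points[, 1]; y <- points[, 2]
  sqrt(sum((x - mean(x))^2) / length(x) + sum((y - mean(y))^2) / length(y))
}

#' Standard-distance series of a cluster over time
#'
#' @param cluster a `cell_cluster` (see [identify_clusters()]).
#' @param tracks a [trajectory_set()] containing every member over
#'   `[t0, t_end]`.
#' @param t_end last frame (0-based). Trunk analyses conventionally use an
#'   8-hour window and tip analyses a shorter 2-hour window.
#' @param group optional group label carried into inference.
#' @param cluster_id optional identifier.
#' @return a `dispersal_series`: data.frame with `time` (minutes from `t0`)
#'   and `sd` (px), plus metadata attributes. Errors if a member track ends
#'   before `t_end`.
#' @export
dispersal_series <- function(cluster, tracks, t_end, group = NA_character_,
                             cluster_id = NA) {
  assert_that(inherits(cluster, "cell_cluster"), "cluster must be a cell_cluster")
  assert_that(t_end >= cluster$t0, "t_end must be >= t0")
  dt <- ts_dt(tracks)
  frames <- cluster$t0:t_end
  sdv <- numeric(length(frames))
  sub <- tracks[tracks$track_id %in% cluster$members, , drop = FALSE]
  for (i in seq_along(frames)) {
    p <- sub[sub$frame == frames[i], c("track_id", "x", "y"), drop = FALSE]
    if (nrow(p) < length(cluster$members))
      stop_mf("cluster ", cluster_id, ": track(s) ",
              paste(setdiff(cluster$members, p$track_id), collapse = ", "),
              " not sampled at frame ", frames[i],
              " - cluster excluded from analysis")
    sdv[i] <- standard_distance(p[, c("x", "y")])
  }
  new_dispersal_series(time = (frames - cluster$t0) * dt, sd = sdv,
                       cluster_id = cluster_id, group = group)
}

new_dispersal_series <- function(time, sd, cluster_id = NA,
                                 group = NA_character_, normalized = FALSE) {
  assert_that(length(time) == length(sd), "time/sd length mismatch")
  structure(data.frame(time = time, sd = sd),
            class = c("dispersal_series", "data.frame"),
            cluster_id = cluster_id, group = group, normalized = normalized)
}

#' Normalize a dispersal series to its first time point
#'
#' @param series a `dispersal_series`.
#' @return the series with every value divided by the first value (which
#'   becomes 1) and the `normalized` attribute set.
#' @export
normalize_series <- function(series) {
  assert_that(inherits(series, "dispersal_series"), "series must be a dispersal_series")
  assert_that(series$sd[1] > 0,
              "cannot normalize: standard distance at the first time point is ",
              series$sd[1])
  out <- series
  out$sd <- series$sd / series$sd[1]
  attr(out, "normalized") <- TRUE
  out
}

#' Track speed: path length over elapsed time
#'
#' Total path length (sum of per-step Euclidean displacements, using z when
#' present) divided by elapsed time.
#'
#' @param track data.frame with columns `frame`, `x`, `y` and optional `z`
#'   for a single track.
#' @param dt frame interval in minutes.
#' @return speed in px/min.
#' @export
track_speed <- function(track, dt = 10) {
  assert_that(nrow(track) >= 2, "track speed needs at least 2 samples")
  track <- track[order(track$frame), , drop = FALSE]
  dx <- diff(track$x); dy <- diff(track$y)
  dz <- if ("z" %in% names(track) && all(is.finite(track$z))) diff(track$z) else 0
  path <- sum(sqrt(dx^2 + dy^2 + dz^2))
  elapsed <- (max(track$frame) - min(track$frame)) * dt
  assert_that(elapsed > 0, "track spans zero time")
  path / elapsed
}
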