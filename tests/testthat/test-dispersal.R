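# Standard distance, cluster identification, series, track speed.

test_that("standard_distance: closed forms and brute-force oracle", {
  expect_equal(standard_distance(cbind(c(1, 1, 1), c(2, 2, 2))), 0)
  expect_equal(standard_distance(cbind(c(1, 1, -1, -1), c(1, -1, 1, -1))),
               sqrt(2), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    pts <- matrix(rnorm(12, sd = 20), ncol = 2)
    expect_equal(standard_distance(pts), bf_standard_distance(pts),
                 tolerance = 1e-12)
  }
  expect_error(standard_distance(matrix(1:2, ncol = 2)), "at least 2")
})

test_that("standard_distance is translation/rotation invariant, scales linearly", {
  set.seed(5)
  pts <- matrix(rnorm(14), ncol = 2)
  s0 <- standard_distance(pts)
  expect_equal(standard_distance(sweep(pts, 2, c(100, -40), "+")), s0,
               tolerance = 1e-9)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(standard_distance(pts %*% R), s0, tolerance = 1e-9)
  expect_equal(standard_distance(3.5 * pts), 3.5 * s0, tolerance = 1e-9)
})

test_that("identify_clusters: trivial configurations", {
  # 5 cells near one point, others isolated
  df <- data.frame(track_id = 1:8, frame = 0,
                   x = c(10, 12, 14, 11, 13, 200, 300, 400),
                   y = c(10, 11, 12, 14, 10, 200, 300, 400))
  ts <- trajectory_set(df, dt = 10)
  cl <- identify_clusters(ts, t0 = 0, radius = 15, seed = 1)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, 1:5)
  # only 3 co-located cells: below min_size
  df3 <- data.frame(track_id = 1:3, frame = 0, x = c(1, 2, 3), y = c(1, 2, 3))
  expect_length(identify_clusters(trajectory_set(df3), t0 = 0, seed = 1), 0)
})

test_that("identify_clusters is seeded-deterministic and within the candidate set", {
  set.seed(17)
  df <- data.frame(track_id = 1:60, frame = 0,
                   x = runif(60, 0, 120), y = runif(60, 0, 120))
  ts <- trajectory_set(df, dt = 10)
  c1 <- identify_clusters(ts, t0 = 0, radius = 15, seed = 7)
  c2 <- identify_clusters(ts, t0 = 0, radius = 15, seed = 7)
  expect_identical(c1, c2)
  # exhaustive oracle: every reported cluster sits inside the radius
  # neighbourhood of its convergent point, with size in [4, 8], no reuse
  used <- integer(0)
  for (cl in c1) {
    expect_true(length(cl$members) >= 4 && length(cl$members) <= 8)
    expect_length(intersect(used, cl$members), 0)
    used <- c(used, cl$members)
    pos <- df[df$track_id %in% cl$members, ]
    d <- sqrt((pos$x - cl$convergent_point["x"])^2 +
              (pos$y - cl$convergent_point["y"])^2)
    expect_true(all(d <= 15))
    # the convergent point must be a brute-force candidate
    nbh <- sum(sqrt((df$x - cl$convergent_point["x"])^2 +
                    (df$y - cl$convergent_point["y"])^2) <= 15)
    expect_gte(nbh, 4)
  }
})

test_that("dispersal_series matches frame-wise standard_distance", {
  sp <- cluster_dynamics_spec(n_clusters = 1, cells_per_cluster = 6,
                              model = list(type = "linear", a = 0.5, b = 5),
                              jitter_sigma = 1, dt = 10, n_frames = 6, seed = 3)
  g <- generate_cluster_trajectories(sp)
  s <- dispersal_series(g$clusters[[1]], g$tracks, 5)
  for (k in 0:5) {
    p <- g$tracks[g$tracks$frame == k, c("x", "y")]
    expect_equal(s$sd[k + 1], bf_standard_distance(as.matrix(p)),
                 tolerance = 1e-12)
  }
  expect_equal(s$time, (0:5) * 10)
})

test_that("a member track ending early excludes the cluster with a message", {
  sp <- cluster_dynamics_spec(n_clusters = 1, seed = 4, n_frames = 5)
  g <- generate_cluster_trajectories(sp)
  trunc <- g$tracks[!(g$tracks$track_id == 1 & g$tracks$frame > 2), ]
  ts <- trajectory_set(as.data.frame(trunc), dt = 10)
  expect_error(dispersal_series(g$clusters[[1]], ts, 4), "not sampled")
})

test_that("normalize_series: examples and element-wise oracle", {
  s <- mk_series(c(0, 10, 20), c(2, 4, 6))
  expect_equal(normalize_series(s)$sd, c(1, 2, 3))
  sc <- mk_series(c(0, 10), c(5, 5))
  expect_equal(normalize_series(sc)$sd, c(1, 1))
  set.seed(6)
  sr <- mk_series(0:9, runif(10, 1, 20))
  expect_equal(normalize_series(sr)$sd, sr$sd / sr$sd[1], tolerance = 1e-12)
  expect_error(normalize_series(mk_series(0:2, c(0, 1, 2))), "first time point")
})

test_that("track_speed: trivial values and step-sum oracle", {
  still <- data.frame(frame = 0:5, x = 3, y = 4)
  expect_equal(track_speed(still, dt = 10), 0)
  straight <- data.frame(frame = 0:5, x = 2 * (0:5), y = 0)
  expect_equal(track_speed(straight, dt = 10), 0.2)
  set.seed(9)
  rw <- data.frame(frame = 0:19, x = cumsum(rnorm(20)), y = cumsum(rnorm(20)))
  steps <- sum(sqrt(diff(rw$x)^2 + diff(rw$y)^2))
  expect_equal(track_speed(rw, dt = 5), steps / (19 * 5), tolerance = 1e-12)
  expect_error(track_speed(rw[1, , drop = FALSE]), "at least 2")
})

test_that("trajectory_set validates its input", {
  expect_error(trajectory_set(data.frame(track_id = 1, frame = 0, x = 1)),
               "missing column")
  expect_error(trajectory_set(data.frame(track_id = c(1, 1), frame = c(0, 0),
                                         x = 1:2, y = 1:2)), "duplicate")
  expect_error(trajectory_set(data.frame(track_id = 1, frame = 0, x = NaN,
                                         y = 1)), "finite")
})
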