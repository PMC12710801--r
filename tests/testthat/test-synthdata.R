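# Synthetic-data module: generators, ground truth, seeded determinism.

test_that("flow movie: identity and integer-roll advection by construction", {
  sp0 <- flow_spec(kind = "uniform", displacement = c(0, 0, 0),
                   shape = c(13, 52, 52), density = 0.02, seed = 3)
  mv0 <- generate_flow_movie(sp0)
  expect_identical(mv0$volumes$frames[[1]], mv0$volumes$frames[[2]])

  sp <- flow_spec(kind = "uniform", displacement = c(4, 2, 1),
                  shape = c(13, 52, 52), density = 0.02, seed = 3)
  mv <- generate_flow_movie(sp)
  expect_equal(mv$volumes$frames[[2]],
               shift3(mv$volumes$frames[[1]], 4, 2, 1), tolerance = 1e-12)
  # ground truth on the PIV grid matches the prescribed displacement
  expect_true(all(mv$truth[[1]]$u == 4) && all(mv$truth[[1]]$v == 2) &&
              all(mv$truth[[1]]$w == 1))
})

test_that("rotation ground truth matches brute-force kinematics at random voxels", {
  sp <- flow_spec(kind = "rotation", angular_rate = 0.03, shape = c(13, 80, 80),
                  density = 0.01, seed = 9)
  f <- flow_field_function(sp)
  set.seed(42)
  P <- cbind(runif(100, 0, 79), runif(100, 0, 79), runif(100, 0, 12))
  disp <- f(P)
  cx <- (80 - 1) / 2; cy <- (80 - 1) / 2
  radius <- sqrt((P[, 1] - cx)^2 + (P[, 2] - cy)^2)
  expect_equal(sqrt(rowSums(disp^2)), 0.03 * radius, tolerance = 1e-12)
})

test_that("flow ground truth is consistent with the advection actually applied", {
  sp <- flow_spec(kind = "shear", shear_rate = 0.08, shape = c(9, 48, 48),
                  density = 0.03, noise_sigma = 0, seed = 5, boundary = "pad")
  mv <- generate_flow_movie(sp)
  # independently re-advect the frame-1 particles and re-render
  p2 <- mv$particles[[1]] + mv$field(mv$particles[[1]])
  re <- morphoflow:::render_particles(p2, dim(mv$volumes$frames[[1]]),
                                      sp$particle_sigma, periodic = FALSE)
  expect_equal(re, mv$volumes$frames[[2]], tolerance = 1e-12)
})

test_that("flow movie warns when displacement exceeds the search margin", {
  sp <- flow_spec(kind = "uniform", displacement = c(12, 0, 0),
                  shape = c(13, 64, 64), density = 0.01, seed = 1)
  expect_warning(mv <- generate_flow_movie(sp), "exceeds search margin")
  expect_gt(length(mv$warnings), 0)
})

test_that("flow spec validates its invariants", {
  expect_error(flow_spec(n_frames = 1), "n_frames")
  expect_error(flow_spec(density = 0), "density")
  expect_error(flow_spec(kind = "vortex"), "arg")
})

test_that("noiseless clusters reproduce the target SD exactly", {
  sp <- cluster_dynamics_spec(n_clusters = 3, cells_per_cluster = 5,
                              model = list(type = "linear", a = 2, b = 1),
                              jitter_sigma = 0, dt = 1, n_frames = 5, seed = 5)
  g <- generate_cluster_trajectories(sp)
  for (cl in g$clusters) {
    s <- dispersal_series(cl, g$tracks, 4)
    expect_equal(s$sd, c(1, 3, 5, 7, 9), tolerance = 1e-9)
  }
})

test_that("noiseless quadratic clusters round-trip their coefficients", {
  sp <- cluster_dynamics_spec(n_clusters = 2, cells_per_cluster = 6,
                              model = list(type = "quadratic", a = 1, b = -2, c = 3),
                              jitter_sigma = 0, dt = 1, n_frames = 8, seed = 2)
  # SD(t) = t^2 - 2t + 3 > 0 for all t
  g <- generate_cluster_trajectories(sp)
  s <- dispersal_series(g$clusters[[1]], g$tracks, 7)
  fit <- fit_quadratic_trend(s)
  expect_equal(c(fit$a, fit$b, fit$c), c(1, -2, 3), tolerance = 1e-8)
})

test_that("cluster spec rejects non-positive target SD and bad sizes", {
  expect_error(cluster_dynamics_spec(model = list(type = "linear", a = -1, b = 1),
                                     dt = 1, n_frames = 5), "target SD")
  expect_error(cluster_dynamics_spec(cells_per_cluster = 3), "\\[4, 8\\]")
  expect_error(cluster_dynamics_spec(cells_per_cluster = 9), "\\[4, 8\\]")
})

test_that("common centroid drift leaves the SD series unchanged", {
  base <- list(n_clusters = 2, model = list(type = "linear", a = 1.5, b = 2),
               jitter_sigma = 0, dt = 1, n_frames = 6, seed = 8)
  g0 <- generate_cluster_trajectories(do.call(cluster_dynamics_spec, base))
  g1 <- generate_cluster_trajectories(do.call(cluster_dynamics_spec,
                                              c(base, list(drift = c(3, -2)))))
  s0 <- dispersal_series(g0$clusters[[1]], g0$tracks, 5)
  s1 <- dispersal_series(g1$clusters[[1]], g1$tracks, 5)
  expect_equal(s0$sd, s1$sd, tolerance = 1e-9)
})

test_that("tree specs carry graph-oracle ground truth", {
  bar <- tubule_tree_spec(data.frame(x0 = 30, y0 = 100, x1 = 170, y1 = 100,
                                     width = 5))
  expect_identical(bar$ground_truth_tips, 2L)
  ytree <- tubule_tree_spec(data.frame(x0 = c(100, 100, 100),
                                       y0 = c(170, 100, 100),
                                       x1 = c(100, 40, 160),
                                       y1 = c(100, 40, 40), width = 5))
  expect_identical(ytree$ground_truth_tips, 3L)
  # random trees: tips == degree-1 node count == n_bifurcations + 1
  for (d in 2:6) {
    rt <- random_tree_spec(d, seed = d + 10)
    deg <- morphoflow:::graph_degrees(rt$graph)
    expect_identical(rt$ground_truth_tips, sum(deg == 1))
    expect_identical(rt$ground_truth_tips, d + 1L)
  }
})

test_that("disconnected segment sets are rejected", {
  segs <- data.frame(x0 = c(10, 100), y0 = c(10, 100),
                     x1 = c(30, 150), y1 = c(10, 100), width = 4)
  expect_error(tubule_tree_spec(segs), "connected")
})

test_that("division angles: range, distributions, determinism", {
  a <- generate_division_angles(2000, "uniform", seed = 3)
  expect_true(all(a >= 0 & a <= 90))
  ac <- generate_division_angles(2000, "concentrated", mu = 0, kappa = 50,
                                 seed = 4)
  expect_true(all(ac >= 0 & ac <= 90))
  expect_lt(mean(ac), 10)
  expect_identical(generate_division_angles(1, "uniform", seed = 7),
                   generate_division_angles(1, "uniform", seed = 7))
  expect_error(generate_division_angles(0), "positive")
})

test_that("fixed seed gives bit-identical generator output", {
  sp <- flow_spec(kind = "random-jitter", jitter_sigma = 1, noise_sigma = 0.1,
                  shape = c(7, 32, 32), seed = 77)
  expect_identical(generate_flow_movie(sp)$volumes$frames,
                   generate_flow_movie(sp)$volumes$frames)
  cs <- cluster_dynamics_spec(seed = 13)
  expect_identical(generate_cluster_trajectories(cs)$tracks$x,
                   generate_cluster_trajectories(cs)$tracks$x)
  rt1 <- random_tree_spec(4, seed = 5, noise_sigma = 3)
  rt2 <- random_tree_spec(4, seed = 5, noise_sigma = 3)
  expect_identical(generate_tree_image(rt1)$image,
                   generate_tree_image(rt2)$image)
})
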