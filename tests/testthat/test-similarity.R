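# Motion similarity and coherence profiles.

mk_field <- function(u, v, w, valid = NULL) {
  d <- dim(u)
  structure(list(u = u, v = v, w = w,
                 valid = valid %||% array(TRUE, dim = d),
                 grid = NULL, pair = 1, dt = 10, params = NULL),
            class = "velocity_field")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

const_field <- function(d, vec) {
  mk_field(array(vec[1], dim = d), array(vec[2], dim = d), array(vec[3], dim = d))
}

test_that("uniform field has similarity 1 everywhere (normalized)", {
  f <- const_field(c(6, 8, 2), c(2, -1, 0.5))
  m <- motion_similarity_map(f)
  expect_true(all(m$valid))
  expect_equal(unname(m$values[m$valid]), rep(1, sum(m$valid)), tolerance = 1e-12)
})

test_that("antiparallel neighbours give -1", {
  # checkerboard of +x / -x unit vectors: every neighbour is antiparallel
  d <- c(6, 6, 1)
  sgn <- outer(1:6, 1:6, function(y, x) ifelse((x + y) %% 2 == 0, 1, -1))
  f <- mk_field(array(sgn, dim = d), array(0, dim = d), array(0, dim = d))
  m <- motion_similarity_map(f)
  expect_equal(unname(m$values[m$valid]), rep(-1, sum(m$valid)), tolerance = 1e-12)
})

test_that("raw mode scales with magnitude, normalized mode does not", {
  d <- c(4, 4, 1)
  f <- const_field(d, c(3, 0, 0))
  expect_equal(unname(motion_similarity_map(f, mode = "raw")$values[2, 2, 1]), 9)
  expect_equal(unname(motion_similarity_map(f, mode = "normalized")$values[2, 2, 1]), 1)
})

test_that("normalized similarity is bounded and invariant to rotation/scaling", {
  set.seed(31)
  d <- c(10, 10, 2)
  n <- prod(d)
  u <- array(rnorm(n), dim = d); v <- array(rnorm(n), dim = d)
  w <- array(rnorm(n), dim = d)
  m0 <- motion_similarity_map(mk_field(u, v, w))
  expect_true(all(m0$values[m0$valid] >= -1 - 1e-12 &
                  m0$values[m0$valid] <= 1 + 1e-12))
  # global rotation of all vectors (about z by 0.7 rad)
  th <- 0.7
  m1 <- motion_similarity_map(mk_field(cos(th) * u - sin(th) * v,
                                       sin(th) * u + cos(th) * v, w))
  expect_equal(m0$values, m1$values, tolerance = 1e-9)
  # global positive rescaling
  m2 <- motion_similarity_map(mk_field(3.7 * u, 3.7 * v, 3.7 * w))
  expect_equal(m0$values, m2$values, tolerance = 1e-9)
})

test_that("zero vectors invalidate their node in normalized mode", {
  d <- c(4, 4, 1)
  u <- array(1, dim = d); u[2, 2, 1] <- 0
  f <- mk_field(u, array(0, dim = d), array(0, dim = d))
  m <- motion_similarity_map(f)
  expect_false(m$valid[2, 2, 1])
  expect_true(m$valid[1, 1, 1])
})

test_that("isotropic random unit vectors have grid-mean similarity near 0", {
  set.seed(99)
  d <- c(100, 100, 1)
  n <- prod(d)
  g <- matrix(rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  m <- motion_similarity_map(mk_field(array(g[, 1], dim = d),
                                      array(g[, 2], dim = d),
                                      array(g[, 3], dim = d)))
  expect_lt(abs(mean(m$values[m$valid])), 0.05)
})

test_that("coherence lines: placement rule and node-set oracle", {
  # uniform field: every line mean 1, sd 0
  f <- const_field(c(7, 9, 1), c(1, 1, 0))
  m <- motion_similarity_map(f)
  pr <- coherence_profile(m, n_lines = 3, axis = "x")
  expect_equal(pr$mean, rep(1, 3))
  expect_equal(pr$sd, rep(0, 3))
  # n_lines = 1 on a 3-row grid samples the middle row
  f3 <- const_field(c(3, 9, 1), c(1, 0, 0))
  m3 <- motion_similarity_map(f3)
  pr3 <- coherence_profile(m3, n_lines = 1, axis = "x")
  expect_identical(pr3$cross_index, 2)
  # two opposing halves along the line axis: means below 1, matching a
  # manual node-set computation
  d <- c(5, 10, 1)
  u <- array(1, dim = d); u[, 6:10, 1] <- -1
  fh <- mk_field(u, array(0, dim = d), array(0, dim = d))
  mh <- motion_similarity_map(fh)
  prh <- coherence_profile(mh, n_lines = 3, axis = "x")
  for (k in 1:3) {
    row <- prh$cross_index[k]
    vals <- mh$values[row, , 1][mh$valid[row, , 1]]
    expect_equal(prh$mean[k], mean(vals), tolerance = 1e-12)
    expect_lt(prh$mean[k], 1)
  }
})

test_that("lines with no valid nodes are reported missing", {
  d <- c(5, 6, 1)
  f <- const_field(d, c(1, 0, 0))
  m <- motion_similarity_map(f)
  m$valid[2, , 1] <- FALSE  # knock out the row line 1 samples
  m$values[2, , 1] <- NA
  pr <- coherence_profile(m, n_lines = 3, axis = "x")
  expect_true(pr$missing[pr$cross_index == 2])
  expect_false(any(pr$missing[pr$cross_index != 2]))
})

test_that("degenerate grids are rejected", {
  f <- const_field(c(1, 5, 1), c(1, 0, 0))
  expect_error(motion_similarity_map(f), ">= 2 nodes")
  f2 <- const_field(c(2, 2, 1), c(1, 0, 0))
  expect_error(coherence_profile(motion_similarity_map(f2), n_lines = 3),
               "too narrow")
})
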