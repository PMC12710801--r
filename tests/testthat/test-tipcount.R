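# Tip-counting pipeline: MIP, thresholding, skeleton census, invariances.

tree_params <- function(...) tip_count_params(background_radius = 40, ...)

test_that("mip: slices, bright voxels, per-pixel max oracle", {
  a <- array(runif(6 * 7 * 1), dim = c(6, 7, 1))
  expect_equal(mip(a), a[, , 1])
  set.seed(22)
  b <- array(runif(8 * 9 * 5), dim = c(8, 9, 5))
  expect_equal(mip(b), bf_mip(b), tolerance = 1e-12)
  expect_warning(m <- mip(matrix(1:4, 2)), "already 2D")
  expect_equal(m, matrix(1:4, 2))
})

test_that("bar gives 2 tips, Y gives 3", {
  bar <- generate_tree_image(tubule_tree_spec(
    data.frame(x0 = 30, y0 = 100, x1 = 170, y1 = 100, width = 5)))
  expect_equal(count_tips(bar$image, tree_params())$tip_count, 2)
  ytree <- generate_tree_image(tubule_tree_spec(
    data.frame(x0 = c(100, 100, 100), y0 = c(170, 100, 100),
               x1 = c(100, 40, 160), y1 = c(100, 40, 40), width = 5)))
  expect_equal(count_tips(ytree$image, tree_params())$tip_count, 3)
})

test_that("tip count is invariant under 90-degree rotation and mirroring", {
  rt <- random_tree_spec(4, shape = c(256, 256), seed = 6, noise_sigma = 8)
  img <- generate_tree_image(rt)$image
  base <- count_tips(img, tree_params())$tip_count
  expect_equal(count_tips(rot90cw(img), tree_params())$tip_count, base)
  expect_equal(count_tips(rot90cw(rot90cw(img)), tree_params())$tip_count, base)
  expect_equal(count_tips(img[nrow(img):1, ], tree_params())$tip_count, base)
  expect_equal(count_tips(img[, ncol(img):1], tree_params())$tip_count, base)
})

test_that("uniform background offset does not change the count", {
  rt <- random_tree_spec(5, shape = c(256, 256), seed = 8, noise_sigma = 8)
  img <- generate_tree_image(rt)$image
  expect_equal(count_tips(img + 50, tree_params())$tip_count,
               count_tips(img, tree_params())$tip_count)
})

test_that("skeleton endpoint census equals brute-force neighbour counting", {
  rt <- random_tree_spec(4, shape = c(256, 256), seed = 12, noise_sigma = 5)
  res <- count_tips(generate_tree_image(rt)$image, tree_params())
  sk <- res$skeleton
  n_ends <- 0
  for (y in seq_len(nrow(sk))) for (x in seq_len(ncol(sk))) {
    if (!sk[y, x]) next
    cnt <- 0
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= nrow(sk) && xx >= 1 && xx <= ncol(sk) && sk[yy, xx])
        cnt <- cnt + 1
    }
    if (cnt == 1) n_ends <- n_ends + 1
  }
  expect_equal(res$tip_count, n_ends)
  expect_equal(nrow(res$endpoints), n_ends)
})

test_that("fixed threshold override and degenerate inputs behave", {
  rt <- random_tree_spec(3, shape = c(200, 200), seed = 3)
  img <- generate_tree_image(rt)$image
  res <- count_tips(img, tip_count_params(background_radius = 0,
                                          threshold = 50))
  expect_equal(res$tip_count, rt$ground_truth_tips)
  expect_warning(
    empty <- count_tips(matrix(1, 60, 60),
                        tip_count_params(background_radius = 0, threshold = 5)),
    "no foreground")
  expect_equal(empty$tip_count, 0L)
  bad <- matrix(1, 30, 30); bad[3, 3] <- NA
  expect_error(count_tips(bad), "non-finite")
  expect_error(tip_count_params(threshold = c(1, 2)), "threshold")
})

test_that("otsu threshold maximizes between-class variance (brute-force oracle)", {
  set.seed(25)
  img <- matrix(rnorm(2500, 10, 2), 50)
  img[20:30, 20:30] <- rnorm(121, 100, 2)
  thr <- otsu_threshold(img)
  # naive oracle: scan candidate thresholds, maximize w0*w1*(m0-m1)^2
  v <- as.vector(img)
  cand <- seq(min(v), max(v), length.out = 400)
  best <- -Inf; best_t <- NA
  for (tc in cand) {
    lo <- v[v <= tc]; hi <- v[v > tc]
    if (!length(lo) || !length(hi)) next
    s <- (length(lo) / length(v)) * (length(hi) / length(v)) *
         (mean(lo) - mean(hi))^2
    if (s > best) { best <- s; best_t <- tc }
  }
  expect_lt(abs(thr - best_t), diff(range(v)) / 100)  # within binning error
  # the resulting mask is exactly the bright square
  expect_identical(unname(which(img > thr)),
                   unname(which(row(img) %in% 20:30 & col(img) %in% 20:30)))
})
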