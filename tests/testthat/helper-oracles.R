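# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities with naive loops / closed forms,
# independent of the package's implementation paths.

# circularly shift volume content by (sx, sy, sz): out[p] = a[p - s]
shift3 <- function(a, sx, sy, sz) {
  d <- dim(a)
  iy <- ((seq_len(d[1]) - 1 - sy) %% d[1]) + 1
  ix <- ((seq_len(d[2]) - 1 - sx) %% d[2]) + 1
  iz <- ((seq_len(d[3]) - 1 - sz) %% d[3]) + 1
  a[iy, ix, iz]
}

# term-by-term evaluation of the printed standard-distance formula
bf_standard_distance <- function(pts) {
  n <- nrow(pts)
  xb <- sum(pts[, 1]) / n
  yb <- sum(pts[, 2]) / n
  sx <- 0; sy <- 0
  for (i in seq_len(n)) {
    sx <- sx + (pts[i, 1] - xb)^2
    sy <- sy + (pts[i, 2] - yb)^2
  }
  sqrt(sx / n + sy / n)
}

# explicit Benjamini-Hochberg step-up loop
bf_fdr <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# O(n^2) Mann-Whitney U count for group a (ties count 1/2)
bf_U <- function(a, b) {
  u <- 0
  for (x in a) for (y in b)
    u <- u + (x > y) + 0.5 * (x == y)
  u
}

# two-sample Hotelling T2 statistic (plain formula, no package code)
bf_t2 <- function(A, B) {
  n1 <- nrow(A); n2 <- nrow(B)
  d <- colMeans(A) - colMeans(B)
  Sp <- ((n1 - 1) * cov(A) + (n2 - 1) * cov(B)) / (n1 + n2 - 2)
  (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(Sp) %*% d)
}

# permutation p-value for the two-sample T2 on fixed data
perm_t2_pvalue <- function(A, B, n_perm = 1e5, seed = 1) {
  X <- rbind(A, B)
  n1 <- nrow(A); n <- nrow(X)
  obs <- bf_t2(A, B)
  hits <- 0L
  set.seed(seed)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    t2 <- bf_t2(X[idx, , drop = FALSE], X[-idx, , drop = FALSE])
    if (t2 >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# per-pixel max loop
bf_mip <- function(a) {
  d <- dim(a)
  out <- matrix(-Inf, d[1], d[2])
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1]))
    if (a[y, x, z] > out[y, x]) out[y, x] <- a[y, x, z]
  out
}

# n_wedges angular sectors meeting at the image centre
wedge_labels <- function(n_wedges, size = 41) {
  c0 <- (size + 1) / 2
  lab <- matrix(0L, size, size)
  for (y in 1:size) for (x in 1:size) {
    a <- atan2(y - c0, x - c0)
    lab[y, x] <- 1L + (floor((a + pi) / (2 * pi) * n_wedges) %% n_wedges)
  }
  lab
}

# nearest-seed (Voronoi) labeling
voronoi_labels <- function(n_seeds, size = 60, seed = 1) {
  set.seed(seed)
  sx <- runif(n_seeds, 1, size); sy <- runif(n_seeds, 1, size)
  lab <- matrix(0L, size, size)
  for (y in 1:size) for (x in 1:size)
    lab[y, x] <- which.min((sx - x)^2 + (sy - y)^2)
  lab
}

# exhaustive rosette scan: junction pixels whose disk neighbourhood holds
# >= min_cells labels, merged into 8-connected components by plain BFS
bf_rosettes <- function(lab, min_cells = 5, radius = 2) {
  ny <- nrow(lab); nx <- ncol(lab)
  r <- ceiling(radius)
  hit <- matrix(FALSE, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    labs <- integer(0)
    for (dy in -r:r) for (dx in -r:r) {
      if (dy^2 + dx^2 > radius^2) next
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
      if (lab[yy, xx] > 0) labs <- c(labs, lab[yy, xx])
    }
    hit[y, x] <- length(unique(labs)) >= min_cells
  }
  # BFS components
  comp <- matrix(0L, ny, nx); k <- 0L
  for (y0 in 1:ny) for (x0 in 1:nx) {
    if (!hit[y0, x0] || comp[y0, x0] > 0) next
    k <- k + 1L
    queue <- list(c(y0, x0)); comp[y0, x0] <- k
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        y <- p[1] + dy; x <- p[2] + dx
        if (y < 1 || y > ny || x < 1 || x > nx) next
        if (hit[y, x] && comp[y, x] == 0) {
          comp[y, x] <- k
          queue[[length(queue) + 1]] <- c(y, x)
        }
      }
    }
  }
  list(mask = hit, n_components = k)
}

# Expectation of the measured standard distance for m cells equally spaced
# on a circle of radius r with isotropic N(0, sigma^2) jitter. The summed
# per-axis mean squared deviation S is (sigma^2/m) * noncentral
# chi-square_{2(m-1)}(m r^2 / sigma^2); E[sqrt(S)] via the second-order
# delta method. Accurate to well under 1e-3 px for r >> sigma.
expected_sd <- function(r, sigma, m) {
  mu <- r^2 + 2 * sigma^2 * (m - 1) / m
  v <- 4 * sigma^4 * (m - 1) / m^2 + 4 * sigma^2 * r^2 / m
  sqrt(mu) * (1 - v / (8 * mu^2))
}

# build a dispersal_series without package constructors
mk_series <- function(time, sd, group = NA_character_) {
  structure(data.frame(time = time, sd = sd),
            class = c("dispersal_series", "data.frame"),
            cluster_id = NA, group = group, normalized = FALSE)
}
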