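# Synthetic branching-tree images with known terminal-tip counts —
# fixtures for the skeleton-based tip-counting pipeline.

# Build the node graph of a segment set; endpoints matching within `tol`
# are merged into one node.
tree_graph <- function(segments, tol = 1e-6) {
  pts <- rbind(as.matrix(segments[, c("x0", "y0")]),
               as.matrix(segments[, c("x1", "y1")]))
  n <- nrow(segments)
  node_of <- integer(2 * n)
  nodes <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(2 * n)) {
    hit <- 0L
    if (nrow(nodes))
      for (k in seq_len(nrow(nodes)))
        if (all(abs(nodes[k, ] - pts[i, ]) <= tol)) { hit <- k; break }
    if (hit == 0L) { nodes <- rbind(nodes, pts[i, ]); hit <- nrow(nodes) }
    node_of[i] <- hit
  }
  edges <- cbind(node_of[seq_len(n)], node_of[n + seq_len(n)])
  list(nodes = nodes, edges = edges)
}

graph_degrees <- function(g) tabulate(as.vector(g$edges), nbins = nrow(g$nodes))

graph_connected <- function(g) {
  n <- nrow(g$nodes)
  if (n <= 1) return(TRUE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges[i, 1]; b <- g$edges[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); stack <- 1L; seen[1] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  all(seen)
}

#' Specify a synthetic tubule tree image
#'
#' @param segments data.frame with columns `x0, y0, x1, y1, width` (px;
#'   0-based image coordinates); must form a single connected tree.
#' @param shape image shape `(ny, nx)`.
#' @param blur_sigma Gaussian blur applied after rendering (px).
#' @param foreground peak foreground intensity.
#' @param background constant background level.
#' @param bg_gradient linear background gradient along x (intensity/px).
#' @param noise_sigma additive Gaussian noise SD.
#' @param seed integer seed (noise only; geometry is deterministic).
#' @return a `tubule_tree_spec`; `ground_truth_tips` is the number of
#'   degree-1 nodes of the segment graph.
#' @export
tubule_tree_spec <- function(segments, shape = c(200, 200), blur_sigma = 1.5,
                             foreground = 100, background = 10,
                             bg_gradient = 0, noise_sigma = 0, seed = 1) {
  req <- c("x0", "y0", "x1", "y1", "width")
  assert_that(all(req %in% names(segments)), "segments need columns ",
              paste(req, collapse = ", "))
  assert_that(nrow(segments) >= 1, "need at least one segment")
  assert_that(all(segments$width > 0), "segment widths must be > 0")
  g <- tree_graph(segments)
  assert_that(graph_connected(g), "segments do not form a single connected tree")
  deg <- graph_degrees(g)
  structure(list(segments = segments, shape = as.integer(shape),
                 blur_sigma = blur_sigma, foreground = foreground,
                 background = background, bg_gradient = bg_gradient,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 graph = g, ground_truth_tips = sum(deg == 1)),
            class = "tubule_tree_spec")
}

#' Random binary tree spec
#'
#' Grows a tree by `n_bifurcations` successive leaf splits starting from a
#' degree-2 root (the root itself bifurcates), so the tree has
#' `n_bifurcations + 1` terminal tips by construction.
#'
#' @param n_bifurcations number of splits (>= 1).
#' @param shape image shape `(ny, nx)`.
#' @param seed integer seed for branch angles and lengths.
#' @param width segment width in px.
#' @param ... passed on to [tubule_tree_spec()].
#' @return a `tubule_tree_spec`.
#' @export
random_tree_spec <- function(n_bifurcations = 4, shape = c(200, 200), seed = 1,
                             width = 4, ...) {
  assert_that(n_bifurcations >= 1, "need at least one bifurcation")
  with_seed(seed, {
    centre <- c(shape[2] / 2, shape[1] / 2)
    rmax <- min(shape) / 2 - 10
    # Radial layout: every leaf owns a disjoint angular sector, children
    # split their parent's sector, so subtrees can never collide.
    phi0 <- runif(1, 0, 2 * pi)
    segs <- NULL
    add_seg <- function(from, to) {
      segs <<- rbind(segs, data.frame(x0 = from[1], y0 = from[2],
                                      x1 = to[1], y1 = to[2], width = width))
    }
    radial <- function(r, ang) centre + r * c(cos(ang), sin(ang))
    step_r <- function(depth) max(rmax * 0.32 * 0.75^depth, 14)
    # root bifurcation: two leaves with half-circle sectors
    leaves <- list()
    for (s in 0:1) {
      sector <- phi0 + c(s * pi, (s + 1) * pi)
      ang <- mean(sector) + runif(1, -0.15, 0.15) * diff(sector)
      r <- step_r(0)
      add_seg(centre, radial(r, ang))
      leaves[[s + 1]] <- list(r = r, ang = ang, sector = sector, depth = 1)
    }
    for (split in seq_len(n_bifurcations - 1)) {
      k <- sample.int(length(leaves), 1)
      lf <- leaves[[k]]
      leaves[[k]] <- NULL
      mid <- lf$ang
      halves <- list(c(lf$sector[1], mid), c(mid, lf$sector[2]))
      for (h in halves) {
        ang <- mean(h) + runif(1, -0.1, 0.1) * diff(h)
        r <- min(lf$r + step_r(lf$depth), rmax)
        add_seg(radial(lf$r, lf$ang), radial(r, ang))
        leaves[[length(leaves) + 1]] <-
          list(r = r, ang = ang, sector = h, depth = lf$depth + 1)
      }
    }
    tubule_tree_spec(segs, shape = shape, seed = seed, ...)
  })
}

#' Render a tree spec into an image with ground truth
#'
#' Segments are drawn as anti-aliased thick bars (intensity ramps over the
#' last pixel of the half-width), combined by maximum, Gaussian-blurred,
#' and background plus seeded noise are added.
#'
#' @param spec a [tubule_tree_spec()].
#' @return list with `image` (ny x nx matrix), `tips` (ground-truth
#'   terminal-tip count) and `spec`.
#' @export
generate_tree_image <- function(spec) {
  assert_that(inherits(spec, "tubule_tree_spec"), "spec must be a tubule_tree_spec")
  ny <- spec$shape[1]; nx <- spec$shape[2]
  img <- matrix(0, ny, nx)
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), nx), ny, nx)
  for (i in seq_len(nrow(spec$segments))) {
    s <- spec$segments[i, ]
    pad <- s$width / 2 + 2
    x0 <- max(0, floor(min(s$x0, s$x1) - pad)); x1 <- min(nx - 1, ceiling(max(s$x0, s$x1) + pad))
    y0 <- max(0, floor(min(s$y0, s$y1) - pad)); y1 <- min(ny - 1, ceiling(max(s$y0, s$y1) + pad))
    sub <- ys >= y0 & ys <= y1 & xs >= x0 & xs <= x1
    px <- xs[sub]; py <- ys[sub]
    vx <- s$x1 - s$x0; vy <- s$y1 - s$y0
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - s$x0) * vx + (py - s$y0) * vy) / L2)) else 0
    d <- sqrt((px - (s$x0 + t * vx))^2 + (py - (s$y0 + t * vy))^2)
    val <- pmin(1, pmax(0, s$width / 2 + 0.5 - d)) * spec$foreground
    img[sub] <- pmax(img[sub], val)
  }
  if (spec$blur_sigma > 0) img <- cpp_gauss_blur2d(img, spec$blur_sigma)
  img <- img + spec$background + spec$bg_gradient * xs
  if (spec$noise_sigma > 0)
    img <- img + with_seed(spec$seed,
                           matrix(rnorm(ny * nx, 0, spec$noise_sigma), ny, nx))
  list(image = img, tips = spec$ground_truth_tips, spec = spec)
}
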