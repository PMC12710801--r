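# Skeleton-based counting of branching tips.
#
# Pipeline, mirroring the standard FIJI recipe: maximum intensity
# projection (3D input), rolling-ball-style background subtraction
# (grayscale opening with a disk), Gaussian blur, threshold (Otsu by
# default), small-component removal, morphological thinning to a 1-px
# skeleton, iterative spur pruning, and a census of endpoints (skeleton
# pixels with exactly one 8-connected neighbour) — each endpoint is one tip.

#' Tip-counting parameters
#'
#' @param background_radius disk radius (px) for background subtraction by
#'   grayscale opening; `NULL` or 0 disables the step. Default 50 px (the
#'   conventional rolling-ball default).
#' @param blur_sigma Gaussian blur SD in px (default 2).
#' @param threshold `"otsu"` or a fixed numeric intensity value.
#' @param min_component_area components smaller than this (px^2) are
#'   dropped; `NULL` (default) keeps only the largest component.
#' @param spur_prune_length skeleton spurs shorter than this many pixels
#'   are pruned iteratively (default 5; 0 disables pruning).
#' @return a `tip_count_params` object.
#' @export
tip_count_params <- function(background_radius = 50, blur_sigma = 2,
                             threshold = "otsu", min_component_area = NULL,
                             spur_prune_length = 5) {
  if (!is.null(background_radius))
    assert_that(background_radius >= 0, "background_radius must be >= 0")
  assert_that(blur_sigma >= 0, "blur_sigma must be >= 0")
  ok <- identical(threshold, "otsu") ||
    (is.numeric(threshold) && length(threshold) == 1 && is.finite(threshold))
  assert_that(ok, "threshold must be \"otsu\" or one numeric value")
  if (!is.null(min_component_area))
    assert_that(min_component_area > 0, "min_component_area must be > 0")
  assert_that(spur_prune_length >= 0, "spur_prune_length must be >= 0")
  structure(list(background_radius = background_radius, blur_sigma = blur_sigma,
                 threshold = threshold, min_component_area = min_component_area,
                 spur_prune_length = spur_prune_length),
            class = "tip_count_params")
}

#' Maximum intensity projection
#'
#' @param stack 3D array `[y, x, z]`, or a 2D matrix (returned as-is with a
#'   warning).
#' @return ny x nx matrix of per-pixel maxima over z.
#' @export
mip <- function(stack) {
  if (is.matrix(stack)) {
    warning("input is already 2D; returning it unchanged")
    return(stack)
  }
  assert_that(length(dim(stack)) == 3, "stack must be 2D or 3D")
  apply(stack, c(1, 2), max)
}

#' Otsu threshold of an image
#'
#' @param img numeric matrix.
#' @param n_bins histogram resolution.
#' @return threshold intensity maximizing between-class variance.
#' @export
otsu_threshold <- function(img, n_bins = 256) {
  v <- as.vector(img)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(n_bins, findInterval(v, breaks, rightmost.closed = TRUE)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  breaks[k + 1]
}

# Grayscale opening (erosion then dilation) with a (2r+1) square
# structuring element via separable running min/max; the square stands in
# for the rolling ball, which it approximates for background estimation.
gray_open_disk <- function(img, radius) {
  r <- as.integer(round(radius))
  er <- cpp_minmax_box2d(img, r, TRUE)
  cpp_minmax_box2d(er, r, FALSE)
}

# Number of 8-neighbour runs around a pixel in cyclic order (the crossing
# number): 1 for an endpoint, 2 for a path (including staircase corners,
# which have 3 raw neighbours but only 2 runs), >= 3 for a true junction.
neighbor_runs <- function(skel, y, x) {
  ny <- nrow(skel); nx <- ncol(skel)
  dy <- c(-1, -1, 0, 1, 1, 1, 0, -1); dx <- c(0, 1, 1, 1, 0, -1, -1, -1)
  v <- logical(8)
  for (i in 1:8) {
    yy <- y + dy[i]; xx <- x + dx[i]
    v[i] <- yy >= 1 && yy <= ny && xx >= 1 && xx <= nx && skel[yy, xx]
  }
  sum(!v & c(v[-1], v[1]))
}

# Delete terminal spurs shorter than min_len: walk from each endpoint
# through path pixels until a true junction (>= 3 neighbour runs) or the
# length budget is reached; only paths that reach a junction early are
# spurs and get removed. Repeats until stable (a removed spur can expose a
# shorter one).
prune_spurs <- function(skel, min_len) {
  if (min_len <= 0 || !any(skel)) return(skel)
  # orthogonal neighbours first so walks follow the thin path at corners
  dy <- c(-1, 1, 0, 0, -1, -1, 1, 1); dx <- c(0, 0, -1, 1, -1, 1, -1, 1)
  repeat {
    nb <- cpp_neighbor_count2d(skel)
    ends <- which(!is.na(nb) & nb == 1)
    removed <- FALSE
    for (e in ends) {
      ij <- arrayInd(e, dim(skel))
      if (!skel[ij[1], ij[2]]) next
      path <- matrix(ij, ncol = 2)
      cur <- ij
      hit_junction <- FALSE
      while (nrow(path) < min_len) {
        nxt <- NULL
        for (i in 1:8) {
          y <- cur[1] + dy[i]; x <- cur[2] + dx[i]
          if (y < 1 || y > nrow(skel) || x < 1 || x > ncol(skel)) next
          if (!skel[y, x]) next
          if (any(path[, 1] == y & path[, 2] == x)) next
          nxt <- c(y, x); break
        }
        if (is.null(nxt)) break                       # tiny isolated piece
        if (neighbor_runs(skel, nxt[1], nxt[2]) >= 3) {
          hit_junction <- TRUE                         # spur meets branch
          break
        }
        cur <- nxt
        path <- rbind(path, nxt)
      }
      if (hit_junction && nrow(path) < min_len) {
        skel[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skel
}

#' Count branching tips in an image
#'
#' Runs the full pipeline described above and returns the skeleton with its
#' endpoint census.
#'
#' @param stack 2D matrix or 3D array `[y, x, z]` (reduced by [mip()]).
#' @param params a [tip_count_params()].
#' @return a `skeleton_result`: `skeleton` (logical matrix), `endpoints`
#'   and `branch_points` (two-column y/x matrices), `tip_count`, `mask`,
#'   the threshold used, and `params`. An all-background threshold yields
#'   `tip_count = 0` with a warning.
#' @export
count_tips <- function(stack, params = tip_count_params()) {
  assert_that(inherits(params, "tip_count_params"), "params must be tip_count_params")
  img <- if (is.matrix(stack)) stack else mip(stack)
  assert_that(all(is.finite(img)), "image contains non-finite pixels")
  if (!is.null(params$background_radius) && params$background_radius > 0)
    img <- pmax(img - gray_open_disk(img, params$background_radius), 0)
  if (params$blur_sigma > 0) img <- cpp_gauss_blur2d(img, params$blur_sigma)
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(img)
         else params$threshold
  mask <- img > thr
  if (!any(mask)) {
    warning("threshold leaves no foreground; tip count is 0")
    return(structure(list(skeleton = mask, endpoints = NULL,
                          branch_points = NULL, tip_count = 0L, mask = mask,
                          threshold = thr, params = params),
                     class = "skeleton_result"))
  }
  lab <- cpp_label2d(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- if (is.null(params$min_component_area)) which.max(sizes)
          else which(sizes >= params$min_component_area)
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  skel <- cpp_thin2d(mask)
  skel <- prune_spurs(skel, params$spur_prune_length)
  nb <- cpp_neighbor_count2d(skel)
  ends <- which(!is.na(nb) & nb == 1)
  branches <- which(!is.na(nb) & nb >= 3)
  structure(list(skeleton = skel,
                 endpoints = arrayInd(ends, dim(skel)),
                 branch_points = arrayInd(branches, dim(skel)),
                 tip_count = length(ends), mask = mask, threshold = thr,
                 params = params),
            class = "skeleton_result")
}

#' @export
print.skeleton_result <- function(x, ...) {
  cat(sprintf("<skeleton_result> %d tip(s), %d branch point(s), threshold %.4g\n",
              x$tip_count, if (is.null(x$branch_points)) 0 else nrow(x$branch_points),
              x$threshold))
  invisible(x)
}
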