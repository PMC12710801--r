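# Rosette detection on labeled cell rasters.
#
# A rosette is a configuration of >= 5 cells sharing a vertex. On a labeled
# segmentation (background 0) a vertex shows up as a pixel whose small disk
# neighbourhood touches >= 5 distinct labels.

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

#' Detect multicellular rosettes in a labeled cell image
#'
#' Every pixel's disk neighbourhood (default radius 2 px) is scanned for
#' the set of distinct nonzero labels; pixels whose neighbourhood holds at
#' least `min_cells` labels are rosette vertices. Overlapping vertex pixels
#' (8-connected) are merged into one reported rosette.
#'
#' @param label_image integer matrix; 0 = background, positive = cell labels.
#' @param min_cells minimum number of labels sharing the vertex (default 5).
#' @param radius neighbourhood radius in px (default 2).
#' @return list of rosettes, each a list with `vertex` (y, x centroid of
#'   the merged vertex pixels) and `labels` (participating cell labels).
#'   Empty list when none found.
#' @export
detect_rosettes <- function(label_image, min_cells = 5, radius = 2) {
  assert_that(is.matrix(label_image), "label_image must be a matrix")
  if (!any(label_image > 0)) return(list())
  ny <- nrow(label_image); nx <- ncol(label_image)
  offs <- disk_offsets(radius)
  no <- nrow(offs)
  # stack the shifted label images: npix x no
  stack <- matrix(0L, ny * nx, no)
  for (o in seq_len(no)) {
    dy <- offs$dy[o]; dx <- offs$dx[o]
    sh <- matrix(0L, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    sh[ys - dy, xs - dx] <- label_image[ys, xs]
    stack[, o] <- as.vector(sh)
  }
  n_labels <- apply(stack, 1, function(v) length(unique(v[v > 0])))
  hit <- matrix(n_labels >= min_cells, ny, nx)
  if (!any(hit)) return(list())
  comp <- cpp_label2d(hit)
  out <- list()
  for (k in seq_len(max(comp))) {
    px <- which(comp == k)
    ij <- arrayInd(px, dim(comp))
    labs <- sort(unique(as.vector(stack[px, ])))
    labs <- labs[labs > 0]
    out[[k]] <- list(vertex = c(y = mean(ij[, 1]), x = mean(ij[, 2])),
                     labels = labs)
  }
  out
}
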