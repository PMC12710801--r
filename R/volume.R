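# VolumeSeries: an ordered set of 3D intensity frames.
#
# Each frame is an array with dim = c(ny, nx, nz), i.e. frame[y, x, z];
# voxel coordinates are 0-based with x the fastest-varying image axis,
# matching the (x, y, z) component convention of the velocimetry module.

#' Construct a volume series
#'
#' @param frames list of 3D numeric arrays, all the same shape, indexed
#'   `[y, x, z]`.
#' @param voxel_size numeric length-3 voxel size in micrometres `(x, y, z)`.
#' @param dt frame interval in minutes.
#' @return a `volume_series` object.
#' @export
volume_series <- function(frames, voxel_size = c(1, 1, 1), dt = 10) {
  assert_that(is.list(frames) && length(frames) >= 1, "frames must be a non-empty list")
  d <- dim(frames[[1]])
  assert_that(length(d) == 3, "frames must be 3D arrays [y, x, z]")
  for (f in frames)
    assert_that(identical(dim(f), d), "inconsistent frame shapes")
  assert_that(length(voxel_size) == 3 && all(voxel_size > 0), "bad voxel_size")
  assert_that(dt > 0, "dt must be positive")
  structure(list(frames = frames, dim = d, voxel_size = as.numeric(voxel_size),
                 dt = as.numeric(dt)),
            class = "volume_series")
}

#' @export
length.volume_series <- function(x) length(x$frames)

#' @export
print.volume_series <- function(x, ...) {
  d <- x$dim
  cat(sprintf("<volume_series> %d frame(s), %d x %d x %d (y,x,z), dt = %g min\n",
              length(x$frames), d[1], d[2], d[3], x$dt))
  invisible(x)
}

#' Write a volume series as multi-page TIFF (TZYX page order)
#'
#' Pages run t-major: all z-slices of frame 1, then frame 2, and so on.
#' A JSON sidecar (`<path>.json`) records the axis layout, voxel size and
#' frame interval so the series round-trips through [read_volume()].
#'
#' @param vs a [volume_series()].
#' @param path output TIFF path.
#' @param bits sample depth passed to [write_tiff_pages()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(vs, path, bits = 32) {
  assert_that(inherits(vs, "volume_series"), "vs must be a volume_series")
  nz <- vs$dim[3]
  pages <- list()
  for (f in vs$frames)
    for (z in seq_len(nz))
      pages[[length(pages) + 1]] <- f[, , z]
  write_tiff_pages(pages, path, bits = bits)
  sidecar <- list(axes = "TZYX", n_frames = length(vs$frames), nz = nz,
                  ny = vs$dim[1], nx = vs$dim[2],
                  voxel_size = vs$voxel_size, dt = vs$dt)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TIFF stack into a volume series
#'
#' Axis metadata is taken from the JSON sidecar written by [write_volume()]
#' when present; otherwise `nz` (slices per time point) must be given and a
#' warning notes the fallback. Pages are assumed TZYX-ordered.
#'
#' @param path TIFF path.
#' @param nz slices per frame; overrides/substitutes sidecar metadata.
#' @param voxel_size,dt metadata fallbacks when no sidecar exists.
#' @return a [volume_series()].
#' @export
read_volume <- function(path, nz = NULL, voxel_size = c(1, 1, 1), dt = 10) {
  pages <- read_tiff_pages(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    nz <- nz %||% meta$nz
    voxel_size <- meta$voxel_size %||% voxel_size
    dt <- meta$dt %||% dt
  } else if (is.null(nz)) {
    warning("no axis metadata sidecar; assuming a single time point")
    nz <- length(pages)
  }
  assert_that(length(pages) %% nz == 0,
              "page count ", length(pages), " not divisible by nz = ", nz)
  nt <- length(pages) / nz
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  frames <- vector("list", nt)
  for (t in seq_len(nt)) {
    a <- array(0, dim = c(ny, nx, nz))
    for (z in seq_len(nz)) a[, , z] <- pages[[(t - 1) * nz + z]]
    frames[[t]] <- a
  }
  volume_series(frames, voxel_size = voxel_size, dt = dt)
}
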