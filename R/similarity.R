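# Motion-similarity maps and line-based coherence profiles.
#
# Similarity at a node is the mean scalar product of its velocity vector
# with its in-plane 4-neighbours (same z slab; z sampling is ~7x coarser
# than x/y in the stacks this targets, and the maps are rendered as 2D
# heatmaps). In normalized mode both vectors are unit-normalized first, so
# values are cosines in [-1, 1]; raw mode keeps the plain scalar product,
# which conflates alignment with speed.

shift_arr <- function(a, dy = 0, dx = 0, dz = 0) {
  d <- dim(a)
  out <- array(NA_real_, dim = d)
  ys <- seq_len(d[1]) - dy; xs <- seq_len(d[2]) - dx; zs <- seq_len(d[3]) - dz
  oky <- ys >= 1 & ys <= d[1]; okx <- xs >= 1 & xs <= d[2]; okz <- zs >= 1 & zs <= d[3]
  out[oky, okx, okz] <- a[ys[oky], xs[okx], zs[okz]]
  out
}

#' Motion-similarity map of a velocity field
#'
#' @param field a `velocity_field`.
#' @param mode `"normalized"` (cosine similarity; bounded in `[-1, 1]`) or
#'   `"raw"` (plain scalar product with the neighbour vectors).
#' @param neighbourhood `"inplane4"` (default: the +/-x, +/-y neighbours in
#'   the same z slab) or `"6"` (adds the +/-z neighbours).
#' @return a `similarity_map`: per-node scalar `values`, `valid` mask, mode.
#'   Nodes with a zero vector (normalized mode) or no valid neighbour are
#'   invalid.
#' @export
motion_similarity_map <- function(field, mode = c("normalized", "raw"),
                                  neighbourhood = c("inplane4", "6")) {
  mode <- match.arg(mode)
  neighbourhood <- match.arg(neighbourhood)
  assert_that(inherits(field, "velocity_field"), "field must be a velocity_field")
  d <- dim(field$u)
  assert_that(d[1] >= 2 && d[2] >= 2,
              "similarity needs >= 2 nodes per in-plane axis")
  u <- field$u; v <- field$v; w <- field$w
  ok <- field$valid
  if (mode == "normalized") {
    mag <- sqrt(u^2 + v^2 + w^2)
    ok <- ok & is.finite(mag) & mag > 0
    u <- u / mag; v <- v / mag; w <- w / mag
  }
  u[!ok] <- NA; v[!ok] <- NA; w[!ok] <- NA
  offs <- list(c(0, -1, 0), c(0, 1, 0), c(-1, 0, 0), c(1, 0, 0))
  if (neighbourhood == "6") offs <- c(offs, list(c(0, 0, -1), c(0, 0, 1)))
  acc <- array(0, dim = d); cnt <- array(0L, dim = d)
  for (o in offs) {
    su <- shift_arr(u, o[1], o[2], o[3])
    sv <- shift_arr(v, o[1], o[2], o[3])
    sw <- shift_arr(w, o[1], o[2], o[3])
    dot <- u * su + v * sv + w * sw
    has <- !is.na(dot)
    acc[has] <- acc[has] + dot[has]
    cnt <- cnt + has
  }
  val <- ok & cnt > 0
  values <- array(NA_real_, dim = d)
  values[val] <- acc[val] / cnt[val]
  structure(list(values = values, valid = val, mode = mode,
                 neighbourhood = neighbourhood, grid = field$grid),
            class = "similarity_map")
}

#' @export
print.similarity_map <- function(x, ...) {
  cat(sprintf("<similarity_map> mode=%s, %d valid nodes, mean=%.3f\n",
              x$mode, sum(x$valid), mean(x$values[x$valid])))
  invisible(x)
}

#' Coherence profile along equidistant parallel lines
#'
#' Draws `n_lines` lines parallel to the tissue's long axis, at cross-axis
#' fractions `k / (n_lines + 1)` of the grid extent, and reports the mean
#' and standard deviation of motion similarity along each line. The z
#' dimension of the map is collapsed by averaging valid nodes first. Lines
#' whose sampled nodes are all invalid are reported missing, not fabricated.
#'
#' @param sim_map a [motion_similarity_map()] result.
#' @param n_lines number of lines (default 3).
#' @param axis long axis of the tissue: `"x"` (lines are grid rows) or `"y"`.
#' @return data.frame with columns `line`, `cross_index` (1-based grid
#'   index of the line), `mean`, `sd`, `n`, `missing`.
#' @export
coherence_profile <- function(sim_map, n_lines = 3, axis = c("x", "y")) {
  axis <- match.arg(axis)
  assert_that(inherits(sim_map, "similarity_map"), "sim_map must be a similarity_map")
  assert_that(is_count(n_lines) && n_lines >= 1, "n_lines must be a positive count")
  d <- dim(sim_map$values)
  # collapse z by averaging valid nodes
  vals2 <- matrix(NA_real_, d[1], d[2])
  for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    vv <- sim_map$values[y, x, ]
    vv <- vv[sim_map$valid[y, x, ]]
    if (length(vv)) vals2[y, x] <- mean(vv)
  }
  ncross <- if (axis == "x") d[1] else d[2]
  assert_that(ncross >= n_lines,
              "grid too narrow to host ", n_lines, " distinct lines")
  idx <- round((ncross - 1) * seq_len(n_lines) / (n_lines + 1)) + 1
  assert_that(length(unique(idx)) == n_lines,
              "grid too narrow to host ", n_lines, " distinct lines")
  out <- data.frame(line = seq_len(n_lines), cross_index = idx,
                    mean = NA_real_, sd = NA_real_, n = 0L, missing = TRUE)
  for (k in seq_len(n_lines)) {
    line_vals <- if (axis == "x") vals2[idx[k], ] else vals2[, idx[k]]
    line_vals <- line_vals[!is.na(line_vals)]
    if (length(line_vals)) {
      out$mean[k] <- mean(line_vals)
      out$sd[k] <- if (length(line_vals) > 1) sd(line_vals) else 0
      out$n[k] <- length(line_vals)
      out$missing[k] <- FALSE
    }
  }
  out
}
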