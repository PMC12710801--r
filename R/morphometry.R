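# Tubule morphometry: cross-sectional polygon areas and narrowing,
# division-angle orientation, and diameter-distribution comparison.

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1 else i + 1
    for (j in seq_len(n)) {
      if (j == i) next
      j2 <- if (j == n) 1 else j + 1
      # skip segments sharing a vertex
      if (i2 == j || j2 == i || (i == 1 && j2 == 1) || (j == 1 && i2 == 1)) next
      if (segments_intersect(xy[i, ], xy[i2, ], xy[j, ], xy[j2, ])) return(FALSE)
    }
  }
  TRUE
}

#' Area of a simple polygon (shoelace formula)
#'
#' @param polygon two-column matrix/data.frame of `(x, y)` vertices of a
#'   closed, non-self-intersecting polygon (last vertex implicitly joined
#'   to the first).
#' @return absolute area in px^2.
#' @export
polygon_area <- function(polygon) {
  xy <- as.matrix(polygon)[, 1:2, drop = FALSE]
  assert_that(nrow(xy) >= 3, "a polygon needs at least 3 vertices")
  assert_that(all(is.finite(xy)), "vertices must be finite")
  assert_that(polygon_is_simple(xy), "polygon is self-intersecting")
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:nrow(xy), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Relative cross-sectional area over time
#'
#' @param polygons list of polygons (see [polygon_area()]), one per time
#'   point, outlining the tubule cross-section.
#' @param times optional time stamps (defaults to 0, 1, ...).
#' @return data.frame with `time`, `area` (px^2) and `relative`
#'   (`area / area[1]`); a value of 0.5 means 50 percent narrowing.
#' @export
relative_area_change <- function(polygons, times = NULL) {
  assert_that(is.list(polygons) && length(polygons) >= 2,
              "need >= 2 time points")
  areas <- vapply(polygons, polygon_area, numeric(1))
  assert_that(areas[1] > 0, "initial area is zero")
  times <- times %||% (seq_along(polygons) - 1)
  data.frame(time = times, area = areas, relative = areas / areas[1])
}

#' Division angle relative to the tubule's longitudinal axis
#'
#' The angle between the line connecting the two daughter-cell centroids
#' and the longitudinal axis of the tubular lumen, folded to the acute
#' range: `acos(|cos(theta)|)` in degrees.
#'
#' @param centroid1,centroid2 daughter centroids `(x, y)`.
#' @param axis unit (or any nonzero) vector along the tubule's long axis.
#' @return angle in degrees in `[0, 90]`.
#' @export
division_angle <- function(centroid1, centroid2, axis = c(1, 0)) {
  v <- c(centroid2[1] - centroid1[1], centroid2[2] - centroid1[2])
  assert_that(sum(v^2) > 0, "daughter centroids coincide")
  assert_that(sum(axis^2) > 0, "axis vector is zero")
  cosang <- abs(sum(v * axis)) / (sqrt(sum(v^2)) * sqrt(sum(axis^2)))
  acos(pmin(1, cosang)) * 180 / pi
}

#' Compare tubule diameter distributions between two groups
#'
#' Reports per-group medians and the two-sided Mann-Whitney U test
#' (exact when samples are small and tie-free, normal approximation with
#' tie/continuity correction otherwise), plus a shared-break histogram
#' summary for distribution-shift plots.
#'
#' @param groupA,groupB numeric diameter vectors (>= 2 values each).
#' @param n_bins histogram bin count for the summary.
#' @return list with `medians`, `U` (for group A), `p`, and `histogram`
#'   (data.frame of shared breaks with per-group counts).
#' @export
compare_diameter_distributions <- function(groupA, groupB, n_bins = 10) {
  assert_that(length(groupA) >= 2 && length(groupB) >= 2,
              "each group needs >= 2 values")
  assert_that(all(is.finite(groupA)) && all(is.finite(groupB)),
              "diameters must be finite")
  wt <- suppressWarnings(wilcox.test(groupA, groupB, alternative = "two.sided"))
  breaks <- seq(min(groupA, groupB), max(groupA, groupB), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  hA <- table(cut(groupA, breaks)); hB <- table(cut(groupB, breaks))
  list(medians = c(A = median(groupA), B = median(groupB)),
       U = unname(wt$statistic), p = wt$p.value,
       histogram = data.frame(lower = head(breaks, -1), upper = tail(breaks, -1),
                              countA = as.integer(hA), countB = as.integer(hB)))
}
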