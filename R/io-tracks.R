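# Trajectory-table readers: the plain dialect written by this package and
# the tracking-software dialect (TRACK_ID / FRAME / POSITION_X|Y|Z columns
# with a few non-numeric header-junk rows below the column names).

#' Read a trajectory CSV
#'
#' @param path CSV path.
#' @param dialect `"auto"` (default; sniff the header), `"plain"`
#'   (`track_id, frame, x, y[, z][, cluster_id]`) or `"trackmate"`
#'   (`TRACK_ID, FRAME, POSITION_X, POSITION_Y[, POSITION_Z]`, with junk
#'   rows under the header tolerated and counted).
#' @param dt frame interval in minutes.
#' @return a [trajectory_set()]; the number of skipped malformed rows is
#'   attached as attribute `n_skipped`.
#' @export
read_tracks <- function(path, dialect = c("auto", "plain", "trackmate"), dt = 10) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "auto")
    dialect <- if ("TRACK_ID" %in% names(raw)) "trackmate" else "plain"
  if (dialect == "trackmate") {
    req <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
    miss <- setdiff(req, names(raw))
    assert_that(length(miss) == 0, "missing required column(s): ",
                paste(miss, collapse = ", "))
    num <- suppressWarnings(as.numeric(raw$FRAME))
    junk <- is.na(num)
    n_skipped <- sum(junk)
    if (n_skipped)
      message(n_skipped, " non-numeric header/junk row(s) skipped")
    raw <- raw[!junk, , drop = FALSE]
    df <- data.frame(track_id = as.numeric(raw$TRACK_ID),
                     frame = as.numeric(raw$FRAME),
                     x = as.numeric(raw$POSITION_X),
                     y = as.numeric(raw$POSITION_Y))
    if ("POSITION_Z" %in% names(raw)) df$z <- as.numeric(raw$POSITION_Z)
  } else {
    req <- c("track_id", "frame", "x", "y")
    miss <- setdiff(req, names(raw))
    assert_that(length(miss) == 0, "missing required column(s): ",
                paste(miss, collapse = ", "))
    keep <- intersect(c("track_id", "cluster_id", "frame", "x", "y", "z"),
                      names(raw))
    df <- raw[, keep, drop = FALSE]
    bad <- !complete.cases(df[, c("track_id", "frame", "x", "y")])
    n_skipped <- sum(bad)
    if (n_skipped) message(n_skipped, " malformed row(s) skipped")
    df <- df[!bad, , drop = FALSE]
  }
  ts <- trajectory_set(df, dt = dt)
  attr(ts, "n_skipped") <- n_skipped
  ts
}
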