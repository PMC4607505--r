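# shared fixtures: representative frames/series built in code

series_times <- function(series) vapply(series$frames, `[[`, 0, "time")
series_matrix_of <- function(series) plasmidsim:::series_matrix(series)

# wide-necked late-anaphase-like frame
frame_wide <- function(t = 0) {
  frame_from_extents(t, 2.6, 1.9, 2.0, 1.5, 1.6, 0.7)
}

# persistently narrow neck
frame_narrow <- function(t = 0) {
  frame_from_extents(t, 2.6, 1.9, 1.8, 1.4, 2.0, 0.16)
}

# small daughter, mother width transiently exceeding its length
frame_skew <- function(t = 0) {
  frame_from_extents(t, 1.8, 2.0, 0.6, 0.5, 0.8, 0.4)
}

# static series (two identical frames) from a frame constructor
static_series <- function(make, duration = 600, id = "static") {
  geometry_series(id, list(make(0), make(duration)))
}

# mirror-symmetric static series
symmetric_series <- function(duration = 600) {
  mk <- function(t) frame_from_extents(t, 1.4, 1.0, 1.4, 1.0, 0.4, 0.5)
  geometry_series("sym", list(mk(0), mk(duration)))
}

# uniform points in the (slightly inflated) bounding box of a frame
bbox_points <- function(frame, n) {
  xm <- frame$mother$center_x - frame$mother$semi_long
  xd <- frame$daughter$center_x + frame$daughter$semi_long
  w <- max(frame$mother$semi_equatorial, frame$daughter$semi_equatorial,
           frame$bridge$radius)
  cbind(runif(n, xm - 0.1, xd + 0.1),
        runif(n, -w - 0.1, w + 0.1),
        runif(n, -w - 0.1, w + 0.1))
}
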