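# Composite nuclear geometry: two prolate spheroids joined by a cylindrical
# bridge on the division (x) axis. Convention: bridge midpoint at x = 0,
# mother lobe at negative x, daughter at positive x; spheroid tips touch the
# bridge ends (tip contact). All lengths in micrometres, times in seconds.
# Measured lengths/widths are full extents and are halved into semi-axes and
# radii on load.

#' Spheroid specification
#'
#' A lobe of the dividing nucleus: a spheroid of revolution about the
#' division axis. `semi_long` is the semi-axis along the division axis,
#' `semi_equatorial` the perpendicular semi-axis. Prolate in intent, but
#' `semi_long >= semi_equatorial` is not enforced since measured widths can
#' transiently exceed lengths.
#'
#' @param center_x position of the spheroid centre on the division axis (um)
#' @param semi_long semi-axis along the division axis (um), > 0
#' @param semi_equatorial semi-axis perpendicular to the axis (um), > 0
#' @return an object of class `spheroid_spec`
#' @export
spheroid_spec <- function(center_x, semi_long, semi_equatorial) {
  if (!is.finite(semi_long) || semi_long <= 0) stopf("semi_long must be > 0")
  if (!is.finite(semi_equatorial) || semi_equatorial <= 0)
    stopf("semi_equatorial must be > 0")
  structure(list(center_x = center_x, semi_long = semi_long,
                 semi_equatorial = semi_equatorial),
            class = "spheroid_spec")
}

#' Bridge specification
#'
#' The cylindrical neck joining the two nuclear lobes, centred on the origin.
#'
#' @param half_length half of the tip-to-tip bridge extent (um), >= 0
#' @param radius cylinder radius (um), >= 0
#' @return an object of class `bridge_spec`
#' @export
bridge_spec <- function(half_length, radius) {
  if (!is.finite(half_length) || half_length < 0)
    stopf("bridge half_length must be >= 0")
  if (!is.finite(radius) || radius < 0) stopf("bridge radius must be >= 0")
  structure(list(half_length = half_length, radius = radius),
            class = "bridge_spec")
}

#' One time point of the nuclear geometry
#'
#' Validates the tip-contact constraint: the mother spheroid's +x tip sits at
#' `-bridge$half_length` and the daughter's -x tip at `+bridge$half_length`
#' (tolerance 1e-9 um), so the union of the three primitives is connected.
#'
#' @param time seconds from anaphase onset
#' @param mother,daughter [spheroid_spec()] objects (mother at negative x)
#' @param bridge a [bridge_spec()]
#' @return an object of class `geometry_frame`
#' @export
geometry_frame <- function(time, mother, daughter, bridge) {
  stopifnot(inherits(mother, "spheroid_spec"),
            inherits(daughter, "spheroid_spec"),
            inherits(bridge, "bridge_spec"))
  if (!(mother$center_x < 0 && daughter$center_x > 0))
    stopf("mother centre must be at negative x, daughter at positive x")
  tol <- 1e-9
  if (abs(mother$center_x + mother$semi_long + bridge$half_length) > tol)
    stopf("tip contact violated: mother tip at %g, expected %g",
          mother$center_x + mother$semi_long, -bridge$half_length)
  if (abs(daughter$center_x - daughter$semi_long - bridge$half_length) > tol)
    stopf("tip contact violated: daughter tip at %g, expected %g",
          daughter$center_x - daughter$semi_long, bridge$half_length)
  structure(list(time = time, mother = mother, daughter = daughter,
                 bridge = bridge),
            class = "geometry_frame")
}

#' Build a frame from full extents as measured on images
#'
#' Lengths and widths are halved into semi-axes and radii; spheroid centres
#' are derived from tip contact with the bridge ends.
#'
#' @param time seconds from anaphase onset
#' @param mother_length,mother_width,daughter_length,daughter_width full
#'   extents of the lobes (um), > 0
#' @param bridge_length,bridge_width tip-to-tip bridge extent and diameter
#'   (um), >= 0
#' @return a [geometry_frame()]
#' @export
frame_from_extents <- function(time, mother_length, mother_width,
                               daughter_length, daughter_width,
                               bridge_length, bridge_width) {
  bh <- bridge_length / 2
  ma <- mother_length / 2
  da <- daughter_length / 2
  geometry_frame(
    time,
    mother = spheroid_spec(-(bh + ma), ma, mother_width / 2),
    daughter = spheroid_spec(bh + da, da, daughter_width / 2),
    bridge = bridge_spec(bh, bridge_width / 2)
  )
}

# 6-parameter vector consumed by the C++ kernels
frame_params <- function(frame) {
  c(frame$mother$semi_long, frame$mother$semi_equatorial,
    frame$daughter$semi_long, frame$daughter$semi_equatorial,
    frame$bridge$half_length, frame$bridge$radius)
}

params_to_frame <- function(time, p) {
  geometry_frame(
    time,
    mother = spheroid_spec(-(p[5] + p[1]), p[1], p[2]),
    daughter = spheroid_spec(p[5] + p[3], p[3], p[4]),
    bridge = bridge_spec(p[5], p[6])
  )
}

#' Ordered geometry frames for one cell's anaphase
#'
#' @param cell_id label
#' @param frames list of [geometry_frame()] objects, >= 2, strictly
#'   increasing times
#' @return an object of class `geometry_series`
#' @export
geometry_series <- function(cell_id, frames) {
  if (length(frames) < 2L) stopf("a geometry series needs at least 2 frames")
  stopifnot(all(vapply(frames, inherits, TRUE, "geometry_frame")))
  times <- vapply(frames, `[[`, 0, "time")
  if (any(diff(times) <= 0))
    stopf("frame times must be strictly increasing (cell %s)", cell_id)
  structure(list(cell_id = as.character(cell_id), frames = frames),
            class = "geometry_series")
}

series_times <- function(series) vapply(series$frames, `[[`, 0, "time")

# matrix (time, ma, mb, da, db, bh, br) consumed by the simulation kernel
series_matrix <- function(series) {
  t(vapply(series$frames,
           function(f) c(f$time, frame_params(f)), numeric(7)))
}

#' @export
print.geometry_series <- function(x, ...) {
  tt <- series_times(x)
  cat(sprintf("geometry_series '%s': %d frames, t = %g..%g s\n",
              x$cell_id, length(x$frames), tt[1], tt[length(tt)]))
  invisible(x)
}

#' Interpolate the geometry at an arbitrary time
#'
#' Every scalar parameter (semi-axes, bridge half-length and radius) is
#' linearly interpolated between the bracketing measured frames; spheroid
#' centres are re-derived from tip contact afterwards, so the interpolated
#' frame satisfies all frame invariants.
#'
#' @param series a [geometry_series()]
#' @param t time in seconds, within the span of the series
#' @return a [geometry_frame()]
#' @export
frame_at <- function(series, t) {
  tt <- series_times(series)
  if (t < tt[1] - 1e-9 || t > tt[length(tt)] + 1e-9)
    stopf("t=%g outside the series span [%g, %g]", t, tt[1], tt[length(tt)])
  t <- min(max(t, tt[1]), tt[length(tt)])
  P <- series_matrix(series)
  p <- vapply(2:7, function(j) approx(tt, P[, j], xout = t)$y, numeric(1))
  params_to_frame(t, p)
}

#' Signed clearance of points with respect to the nuclear envelope
#'
#' For each point, the maximum over the three primitives of the per-primitive
#' signed clearance: the distance to that primitive's surface, positive if
#' the point is inside it and negative otherwise. Positive iff the point is
#' strictly inside the union. Spheroid surface distance reduces, by rotational
#' symmetry, to a 2D point-to-ellipse problem solved numerically to 1e-9 um.
#'
#' @param frame a [geometry_frame()]
#' @param points a length-3 vector or an n x 3 matrix (um)
#' @return numeric vector of signed clearances (um)
#' @export
clearance <- function(frame, points) {
  cpp_clearance(frame_params(frame), as_points_matrix(points))
}

#' Does a particle of radius r fit at each position?
#'
#' Volume exclusion treats the plasmid as a solid sphere: a centre position
#' is admissible iff the sphere fits entirely within at least one primitive
#' (the r-erosion of the union is approximated by the union of per-primitive
#' r-erosions; slightly conservative near the junctions). Equivalent to
#' `clearance(frame, points) >= r`; `r = 0` reduces to interior membership.
#'
#' @inheritParams clearance
#' @param r particle radius (um), >= 0
#' @return logical vector
#' @export
is_inside <- function(frame, points, r = 0) {
  if (r < 0) stopf("particle radius must be >= 0")
  cpp_contains(frame_params(frame), as_points_matrix(points), r)
}

#' Remap positions to the closest admissible point
#'
#' Positions where the particle does not fit are moved to the nearest
#' (Euclidean) position whose clearance is at least `r`, taken as the best
#' candidate over projections onto the r-eroded primitives (each of which is
#' convex). Admissible positions are returned unchanged, so the operation is
#' idempotent.
#'
#' @inheritParams is_inside
#' @return n x 3 matrix of admissible positions
#' @export
project_inside <- function(frame, points, r = 0) {
  if (r < 0) stopf("particle radius must be >= 0")
  cpp_project(frame_params(frame), as_points_matrix(points), r)
}

#' Mother/daughter compartment of positions
#'
#' The bridge midpoint (x = 0) is the boundary between the lobes; x = 0
#' itself is assigned to the mother (documented tie-break).
#'
#' @param points a length-3 vector or an n x 3 matrix
#' @return character vector, `"mother"` or `"daughter"`
#' @export
compartment_of <- function(points) {
  x <- as_points_matrix(points)[, 1]
  ifelse(x > 0, "daughter", "mother")
}

#' Sample particle positions uniformly over the admissible volume
#'
#' Rejection sampling from the axis-aligned bounding box of the union,
#' keeping positions where a particle of radius `r` fits. Draws from R's
#' global RNG; seed with [set.seed()] for reproducibility.
#'
#' @inheritParams is_inside
#' @param n number of positions
#' @param compartment `"any"` (default), `"mother"` or `"daughter"` to
#'   restrict the initial compartment
#' @return n x 3 matrix of positions
#' @export
sample_uniform <- function(frame, n, r = 0, compartment = c("any", "mother",
                                                            "daughter")) {
  if (n < 1) stopf("n must be >= 1")
  compartment <- match.arg(compartment)
  code <- match(compartment, c("any", "mother", "daughter")) - 1L
  cpp_sample_uniform(frame_params(frame), as.integer(n), r, code)
}

#' Monte-Carlo lobe volumes and volume fractions
#'
#' Uniform bounding-box sampling classified by union membership and
#' compartment. Fractions sum to 1 exactly; the binomial standard error of
#' the daughter fraction is reported.
#'
#' @param frame a [geometry_frame()]
#' @param n_samples Monte-Carlo sample count (>= 1e4)
#' @param seed optional seed for a dedicated RNG stream, so volume estimates
#'   do not perturb simulation streams
#' @return list with `mother_fraction`, `daughter_fraction`,
#'   `mother_volume`, `daughter_volume` (um^3), `se` (fraction SE)
#' @export
lobe_volume_fractions <- function(frame, n_samples = 1e5, seed = NULL) {
  if (n_samples < 1e4) stopf("n_samples must be >= 1e4")
  run <- function() cpp_mc_lobes(frame_params(frame), as.integer(n_samples))
  cnt <- if (is.null(seed)) run() else with_seed(seed, run())
  nin <- cnt[1] + cnt[2]
  if (nin == 0) stopf("no Monte-Carlo samples fell inside the geometry")
  fd <- cnt[2] / nin
  list(mother_fraction = 1 - fd, daughter_fraction = fd,
       mother_volume = cnt[3] * cnt[1] / n_samples,
       daughter_volume = cnt[3] * cnt[2] / n_samples,
       se = sqrt(fd * (1 - fd) / nin))
}

#' Morphology metrics of a geometry series
#'
#' Summary metrics of one cell's anaphase: maxima over frames of lobe
#' lengths and widths (full extents), Monte-Carlo final lobe volumes, mean
#' bridge width over frames, daughter/mother final volume ratio and
#' anaphase duration.
#'
#' @param series a [geometry_series()]
#' @param n_samples Monte-Carlo samples for the final-frame volumes
#' @param seed optional seed for the volume Monte-Carlo stream
#' @return list of class `geometry_metrics`
#' @export
series_metrics <- function(series, n_samples = 1e5, seed = NULL) {
  P <- series_matrix(series)
  fin <- series$frames[[length(series$frames)]]
  vol <- lobe_volume_fractions(fin, n_samples, seed = seed)
  structure(list(
    mother_max_length = 2 * max(P[, 2]),
    mother_max_width = 2 * max(P[, 3]),
    mother_final_volume = vol$mother_volume,
    daughter_max_length = 2 * max(P[, 4]),
    daughter_max_width = 2 * max(P[, 5]),
    daughter_final_volume = vol$daughter_volume,
    mean_bridge_width = mean(2 * P[, 7]),
    final_volume_ratio = vol$daughter_volume / vol$mother_volume,
    anaphase_duration = P[nrow(P), 1] - P[1, 1]
  ), class = "geometry_metrics")
}

geometry_columns <- c("cell_id", "time_s", "mother_length_um",
                      "mother_width_um", "daughter_length_um",
                      "daughter_width_um", "bridge_length_um",
                      "bridge_width_um")

#' Read geometry series from the measurement CSV dialect
#'
#' Expected columns: `cell_id, time_s, mother_length_um, mother_width_um,
#' daughter_length_um, daughter_width_um, bridge_length_um, bridge_width_um`;
#' one row per frame. Lengths and widths are full extents and are halved
#' into semi-axes/radii; spheroid centres follow from tip contact.
#'
#' @param path CSV file path
#' @param cell_id optionally select one cell from a multi-cell file
#' @param dialect optional named character vector mapping the canonical
#'   column names to the file's column names
#' @return a [geometry_series()], or a named list of them when the file
#'   holds several cells and `cell_id` is `NULL`
#' @export
read_geometry_series <- function(path, cell_id = NULL, dialect = NULL) {
  if (!file.exists(path)) stopf("geometry file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(df))
        stopf("geometry file %s: missing column '%s'", path, dialect[[canon]])
      names(df)[names(df) == dialect[[canon]]] <- canon
    }
  }
  missing <- setdiff(geometry_columns, names(df))
  if (length(missing))
    stopf("geometry file %s: missing column '%s'", path, missing[1])
  num <- geometry_columns[-1]
  if (any(!vapply(df[num], is.numeric, TRUE)))
    stopf("geometry file %s: non-numeric measurement columns", path)
  if (any(as.matrix(df[, c("mother_length_um", "mother_width_um",
                           "daughter_length_um", "daughter_width_um")]) <= 0))
    stopf("geometry file %s: lobe dimensions must be > 0", path)
  if (any(as.matrix(df[, c("bridge_length_um", "bridge_width_um")]) < 0))
    stopf("geometry file %s: bridge dimensions must be >= 0", path)
  build <- function(sub) {
    sub <- sub[order(sub$time_s), , drop = FALSE]
    if (any(duplicated(sub$time_s)))
      stopf("geometry file %s: duplicated time for cell %s", path,
            sub$cell_id[1])
    frames <- lapply(seq_len(nrow(sub)), function(i) {
      r <- sub[i, ]
      frame_from_extents(r$time_s, r$mother_length_um, r$mother_width_um,
                         r$daughter_length_um, r$daughter_width_um,
                         r$bridge_length_um, r$bridge_width_um)
    })
    geometry_series(sub$cell_id[1], frames)
  }
  if (!is.null(cell_id)) {
    sub <- df[df$cell_id == cell_id, , drop = FALSE]
    if (!nrow(sub)) stopf("cell '%s' not found in %s", cell_id, path)
    return(build(sub))
  }
  ids <- unique(df$cell_id)
  if (length(ids) == 1L) return(build(df))
  out <- lapply(ids, function(id) build(df[df$cell_id == id, , drop = FALSE]))
  names(out) <- ids
  out
}

#' Write geometry series in the measurement CSV dialect
#'
#' Inverse of [read_geometry_series()]: semi-axes and radii are doubled back
#' into full extents.
#'
#' @param series a [geometry_series()] or a list of them
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_geometry_series <- function(series, path) {
  if (inherits(series, "geometry_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    P <- series_matrix(s)
    data.frame(cell_id = s$cell_id, time_s = P[, 1],
               mother_length_um = 2 * P[, 2], mother_width_um = 2 * P[, 3],
               daughter_length_um = 2 * P[, 4], daughter_width_um = 2 * P[, 5],
               bridge_length_um = 2 * P[, 6], bridge_width_um = 2 * P[, 7])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
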