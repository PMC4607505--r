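# Brute-force oracle for the geometry predicates, independent of the
# package's Newton point-to-ellipse solver. All three primitives share the
# division axis, so every query reduces exactly to the meridional half-plane
# (x, v) with v = sqrt(y^2 + z^2): surfaces are sampled densely there and
# distances taken as minima over the samples.

oracle_frame_pieces <- function(frame) {
  list(m = frame$mother, d = frame$daughter, b = frame$bridge,
       hext = 1.01 * frame$bridge$half_length)
}

# dense meridional boundary samples of one spheroid (full half-ellipse)
oracle_ellipse_points <- function(center_x, a, b, n = 8000) {
  phi <- seq(0, pi, length.out = n)
  cbind(center_x + a * cos(phi), b * sin(phi))
}

# min distance from meridional point (x, v) to a sampled point set
oracle_min_dist <- function(x, v, set) {
  min(sqrt((set[, 1] - x)^2 + (set[, 2] - v)^2))
}

# signed clearance (positive inside) of one point w.r.t. the whole frame
oracle_clearance_1 <- function(frame, p, sets) {
  g <- oracle_frame_pieces(frame)
  x <- p[1]; v <- sqrt(p[2]^2 + p[3]^2)
  best <- -Inf
  for (nm in c("m", "d")) {
    s <- g[[nm]]
    dist <- oracle_min_dist(x, v, sets[[nm]])
    inside <- ((x - s$center_x) / s$semi_long)^2 +
      (v / s$semi_equatorial)^2 <= 1
    best <- max(best, if (inside) dist else -dist)
  }
  if (g$b$radius > 0 && g$b$half_length > 0) {
    dx <- abs(x) - g$hext; dv <- v - g$b$radius
    cb <- if (dx <= 0 && dv <= 0) min(-dx, -dv) else
      -sqrt(max(dx, 0)^2 + max(dv, 0)^2)
    best <- max(best, cb)
  }
  best
}

oracle_clearance <- function(frame, pts) {
  g <- oracle_frame_pieces(frame)
  sets <- list(m = oracle_ellipse_points(g$m$center_x, g$m$semi_long,
                                         g$m$semi_equatorial),
               d = oracle_ellipse_points(g$d$center_x, g$d$semi_long,
                                         g$d$semi_equatorial))
  apply(pts, 1, function(p) oracle_clearance_1(frame, p, sets))
}

# does a sphere of radius r fit inside at least one primitive?
oracle_contains <- function(frame, pts, r) {
  g <- oracle_frame_pieces(frame)
  sets <- list(m = oracle_ellipse_points(g$m$center_x, g$m$semi_long,
                                         g$m$semi_equatorial),
               d = oracle_ellipse_points(g$d$center_x, g$d$semi_long,
                                         g$d$semi_equatorial))
  apply(pts, 1, function(p) {
    x <- p[1]; v <- sqrt(p[2]^2 + p[3]^2)
    for (nm in c("m", "d")) {
      s <- g[[nm]]
      inside <- ((x - s$center_x) / s$semi_long)^2 +
        (v / s$semi_equatorial)^2 <= 1
      if (inside && oracle_min_dist(x, v, sets[[nm]]) >= r) return(TRUE)
    }
    g$b$radius > 0 && g$b$half_length > 0 &&
      v <= g$b$radius - r && abs(x) <= g$hext - r
  })
}

# candidate boundary points of the r-eroded primitives (meridional plane).
# Spheroid erosion boundary = the inward normal offset of the ellipse,
# trimmed where the offset leaves the erosion (checked against a densely
# sampled ellipse, so near-tip swallowtail points are dropped).
oracle_erosion_candidates <- function(frame, r, n = 8000) {
  g <- oracle_frame_pieces(frame)
  cand <- NULL
  for (nm in c("m", "d")) {
    s <- g[[nm]]
    a <- s$semi_long; b <- s$semi_equatorial
    if (r >= min(a, b)) next
    phi <- seq(0, pi, length.out = n)
    nx <- cos(phi) / a; nv <- sin(phi) / b
    nn <- sqrt(nx^2 + nv^2)
    qx <- a * cos(phi) - r * nx / nn
    qv <- b * sin(phi) - r * nv / nn
    keep <- qv >= 0
    if (r > 0) {
      # validity needs checking only near the high-curvature tips
      tipish <- keep & abs(cos(phi)) > 0.6
      if (any(tipish)) {
        ell <- oracle_ellipse_points(0, a, b, 4000)
        dst <- vapply(which(tipish), function(i)
          oracle_min_dist(qx[i], qv[i], ell), numeric(1))
        keep[which(tipish)[dst < r - 2e-3]] <- FALSE
      }
    }
    cand <- rbind(cand, cbind(s$center_x + qx[keep], qv[keep]))
  }
  if (g$b$radius - r > 0 && g$hext - r > 0) {
    R <- g$b$radius - r; H <- g$hext - r
    xs <- seq(-H, H, length.out = n)
    vs <- seq(0, R, length.out = max(100L, as.integer(n * R / (2 * H))))
    cand <- rbind(cand, cbind(xs, R), cbind(-H, vs), cbind(H, vs))
  }
  cand
}

# distance from each (exterior) point to the nearest admissible position
oracle_project_dist <- function(frame, pts, r,
                                cand = oracle_erosion_candidates(frame, r)) {
  apply(pts, 1, function(p) {
    v <- sqrt(p[2]^2 + p[3]^2)
    min(sqrt((cand[, 1] - p[1])^2 + (cand[, 2] - v)^2))
  })
}
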