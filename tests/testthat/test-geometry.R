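test_that("frames built from measured extents halve dimensions and derive centres", {
  f <- frame_from_extents(0, 2.0, 1.6, 1.0, 0.8, 1.0, 0.4)
  expect_equal(f$mother$semi_long, 1.0)
  expect_equal(f$mother$semi_equatorial, 0.8)
  expect_equal(f$bridge$half_length, 0.5)
  expect_equal(f$bridge$radius, 0.2)
  expect_equal(f$mother$center_x, -1.5)
  expect_equal(f$daughter$center_x, 1.0)
})

test_that("frame invariants are enforced", {
  expect_error(spheroid_spec(0, -1, 1), "semi_long")
  expect_error(bridge_spec(-0.1, 0.2), "half_length")
  # tip contact violation
  expect_error(geometry_frame(0, spheroid_spec(-2, 1, 0.8),
                              spheroid_spec(1, 0.5, 0.4),
                              bridge_spec(0.5, 0.2)),
               "tip contact")
  # series need >= 2 frames with strictly increasing times
  f0 <- frame_wide(0)
  expect_error(geometry_series("c", list(f0)), "at least 2")
  expect_error(geometry_series("c", list(f0, frame_wide(0))),
               "strictly increasing")
})

test_that("geometry CSV round-trips and validates", {
  s <- generate_geometry_series(seed = 11, cell_id = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_geometry_series(s, path)
  s2 <- read_geometry_series(path)
  expect_equal(series_times(s2), series_times(s))
  expect_equal(sapply(s2$frames, plasmidsim:::frame_params),
               sapply(s$frames, plasmidsim:::frame_params),
               tolerance = 1e-12)
  # missing column named in the error
  df <- read.csv(path)
  df$bridge_width_um <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_geometry_series(path), "bridge_width_um")
})

test_that("duplicate frame times in a file are a validation error", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(cell_id = "x", time_s = c(0, 30, 30),
                   mother_length_um = 2, mother_width_um = 1.6,
                   daughter_length_um = 1, daughter_width_um = 0.8,
                   bridge_length_um = 1, bridge_width_um = 0.4)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_geometry_series(path), "duplicated time")
})

test_that("frame_at is exact at stored times and linear between them", {
  mk <- function(t, bw) frame_from_extents(t, 2, 1.6, 1, 0.8, 1, bw)
  s <- geometry_series("c", list(mk(0, 0.8), mk(30, 0.4)))
  # stored time: exact frame
  expect_equal(plasmidsim:::frame_params(frame_at(s, 30)),
               plasmidsim:::frame_params(s$frames[[2]]))
  # linear midpoint and quarter point of the bridge radius (0.4 -> 0.2)
  expect_equal(frame_at(s, 15)$bridge$radius, 0.3)
  expect_equal(frame_at(s, 7.5)$bridge$radius, 0.35)
  # convex combination of every parameter at arbitrary t
  w <- 11 / 30
  expect_equal(plasmidsim:::frame_params(frame_at(s, 11)),
               (1 - w) * plasmidsim:::frame_params(s$frames[[1]]) +
                 w * plasmidsim:::frame_params(s$frames[[2]]))
  expect_error(frame_at(s, 31), "outside")
})

test_that("clearance matches hand values at primitive centres and on the bridge axis", {
  f <- frame_from_extents(0, 2.0, 1.6, 1.0, 0.8, 1.0, 0.4)
  # mother centre: nearest surface is its own equator
  expect_equal(clearance(f, c(-1.5, 0, 0)), 0.8, tolerance = 1e-9)
  # bridge axis midpoint: cylinder wall at 0.2
  expect_equal(clearance(f, c(0, 0, 0)), 0.2, tolerance = 1e-9)
  # far outside on the axis: negative distance to the daughter tip
  expect_equal(clearance(f, c(5, 0, 0)), -3.5, tolerance = 1e-9)
})

test_that("compartment split is at the bridge midpoint with x=0 tied to mother", {
  expect_equal(compartment_of(c(-0.3, 0, 0)), "mother")
  expect_equal(compartment_of(c(1e-4, 0.2, 0)), "daughter")
  expect_equal(compartment_of(c(0, 0, 0)), "mother")
})

test_that("volume exclusion blocks a sphere wider than the bridge", {
  f <- frame_from_extents(0, 2.0, 1.6, 1.0, 0.8, 2.0, 0.08)
  # bridge radius 0.04 < particle radius 0.05, point far from both lobes
  expect_false(is_inside(f, c(0, 0, 0), r = 0.05))
  expect_true(is_inside(f, c(0, 0, 0), r = 0))
})

test_that("projection is identity inside, radial for a lone sphere, idempotent", {
  f <- frame_from_extents(0, 2, 2, 2, 2, 0.2, 0.1) # two unit spheres
  p_in <- c(-1.1, 0.3, 0.1)
  expect_equal(project_inside(f, p_in, 0.1)[1, ], p_in)
  # exterior point above the mother sphere centre (-1.1, 0, 0):
  # radial projection onto the radius (1 - r) shell
  pr <- project_inside(f, c(-1.1, 3, 0), r = 0.1)[1, ]
  expect_equal(pr, c(-1.1, 0.9, 0), tolerance = 1e-6)
  # idempotence on random exterior points
  withr::local_seed(42)
  g <- frame_narrow()
  pts <- bbox_points(g, 200)
  out <- pts[!is_inside(g, pts, 0.05), , drop = FALSE]
  p1 <- project_inside(g, out, 0.05)
  p2 <- project_inside(g, p1, 0.05)
  expect_lt(max(abs(p1 - p2)), 1e-9)
  expect_true(all(is_inside(g, p1, 0.05)))
})

test_that("uniform sampling respects containment and symmetry", {
  withr::local_seed(7)
  sym <- symmetric_series()$frames[[1]]
  pts <- sample_uniform(sym, 1e5, r = 0)
  expect_true(all(is_inside(sym, pts, 0)))
  fd <- mean(compartment_of(pts) == "daughter")
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(fd - 0.5), 3 * se)
  # restricted initial compartment
  pm <- sample_uniform(sym, 500, compartment = "mother")
  expect_true(all(pm[, 1] <= 0))
})

test_that("sampled daughter fraction agrees with the MC volume fraction on an asymmetric frame", {
  withr::local_seed(8)
  f <- frame_skew()
  pts <- sample_uniform(f, 1e5, r = 0)
  fd <- mean(compartment_of(pts) == "daughter")
  vf <- lobe_volume_fractions(f, 2e5, seed = 99)
  se <- sqrt(fd * (1 - fd) / 1e5) + vf$se
  expect_lt(abs(fd - vf$daughter_fraction), 3 * se)
})

test_that("MC volume fractions match closed-form spheroid volumes when the bridge is negligible", {
  # two clearly separated lobes, hairline bridge
  f <- frame_from_extents(0, 2.4, 1.8, 1.6, 1.2, 1.0, 0.02)
  vf <- lobe_volume_fractions(f, 2e6, seed = 123)
  vm <- pi / 6 * 2.4 * 1.8^2
  vd <- pi / 6 * 1.6 * 1.2^2
  expect_equal(vf$daughter_fraction, vd / (vm + vd), tolerance = 0.01)
  expect_equal(vf$mother_fraction + vf$daughter_fraction, 1)
  expect_equal(vf$mother_volume, vm, tolerance = 0.02)
})

test_that("halving all linear dimensions divides MC volumes by 8", {
  f1 <- frame_wide()
  f2 <- frame_from_extents(0, 1.3, 0.95, 1.0, 0.75, 0.8, 0.35)
  v1 <- lobe_volume_fractions(f1, 3e5, seed = 5)
  v2 <- lobe_volume_fractions(f2, 3e5, seed = 6)
  tot1 <- v1$mother_volume + v1$daughter_volume
  tot2 <- v2$mother_volume + v2$daughter_volume
  expect_equal(tot1 / tot2, 8, tolerance = 0.05)
})

test_that("series metrics summarise maxima, volumes and duration", {
  s <- static_series(frame_wide, duration = 600)
  m <- series_metrics(s, n_samples = 5e4, seed = 2)
  expect_equal(m$mother_max_length, 2.6)
  expect_equal(m$daughter_max_width, 1.5)
  expect_equal(m$mean_bridge_width, 0.7)
  expect_equal(m$anaphase_duration, 600)
  expect_equal(m$final_volume_ratio,
               m$daughter_final_volume / m$mother_final_volume)
  # mirror-symmetric frame: ratio 1 within MC error
  ms <- series_metrics(symmetric_series(), n_samples = 2e5, seed = 3)
  expect_equal(ms$final_volume_ratio, 1.0, tolerance = 0.03)
})
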