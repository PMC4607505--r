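test_that("time step follows s_res^2/(m*D)", {
  expect_equal(time_step(0.001, 0.025, 4), 0.15625)
  expect_equal(time_step(0.009, 0.025, 4), 0.025^2 / (4 * 0.009))
  # doubling m halves dt
  expect_equal(time_step(0.003, 0.025, 8), time_step(0.003, 0.025, 4) / 2)
  expect_error(time_step(-1, 0.025, 4), "> 0")
})

test_that("free-space propagation has per-axis variance 2*D*dt and zero mean", {
  withr::local_seed(3)
  D <- 0.0027; dt <- 0.15625
  disp <- propagate(D = D, dt = dt, n = 1e6)
  v <- apply(disp, 2, var)
  expect_equal(unname(v), rep(2 * D * dt, 3), tolerance = 0.01)
  se <- sqrt(2 * D * dt / 1e6)
  expect_true(all(abs(colMeans(disp)) < 3 * se))
  # empirical 3D MSD equals 6*D*dt within 1%
  expect_equal(mean(rowSums(disp^2)), 6 * D * dt, tolerance = 0.01)
})

test_that("single runs are bit-identical under a fixed seed", {
  s <- symmetric_series()
  cfg <- simulation_config(D = 0.004, n_repeats = 1, seed = 5)
  r1 <- simulate_particle(s, cfg, seed = 77, record_positions = TRUE)
  r2 <- simulate_particle(s, cfg, seed = 77, record_positions = TRUE)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$positions, r2$positions)
  r3 <- simulate_particle(s, cfg, seed = 78)
  expect_false(identical(r1$labels, r3$labels))
})

test_that("recorded positions always satisfy containment", {
  s <- generate_geometry_series(geometry_preset("default"), seed = 13)
  cfg <- simulation_config(D = 0.005, particle_radius = 0.05, seed = 2)
  for (k in 1:5) {
    run <- simulate_particle(s, cfg, record_positions = TRUE,
                             seed = derive_seed(2, k))
    ok <- vapply(seq_along(run$times), function(j)
      is_inside(frame_at(s, run$times[j]), run$positions[j, ],
                cfg$particle_radius),
      TRUE)
    expect_true(all(ok))
  }
})

test_that("ensembles conserve probability and reproduce under the same seed", {
  s <- symmetric_series()
  cfg <- simulation_config(D = 0.004, n_repeats = 40, seed = 11)
  tr <- run_ensemble(s, cfg, volume_fractions = FALSE)
  expect_true(all(tr$daughter_fraction >= 0 & tr$daughter_fraction <= 1))
  expect_true(all(tr$ci_low <= tr$daughter_fraction &
                    tr$daughter_fraction <= tr$ci_high))
  # mother + daughter fractions sum to 1 by construction of the label split
  expect_equal((1 - tr$daughter_fraction) + tr$daughter_fraction,
               rep(1, nrow(tr)))
  tr2 <- run_ensemble(s, cfg, volume_fractions = FALSE)
  expect_identical(tr$daughter_fraction, tr2$daughter_fraction)
  # single repeat gives 0/1 fractions
  tr1 <- run_ensemble(s, simulation_config(D = 0.004, n_repeats = 1, seed = 3),
                      volume_fractions = FALSE)
  expect_true(all(tr1$daughter_fraction %in% c(0, 1)))
})

test_that("a mirror-symmetric static geometry transmits half the particles", {
  s <- symmetric_series(duration = 900)
  cfg <- simulation_config(D = 0.008, n_repeats = 1500, seed = 19)
  tr <- run_ensemble(s, cfg, volume_fractions = FALSE)
  fin <- tr$daughter_fraction[nrow(tr)]
  expect_lt(abs(fin - 0.5), 3 * sqrt(0.25 / 1500))
})

test_that("particles wider than the bridge never cross from the mother", {
  mk <- function(t) frame_from_extents(t, 2.0, 1.6, 1.6, 1.2, 1.0, 0.08)
  s <- geometry_series("blocked", list(mk(0), mk(300)))
  cfg <- simulation_config(D = 0.01, particle_radius = 0.05, n_repeats = 200,
                           seed = 23, init_compartment = "mother")
  tr <- run_ensemble(s, cfg, volume_fractions = FALSE)
  expect_true(all(tr$daughter_fraction == 0))
})

test_that("moving boundaries retain plasmids in the mother below the volume fraction", {
  # narrowing-bridge synthetic cell: final occupancy should sit below the
  # final daughter volume fraction (the asymmetry the model produces)
  s <- generate_geometry_series(geometry_preset("narrow_bridge"), seed = 3)
  cfg <- simulation_config(D = 0.0027, n_repeats = 300, seed = 31)
  tr <- run_ensemble(s, cfg)
  n <- nrow(tr)
  se <- sqrt(tr$daughter_fraction[n] * (1 - tr$daughter_fraction[n]) / 300 +
               1 / (4 * 2e4))
  expect_lt(tr$daughter_fraction[n],
            tr$daughter_volume_fraction[n] - 2 * se)
})

test_that("sweeps produce one row per combination with sane fractions", {
  s <- generate_geometry_series(seed = 41)
  cfg <- simulation_config(n_repeats = 20, seed = 7, record_interval = 1e4)
  sw <- sweep_diffusion(list(s, s), D_values = c(0.001, 0.009),
                        radii = c(0, 0.05), config = cfg)
  expect_equal(nrow(sw), 8)
  expect_true(all(sw$final_daughter_fraction >= 0 &
                    sw$final_daughter_fraction <= 1))
  sw1 <- sweep_diffusion(s, 0.003, 0, cfg)
  expect_equal(nrow(sw1), 1)
})

test_that("timestep study rows conserve probability and reproduce", {
  s <- symmetric_series(duration = 300)
  cfg <- simulation_config(D = 0.004, n_repeats = 50, seed = 13)
  st <- timestep_study(s, c(2, 4), cfg)
  expect_equal(st$mother_fraction + st$daughter_fraction, c(1, 1))
  st2 <- timestep_study(s, c(2, 4), cfg)
  expect_identical(st, st2)
})
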