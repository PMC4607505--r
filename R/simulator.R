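# Single-particle Brownian dynamics inside the moving nuclear geometry,
# ensembles and parameter sweeps.

#' Simulation time step from the target spatial resolution
#'
#' For free diffusion the per-axis mean-squared displacement is 2*D*t, so a
#' desired spatial resolution s_res motivates dt = s_res^2 / (m * D), with
#' the divisor m >= 1 tightening the step to keep boundary motion per step
#' negligible relative to diffusive motion.
#'
#' @param D diffusion constant (um^2/s), > 0
#' @param s_res target spatial resolution (um), > 0
#' @param m time-step divisor, >= 1
#' @return the time step in seconds
#' @export
time_step <- function(D, s_res = 0.025, m = 4) {
  if (!all(c(D, s_res, m) > 0)) stopf("D, s_res and m must all be > 0")
  s_res^2 / (m * D)
}

#' Gaussian free-diffusion displacements
#'
#' Independent zero-mean Gaussian increments per axis with variance 2*D*dt
#' each. Draws from R's global RNG.
#'
#' @param position 3-vector, carried through unused (displacements are
#'   position-independent); kept for signature symmetry with the stepping
#'   kernel
#' @param D diffusion constant (um^2/s)
#' @param dt time step (s), > 0
#' @param n number of displacement draws
#' @return n x 3 matrix of displacements (um)
#' @export
propagate <- function(position = c(0, 0, 0), D, dt, n = 1) {
  if (dt <= 0) stopf("dt must be > 0")
  matrix(rnorm(3 * n, 0, sqrt(2 * D * dt)), ncol = 3)
}

#' Simulation configuration
#'
#' Defaults mirror the standard protocol: spatial resolution 0.025 um,
#' divisor m = 4, occupancy recorded every 30 s, D = 0.0027 um^2/s (the mean
#' measured plasmid diffusion coefficient).
#'
#' @param D diffusion constant (um^2/s), > 0
#' @param particle_radius plasmid radius (um), >= 0 (0 = point particle)
#' @param s_res target spatial resolution (um), > 0
#' @param m time-step divisor, >= 1
#' @param n_repeats ensemble size, >= 1
#' @param seed root RNG seed; each repeat gets a derived substream
#' @param record_interval seconds between recorded occupancy samples, > 0
#' @param init_compartment `"any"` (uniform over the whole nucleus, the
#'   default), `"mother"` or `"daughter"`
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(D = 0.0027, particle_radius = 0,
                              s_res = 0.025, m = 4, n_repeats = 300,
                              seed = 1L, record_interval = 30,
                              init_compartment = "any") {
  stopifnot(D > 0, particle_radius >= 0, s_res > 0, m >= 1, n_repeats >= 1,
            record_interval > 0,
            init_compartment %in% c("any", "mother", "daughter"))
  structure(list(D = D, particle_radius = particle_radius, s_res = s_res,
                 m = m, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), record_interval = record_interval,
                 init_compartment = init_compartment),
            class = "simulation_config")
}

record_times_for <- function(series, config) {
  tt <- series_times(series)
  rt <- seq(tt[1], tt[length(tt)], by = config$record_interval)
  if (rt[length(rt)] < tt[length(tt)]) rt <- c(rt, tt[length(tt)])
  rt
}

#' Simulate one plasmid through one anaphase
#'
#' The particle starts uniformly over the admissible volume of the first
#' frame and is stepped with a fixed time step from [time_step()] (the final
#' step is truncated to the last frame time, with correspondingly reduced
#' variance). Each step advances the clock, re-interpolates the geometry,
#' remaps the particle if the moving boundary overtook it, applies a
#' Gaussian displacement, and remaps again if the step left the domain.
#' Compartment labels are recorded at `record_interval` and at the final
#' frame time (karyofission), the transmission readout.
#'
#' @param series a [geometry_series()]
#' @param config a [simulation_config()]
#' @param record_positions keep the 3D position at each record time
#' @param seed seed of this run's dedicated RNG stream (defaults to the
#'   config seed); the kernel does not touch R's global RNG
#' @return list with `times`, `labels` (`"mother"`/`"daughter"`), `final`
#'   position and optionally `positions`
#' @export
simulate_particle <- function(series, config = simulation_config(),
                              record_positions = FALSE, seed = config$seed) {
  rt <- record_times_for(series, config)
  dt <- time_step(config$D, config$s_res, config$m)
  code <- match(config$init_compartment, c("any", "mother", "daughter")) - 1L
  res <- cpp_simulate_particle(series_matrix(series), config$D,
                               config$particle_radius, dt, rt, code,
                               record_positions, as.double(seed))
  out <- list(times = rt,
              labels = c("mother", "daughter")[res$labels + 1L],
              final = res$final)
  if (record_positions) out$positions <- res$positions
  out
}

#' Ensemble of independent single-plasmid simulations
#'
#' Runs `n_repeats` independent [simulate_particle()] realisations, each on
#' its own RNG substream derived from the root seed (order-independent), and
#' summarises the proportion of runs whose plasmid sits in the daughter lobe
#' at each record time, with normal-approximation binomial confidence
#' intervals. The daughter volume fraction at each record time is estimated
#' by Monte Carlo on a dedicated stream for comparison with the occupancy
#' trace.
#'
#' @param series a [geometry_series()]
#' @param config a [simulation_config()]
#' @param volume_fractions also compute the daughter volume-fraction trace
#' @param volume_samples Monte-Carlo samples per record time
#' @return a `transmission_trace`: data.frame with `time_s`,
#'   `daughter_fraction`, `ci_low`, `ci_high` and (optionally)
#'   `daughter_volume_fraction`; attributes `n_repeats`, `cell_id`, `config`
#' @export
run_ensemble <- function(series, config = simulation_config(),
                         volume_fractions = TRUE, volume_samples = 2e4) {
  rt <- record_times_for(series, config)
  nrep <- config$n_repeats
  counts <- integer(length(rt))
  for (i in seq_len(nrep)) {
    run <- simulate_particle(series, config, seed = derive_seed(config$seed, i))
    counts <- counts + (run$labels == "daughter")
  }
  frac <- counts / nrep
  ci <- binomial_ci(counts, nrep)
  out <- data.frame(time_s = rt, daughter_fraction = frac,
                    ci_low = ci$low, ci_high = ci$high)
  if (volume_fractions) {
    out$daughter_volume_fraction <- vapply(seq_along(rt), function(j) {
      lobe_volume_fractions(frame_at(series, rt[j]), volume_samples,
                            seed = derive_seed(config$seed, 9e5 + j)
      )$daughter_fraction
    }, numeric(1))
  }
  structure(out, n_repeats = nrep, cell_id = series$cell_id, config = config,
            class = c("transmission_trace", "data.frame"))
}

#' Final transmission across diffusion constants and particle radii
#'
#' One [run_ensemble()] per (cell, D, radius) combination; the time step is
#' recomputed from each D. Records the daughter occupancy at the final frame
#' time (immediately preceding karyofission) and the final daughter volume
#' fraction.
#'
#' @param series_list a [geometry_series()] or list of them
#' @param D_values diffusion constants (um^2/s)
#' @param radii particle radii (um)
#' @param config a [simulation_config()] template; its D and radius are
#'   overridden, and each combination gets a derived root seed
#' @return data.frame with one row per combination: `cell_id`, `D_um2_s`,
#'   `radius_um`, `final_daughter_fraction`, `ci_low`, `ci_high`,
#'   `daughter_volume_fraction`
#' @export
sweep_diffusion <- function(series_list, D_values, radii = 0,
                            config = simulation_config()) {
  if (inherits(series_list, "geometry_series"))
    series_list <- list(series_list)
  if (!length(D_values) || !length(radii))
    stopf("D_values and radii must be nonempty")
  combos <- expand.grid(cell = seq_along(series_list),
                        D = D_values, r = radii)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    s <- series_list[[combos$cell[k]]]
    cfg <- config
    cfg$D <- combos$D[k]
    cfg$particle_radius <- combos$r[k]
    cfg$seed <- derive_seed(config$seed, 1e6 + k)
    tr <- run_ensemble(s, cfg, volume_fractions = TRUE)
    n <- nrow(tr)
    data.frame(cell_id = s$cell_id, D_um2_s = cfg$D, radius_um = cfg$particle_radius,
               final_daughter_fraction = tr$daughter_fraction[n],
               ci_low = tr$ci_low[n], ci_high = tr$ci_high[n],
               daughter_volume_fraction = tr$daughter_volume_fraction[n])
  })
  do.call(rbind, rows)
}

#' Sensitivity of final proportions to the time-step divisor m
#'
#' Repeats the ensemble with identical settings while varying the divisor m
#' of dt = s_res^2/(m*D). A well-behaved stepping scheme shows final mother
#' and daughter proportions statistically indistinguishable across m.
#'
#' @param series a [geometry_series()]
#' @param m_values divisors to test, all >= 1
#' @param config a [simulation_config()] template (its `m` is overridden;
#'   each m gets a derived root seed)
#' @return data.frame with `m`, `mother_fraction`, `daughter_fraction`,
#'   `ci_low`, `ci_high` (CI on the daughter fraction)
#' @export
timestep_study <- function(series, m_values = c(1, 2, 4, 8),
                           config = simulation_config()) {
  if (any(m_values < 1)) stopf("all m values must be >= 1")
  rows <- lapply(seq_along(m_values), function(k) {
    cfg <- config
    cfg$m <- m_values[k]
    cfg$seed <- derive_seed(config$seed, 2e6 + k)
    tr <- run_ensemble(series, cfg, volume_fractions = FALSE)
    n <- nrow(tr)
    data.frame(m = m_values[k],
               mother_fraction = 1 - tr$daughter_fraction[n],
               daughter_fraction = tr$daughter_fraction[n],
               ci_low = tr$ci_low[n], ci_high = tr$ci_high[n])
  })
  do.call(rbind, rows)
}

#' @export
print.transmission_trace <- function(x, ...) {
  cat(sprintf("transmission_trace (cell '%s', %d repeats): %d time points\n",
              attr(x, "cell_id"), attr(x, "n_repeats"), nrow(x)))
  NextMethod()
}

#' Plot a transmission trace
#'
#' Daughter occupancy fraction against time with its binomial confidence
#' band, superimposed on the daughter volume fraction when available.
#'
#' @param x a `transmission_trace` from [run_ensemble()]
#' @param ... passed to [plot()]
#' @export
plot.transmission_trace <- function(x, ...) {
  plot(x$time_s, x$daughter_fraction, type = "l", ylim = c(0, 1),
       xlab = "time since anaphase onset (s)",
       ylab = "fraction in daughter lobe", ...)
  graphics::arrows(x$time_s, x$ci_low, x$time_s, x$ci_high,
                   angle = 90, code = 3, length = 0.02)
  if (!is.null(x$daughter_volume_fraction))
    graphics::lines(x$time_s, x$daughter_volume_fraction, lty = 2)
  invisible(x)
}
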