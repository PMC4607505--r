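# Synthetic data with the statistical structure the pipeline assumes:
# anaphase geometry series, Brownian jump datasets and colony counts.
# The geometry generator is an emulation of measured anaphase morphologies
# (smooth monotone growth of the daughter lobe, elongating and optionally
# narrowing bridge), not a fit to any measured dataset.

#' Parameters of the synthetic geometry generator
#'
#' Each range is a (min, max) pair sampled uniformly per cell. Lengths and
#' widths are full extents in um; the daughter lobe grows smoothly from
#' `daughter_initial_scale` of its final size, the bridge elongates linearly
#' and its width moves from the initial to the final range (narrowing when
#' the final range is lower). Cells are rejected and resampled until the
#' final daughter volume fraction lands in `daughter_volume_fraction`, the
#' empirically observed 33-48% range.
#'
#' @param mother_length,mother_width mother lobe extents (um)
#' @param daughter_length,daughter_width final daughter extents (um)
#' @param bridge_width_initial,bridge_width_final bridge diameters (um)
#' @param bridge_length_initial,bridge_length_final tip-to-tip extents (um)
#' @param duration anaphase duration range (s); rounded to `frame_spacing`
#' @param frame_spacing seconds between frames (30 s, the native measurement
#'   spacing)
#' @param daughter_volume_fraction target interval for the final daughter
#'   volume fraction
#' @param daughter_initial_scale daughter size at anaphase onset relative to
#'   final
#' @return an object of class `geometry_gen_params`
#' @export
geometry_gen_params <- function(mother_length = c(2.2, 3.0),
                                mother_width = c(1.6, 2.2),
                                daughter_length = c(1.6, 2.4),
                                daughter_width = c(1.3, 1.9),
                                bridge_width_initial = c(0.45, 0.7),
                                bridge_width_final = c(0.25, 0.45),
                                bridge_length_initial = c(0.4, 0.8),
                                bridge_length_final = c(2.0, 3.5),
                                duration = c(480, 900),
                                frame_spacing = 30,
                                daughter_volume_fraction = c(0.33, 0.48),
                                daughter_initial_scale = 0.15) {
  p <- list(mother_length = mother_length, mother_width = mother_width,
            daughter_length = daughter_length,
            daughter_width = daughter_width,
            bridge_width_initial = bridge_width_initial,
            bridge_width_final = bridge_width_final,
            bridge_length_initial = bridge_length_initial,
            bridge_length_final = bridge_length_final,
            duration = duration, frame_spacing = frame_spacing,
            daughter_volume_fraction = daughter_volume_fraction,
            daughter_initial_scale = daughter_initial_scale)
  ranges <- p[!names(p) %in% c("frame_spacing", "daughter_initial_scale")]
  ok <- vapply(ranges, function(r) length(r) == 2 && all(r > 0) && r[1] <= r[2],
               TRUE)
  if (!all(ok)) stopf("invalid range(s): %s",
                      paste(names(ranges)[!ok], collapse = ", "))
  if (frame_spacing <= 0) stopf("frame_spacing must be > 0")
  structure(p, class = "geometry_gen_params")
}

#' Named generator presets
#'
#' `"default"`: intermediate bridge widths. `"narrow_bridge"` emulates cells
#' that establish a persistently narrow neck from early anaphase, which
#' blocks or strongly suppresses passage of sizeable plasmids irrespective
#' of diffusion rate. `"wide_bridge"` emulates cells with a wide neck
#' throughout, whose transmission is the most sensitive to the diffusion
#' coefficient.
#'
#' @param name preset name
#' @return a [geometry_gen_params()]
#' @export
geometry_preset <- function(name = c("default", "narrow_bridge",
                                     "wide_bridge")) {
  switch(match.arg(name),
         default = geometry_gen_params(),
         narrow_bridge = geometry_gen_params(
           bridge_width_initial = c(0.16, 0.22),
           bridge_width_final = c(0.12, 0.16)),
         wide_bridge = geometry_gen_params(
           bridge_width_initial = c(0.7, 0.9),
           bridge_width_final = c(0.5, 0.7)))
}

runif_range <- function(r) runif(1, r[1], r[2])

#' Generate one synthetic anaphase geometry series
#'
#' The daughter lobe grows from near-zero with a smoothstep profile, the
#' bridge elongates linearly while its width interpolates between the
#' sampled initial and final values, and the mother narrows slightly. The
#' final daughter extents are rescaled so the closed-form spheroid volumes
#' hit a target daughter volume fraction sampled inside the configured
#' interval; infeasible draws are resampled (bounded retries).
#'
#' @param params a [geometry_gen_params()]
#' @param cell_id label for the series
#' @param seed optional seed (otherwise the current RNG state is used)
#' @return a [geometry_series()]
#' @export
generate_geometry_series <- function(params = geometry_gen_params(),
                                     cell_id = "synthetic", seed = NULL) {
  gen <- function() {
    for (try in 1:100) {
      dur <- round(runif_range(params$duration) / params$frame_spacing) *
        params$frame_spacing
      times <- seq(0, dur, by = params$frame_spacing)
      tau <- times / dur
      smooth <- 3 * tau^2 - 2 * tau^3
      Lm <- runif_range(params$mother_length)
      Wm <- runif_range(params$mother_width)
      Ld <- runif_range(params$daughter_length)
      Wd <- runif_range(params$daughter_width)
      Wb0 <- runif_range(params$bridge_width_initial)
      Wb1 <- runif_range(params$bridge_width_final)
      Lb0 <- runif_range(params$bridge_length_initial)
      Lb1 <- runif_range(params$bridge_length_final)
      fv <- params$daughter_volume_fraction
      f <- runif(1, fv[1] + 0.01, fv[2] - 0.01)
      # rescale the final daughter so closed-form volumes hit the target
      # fraction (bridge split evenly at its midpoint)
      Wm_fin <- 0.95 * Wm
      Vm <- pi / 6 * Lm * Wm_fin^2
      Vb <- pi * (Wb1 / 2)^2 * Lb1
      Vd_target <- (f * (Vm + Vb) - Vb / 2) / (1 - f)
      if (Vd_target <= 0) next
      s <- (Vd_target / (pi / 6 * Ld * Wd^2))^(1 / 3)
      if (s < 0.6 || s > 1.6) next
      Ld <- Ld * s
      Wd <- Wd * s
      s0 <- params$daughter_initial_scale
      dgrow <- s0 + (1 - s0) * smooth
      frames <- lapply(seq_along(times), function(i) {
        frame_from_extents(
          times[i],
          mother_length = Lm,
          mother_width = Wm * (1 - 0.05 * tau[i]),
          daughter_length = Ld * dgrow[i],
          daughter_width = Wd * dgrow[i],
          bridge_length = Lb0 + (Lb1 - Lb0) * tau[i],
          bridge_width = Wb0 + (Wb1 - Wb0) * smooth[i]
        )
      })
      return(geometry_series(cell_id, frames))
    }
    stopf("could not generate a feasible geometry in 100 attempts")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate an ensemble of synthetic cells
#'
#' @param n_cells number of cells
#' @param params a [geometry_gen_params()]
#' @param seed root seed; cell k uses substream `derive_seed(seed, k)`
#' @return named list of [geometry_series()]
#' @export
generate_geometry_ensemble <- function(n_cells, params = geometry_gen_params(),
                                       seed = 1L) {
  out <- lapply(seq_len(n_cells), function(k)
    generate_geometry_series(params, cell_id = sprintf("synth-%02d", k),
                             seed = derive_seed(seed, k)))
  names(out) <- vapply(out, `[[`, "", "cell_id")
  out
}

#' Synthetic planar Brownian jump dataset
#'
#' Planar (d = 2) Gaussian increments with per-axis variance 2*D*dt; the
#' squared magnitudes form a [jump_dataset()] for estimator validation.
#'
#' @param D true diffusion coefficient (um^2/s), >= 0
#' @param dt sampling interval (s)
#' @param n_steps number of jumps
#' @param seed optional seed
#' @return a [jump_dataset()]
#' @export
generate_brownian_track <- function(D, dt = 5, n_steps = 1000, seed = NULL) {
  gen <- function() {
    dx <- rnorm(n_steps, 0, sqrt(2 * D * dt))
    dy <- rnorm(n_steps, 0, sqrt(2 * D * dt))
    jump_dataset(dx^2 + dy^2, dt = dt, d = 2)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Synthetic colony counts for loss-rate validation
#'
#' Binomial colony counts at T0 and after `n_generations` of per-generation
#' retention (1 - loss rate). Non-selective counts are fixed at `plated`
#' (dense plating); selective counts are binomial draws.
#'
#' @param true_stability initial mitotic stability, in (0, 1]
#' @param true_loss_rate per-generation loss rate, in [0, 1)
#' @param n_generations generations of non-selective outgrowth
#' @param plated cells plated per condition
#' @param seed optional seed
#' @return list with `selective_T0`, `nonselective_T0`, `selective_T1`,
#'   `nonselective_T1`, `n_generations`
#' @export
generate_colony_counts <- function(true_stability, true_loss_rate,
                                   n_generations, plated = 1e5,
                                   seed = NULL) {
  if (true_stability <= 0 || true_stability > 1)
    stopf("true_stability must be in (0, 1]")
  if (true_loss_rate < 0 || true_loss_rate >= 1)
    stopf("true_loss_rate must be in [0, 1)")
  gen <- function() {
    p1 <- true_stability * (1 - true_loss_rate)^n_generations
    list(selective_T0 = rbinom(1, plated, true_stability),
         nonselective_T0 = plated,
         selective_T1 = rbinom(1, plated, p1),
         nonselective_T1 = plated,
         n_generations = n_generations)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
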