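# Measurement-side estimators: diffusion coefficient from tracked jumps,
# Freedman-Diaconis bin widths, mitotic stability, plasmid loss rate and
# binomial confidence intervals.

#' Jump dataset for diffusion estimation
#'
#' Squared displacement magnitudes of a tracked particle at a fixed sampling
#' interval. Tracking is typically planar (d = 2): with isotropic diffusion,
#' dropping the out-of-plane coordinate does not bias the estimate provided
#' the dimensionality is set accordingly. Jumps recorded against the nuclear
#' membrane are assumed to be excluded upstream, since the estimator targets
#' a free diffusion coefficient.
#'
#' @param jump_sq_displacements squared jump magnitudes (um^2), all >= 0
#' @param dt sampling interval (s), > 0
#' @param d tracking dimensionality, 1, 2 or 3
#' @return an object of class `jump_dataset`
#' @export
jump_dataset <- function(jump_sq_displacements, dt = 5, d = 2) {
  if (!length(jump_sq_displacements)) stopf("jump dataset is empty")
  if (any(jump_sq_displacements < 0)) stopf("squared jumps must be >= 0")
  if (dt <= 0) stopf("dt must be > 0")
  if (!d %in% 1:3) stopf("d must be 1, 2 or 3")
  structure(list(jump_sq_displacements = as.numeric(jump_sq_displacements),
                 dt = dt, d = as.integer(d)),
            class = "jump_dataset")
}

#' Diffusion coefficient from mean squared jump size
#'
#' Under Brownian motion the mean squared displacement over an interval dt
#' in d dimensions is 2*d*D*dt, so D = <x^2> / (2*d*dt) with <x^2> the mean
#' squared jump.
#'
#' @param jumps a [jump_dataset()]
#' @return the estimated diffusion coefficient (um^2/s)
#' @export
estimate_diffusion <- function(jumps) {
  stopifnot(inherits(jumps, "jump_dataset"))
  mean(jumps$jump_sq_displacements) / (2 * jumps$d * jumps$dt)
}

#' Freedman-Diaconis histogram bin width
#'
#' width = 2 * IQR * n^(-1/3), with the IQR computed by linear interpolation
#' between order statistics (quantile type 7, R's default); the rule is
#' convention-sensitive, so the convention is fixed here.
#'
#' @param values numeric vector, length >= 4
#' @return the bin width
#' @export
freedman_diaconis_width <- function(values) {
  if (length(values) < 4) stopf("need at least 4 values")
  iqr <- diff(quantile(values, c(0.25, 0.75), names = FALSE, type = 7))
  if (iqr == 0) stopf("degenerate data: interquartile range is zero")
  2 * iqr * length(values)^(-1 / 3)
}

#' Mitotic stability from colony counts
#'
#' Fraction of plated cells retaining the plasmid: colonies on selective
#' media divided by colonies on non-selective media. Ratios above 1 (counting
#' noise) are kept with a warning rather than rejected.
#'
#' @param selective_count colonies on selective plates, >= 0
#' @param nonselective_count colonies on non-selective plates, > 0
#' @return the stability proportion
#' @export
mitotic_stability <- function(selective_count, nonselective_count) {
  if (nonselective_count <= 0) stopf("nonselective count must be > 0")
  if (selective_count < 0) stopf("selective count must be >= 0")
  ratio <- selective_count / nonselective_count
  if (ratio > 1)
    warning("mitotic stability above 1 (", signif(ratio, 4),
            "): counting noise?", call. = FALSE)
  ratio
}

#' Per-generation plasmid loss rate
#'
#' rate = 1 - (T1/T0)^(1/n): the per-generation probability that a dividing
#' cell produces a plasmid-free daughter, from the mitotic stability before
#' (T0) and after (T1) n generations of non-selective outgrowth. The
#' composition property holds by construction: applying the per-generation
#' retention (1 - rate) n times returns T1/T0.
#'
#' @param T0 initial mitotic stability, in (0, 1]
#' @param T1 stability after outgrowth, in [0, 1]
#' @param n_generations number of generations elapsed, >= 1
#' @return loss rate per generation, in [0, 1] when T1 <= T0
#' @export
plasmid_loss_rate <- function(T0, T1, n_generations) {
  if (T0 <= 0 || T0 > 1) stopf("T0 must be in (0, 1]")
  if (T1 < 0 || T1 > 1) stopf("T1 must be in [0, 1]")
  if (n_generations < 1) stopf("n_generations must be >= 1")
  1 - (T1 / T0)^(1 / n_generations)
}

#' Normal-approximation binomial confidence interval
#'
#' p_hat +/- z * sqrt(p_hat * (1 - p_hat) / trials), clipped to [0, 1].
#' Degenerates to a zero-width interval at p_hat = 0 or 1 (documented
#' behaviour of the normal approximation). Vectorised over `successes`.
#'
#' @param successes number of successes, 0..trials
#' @param trials number of trials, >= 1
#' @param level confidence level (default 0.95)
#' @return list with `low` and `high`
#' @export
binomial_ci <- function(successes, trials, level = 0.95) {
  if (any(trials < 1)) stopf("trials must be >= 1")
  if (any(successes < 0 | successes > trials))
    stopf("successes must be between 0 and trials")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  half <- z * sqrt(p * (1 - p) / trials)
  list(low = pmax(0, p - half), high = pmin(1, p + half))
}

#' Read a jump CSV and estimate diffusion per group
#'
#' Expected columns: `cell_id`, `phase`, `jump_sq_um2`. One estimate per
#' phase group (and overall).
#'
#' @param path CSV path
#' @param dt sampling interval (s)
#' @param d tracking dimensionality
#' @return data.frame with `phase`, `n_jumps`, `D_um2_s`
#' @export
estimate_diffusion_file <- function(path, dt = 5, d = 2) {
  if (!file.exists(path)) stopf("jump file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("phase", "jump_sq_um2"))
    if (!col %in% names(df)) stopf("jump file %s: missing column '%s'",
                                   path, col)
  groups <- split(df$jump_sq_um2, df$phase)
  groups <- c(groups, list(all = df$jump_sq_um2))
  do.call(rbind, lapply(names(groups), function(g) {
    data.frame(phase = g, n_jumps = length(groups[[g]]),
               D_um2_s = estimate_diffusion(jump_dataset(groups[[g]], dt, d)))
  }))
}
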