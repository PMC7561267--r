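#' Experiment configuration
#'
#' A validated container for the reproducible experiment drivers. Every
#' stochastic element is controlled by `base_seed`: trial `t` at grid point
#' `g` uses seed `base_seed + 10000 * (g - 1) + t`, so any run is
#' bit-reproducible. The `"paper"` preset mirrors the source protocols
#' (2000 trials, 2000 beats); the `"scaled"` preset (default) keeps the same
#' structure at desk scale.
#'
#' @param model `"fhn"` or `"cml"`.
#' @param preset `"scaled"` or `"paper"`.
#' @param alpha_grid feedback strengths to sweep.
#' @param period_grid pacing periods (FHN sweeps).
#' @param gamma_grid map midpoints (CML sweeps).
#' @param n_ic initial conditions per phase-diagram grid point (1 near
#'   uniform + `n_ic - 1` random).
#' @param n_trials trials for histogram ensembles.
#' @param n_beats beats (FHN) or iterations (CML) per trial.
#' @param delta initial-condition heterogeneity half-width.
#' @param L lattice size.
#' @param base_seed integer base seed.
#' @param c_ref feedback reference (FHN); `NULL` uses the
#'   [feedback_config()] default.
#' @param dt FHN integrator step.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(model = c("fhn", "cml"),
                              preset = c("scaled", "paper"),
                              alpha_grid = 0, period_grid = 45,
                              gamma_grid = 0.7, n_ic = 6L,
                              n_trials = NULL, n_beats = NULL,
                              delta = 0.15, L = 128L, base_seed = 1L,
                              c_ref = NULL, dt = 0.01) {
  model <- match.arg(model)
  preset <- match.arg(preset)
  if (is.null(n_trials)) n_trials <- if (preset == "paper") 2000L else 100L
  if (is.null(n_beats)) n_beats <- if (preset == "paper") 2000L else 500L
  structure(list(model = model, preset = preset, alpha_grid = alpha_grid,
                 period_grid = period_grid, gamma_grid = gamma_grid,
                 n_ic = as.integer(n_ic), n_trials = as.integer(n_trials),
                 n_beats = as.integer(n_beats), delta = delta,
                 L = as.integer(L), base_seed = as.integer(base_seed),
                 c_ref = c_ref, dt = dt),
            class = "experiment_config")
}

# run one FHN trial under a config
.fhn_trial <- function(config, alpha, period, delta, seed, keep_field = TRUE,
                       tiny_perturbation = FALSE) {
  params <- fhn_params(L = config$L, dt = config$dt)
  fb <- if (is.null(config$c_ref)) feedback_config(alpha = alpha)
        else feedback_config(alpha = alpha, c_ref = config$c_ref)
  st <- random_initial_state(config$L, delta, seed = seed)
  if (tiny_perturbation) {
    set.seed(seed)
    st$w <- 0.5 + 1e-6 * runif(config$L, -1, 1)
  }
  run_paced(st, params, pacing_config(period = period,
                                      n_beats = config$n_beats), fb,
            keep_field = keep_field)
}

# run one CML trial under a config
.cml_trial <- function(config, alpha, gamma, delta, seed,
                       tiny_perturbation = FALSE) {
  par <- cml_params(gamma = gamma, L = config$L, alpha = alpha)
  c0 <- random_initial_cml(par, if (tiny_perturbation) 1e-6 else delta,
                           seed = seed)
  run_cml(c0, par, config$n_beats)
}

#' Phase-diagram sweep
#'
#' At each grid point -- (`alpha`, `period`) for the FHN lattice or
#' (`alpha`, `gamma`) for the CML -- runs `n_ic` trials: one near-uniform
#' initial condition (heterogeneity 1e-6, probing the stability of the
#' uniform branch rather than its symmetry-protected invariance) and
#' `n_ic - 1` random initial conditions at the configured `delta`. The point
#' label pools the per-trial classifications: `"Con_or_Dis_P2"` when both P2
#' types occur, `"DisP2_only"` / `"ConP2_only"` for a single type, `"P1"`
#' otherwise. Diverged trials are dropped and the point flagged.
#'
#' @param config an [experiment_config()].
#' @return an object of class `phase_diagram`: data frame with the grid
#'   coordinates, `label`, `n_dis`, `n_con`, `n_p1`, `flagged`.
#' @export
sweep_phase_diagram <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  fhn <- config$model == "fhn"
  grid <- expand.grid(alpha = config$alpha_grid,
                      x = if (fhn) config$period_grid else config$gamma_grid)
  names(grid)[2] <- if (fhn) "period" else "gamma"
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    labs <- character(0); flagged <- FALSE
    for (t in seq_len(config$n_ic)) {
      seed <- config$base_seed + 10000L * (g - 1L) + t
      tr <- tryCatch(
        if (fhn) .fhn_trial(config, grid$alpha[g], grid$period[g],
                            config$delta, seed, tiny_perturbation = (t == 1L))
        else .cml_trial(config, grid$alpha[g], grid$gamma[g],
                        config$delta, seed, tiny_perturbation = (t == 1L)),
        error = function(e) NULL)
      if (is.null(tr)) { flagged <- TRUE; next }
      labs <- c(labs, .label_trial(tr))
    }
    out[[g]] <- data.frame(
      grid[g, , drop = FALSE],
      label = .pool_labels(labs), n_dis = sum(labs == "Dis_P2"),
      n_con = sum(labs == "Con_P2"), n_p1 = sum(labs == "uniform_P1"),
      flagged = flagged, row.names = NULL)
  }
  structure(do.call(rbind, out),
            class = c("phase_diagram", "data.frame"), config = config)
}

# classify a single trial with thresholds relative to its own amplitude
.label_trial <- function(tr, m = 1L) {
  prof <- beat_difference(tr, m = m)
  amp <- max(abs(prof$delta))
  eps <- max(0.01 * amp, 1e-4)
  classify_pattern(prof, tr$global_peaks, eps_p1 = eps, eps_node = eps)$label
}

.pool_labels <- function(labs) {
  has_dis <- any(labs == "Dis_P2"); has_con <- any(labs == "Con_P2")
  if (has_dis && has_con) "Con_or_Dis_P2"
  else if (has_dis) "DisP2_only"
  else if (has_con) "ConP2_only"
  else "P1"
}

#' Histogram ensemble at a single parameter point
#'
#' Runs `n_trials` random-initial-condition trials at the first grid values
#' of the configuration and aggregates them with [ensemble_stats()]; this is
#' the domain-size / global-amplitude histogram protocol.
#'
#' @param config an [experiment_config()].
#' @param m averaging depth passed to [ensemble_stats()].
#' @param out optional directory; when given, the ensemble files are written
#'   via [write_ensemble_stats()].
#' @return an [ensemble_stats()] object (invisibly also written to `out`).
#' @export
histogram_experiment <- function(config, m = 1L, out = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  fhn <- config$model == "fhn"
  alpha <- config$alpha_grid[1]
  x <- if (fhn) config$period_grid[1] else config$gamma_grid[1]
  trials <- vector("list", config$n_trials)
  for (t in seq_len(config$n_trials)) {
    seed <- config$base_seed + t
    trials[[t]] <- if (fhn)
      .fhn_trial(config, alpha, x, config$delta, seed)
    else .cml_trial(config, alpha, x, config$delta, seed)
  }
  stats <- ensemble_stats(trials, m = m)
  if (!is.null(out)) write_ensemble_stats(stats, out, config = config)
  stats
}

#' Discordant-fraction curve versus initial heterogeneity
#'
#' For each heterogeneity level, runs `n_per_level` random-initial-condition
#' trials and records the fraction classified discordant, with an exact
#' binomial confidence interval. The reported `sigma_ini` is the standard
#' deviation `delta / sqrt(3)` of the Uniform\[-delta, delta\] perturbation.
#'
#' @param config an [experiment_config()]; its `alpha_grid[1]` and
#'   `period_grid[1]` / `gamma_grid[1]` select the parameter point.
#' @param delta_grid heterogeneity half-widths (>= 3 levels recommended).
#' @param n_per_level trials per level (the source protocol uses 100).
#' @param conf confidence level of the binomial interval.
#' @return data frame with `delta`, `sigma_ini`, `fraction_dis`, `lower`,
#'   `upper`, `n`.
#' @export
dis_p2_fraction_curve <- function(config, delta_grid,
                                  n_per_level = 100L, conf = 0.95) {
  stopifnot(inherits(config, "experiment_config"))
  fhn <- config$model == "fhn"
  alpha <- config$alpha_grid[1]
  x <- if (fhn) config$period_grid[1] else config$gamma_grid[1]
  rows <- lapply(seq_along(delta_grid), function(i) {
    d <- delta_grid[i]
    labs <- vapply(seq_len(n_per_level), function(t) {
      seed <- config$base_seed + 10000L * (i - 1L) + t
      tr <- if (fhn) .fhn_trial(config, alpha, x, d, seed, keep_field = TRUE)
            else .cml_trial(config, alpha, x, d, seed)
      .label_trial(tr)
    }, character(1))
    k <- sum(labs == "Dis_P2")
    ci <- binom.test(k, n_per_level, conf.level = conf)$conf.int
    data.frame(delta = d, sigma_ini = d / sqrt(3),
               fraction_dis = k / n_per_level, lower = ci[1], upper = ci[2],
               n = n_per_level)
  })
  do.call(rbind, rows)
}
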