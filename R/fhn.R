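#' FitzHugh-Nagumo lattice parameters
#'
#' Parameters of the 1D array of diffusively coupled FHN units. The defaults
#' reproduce the standard kinetics
#' \deqn{f(c, w) = -c(c-1)(c-c_{th}) - 0.1 w, \qquad
#'       g(c, w) = (c - 0.25 w - 0.3)/10,}
#' with excitation threshold \eqn{c_{th} = 0.5} and nearest-neighbour
#' diffusive coupling of strength \eqn{D = 0.1} under no-flux boundaries.
#'
#' @param L lattice length (number of units, >= 1; a single unit ignores `D`).
#' @param c_th excitation threshold of the cubic nullcline.
#' @param D diffusive coupling strength (>= 0).
#' @param inhibitor_weight coefficient multiplying `w` in the activator rate.
#' @param w_slope,w_offset,w_timescale inhibitor kinetics: `g = (c -
#'   w_slope*w - w_offset)/w_timescale`.
#' @param dt fixed integration step for the RK4 integrator (model time units).
#' @return an object of class `fhn_params`.
#' @seealso [run_paced()], [reaction_terms()]
#' @export
fhn_params <- function(L = 128L, c_th = 0.5, D = 0.1, inhibitor_weight = 0.1,
                       w_slope = 0.25, w_offset = 0.3, w_timescale = 10,
                       dt = 0.01) {
  L <- as.integer(L)
  if (L < 1L) stop("invalid lattice: L must be >= 1")
  if (dt <= 0) stop("dt must be positive")
  if (D < 0) stop("D must be non-negative")
  structure(list(L = L, c_th = c_th, D = D,
                 inhibitor_weight = inhibitor_weight, w_slope = w_slope,
                 w_offset = w_offset, w_timescale = w_timescale, dt = dt),
            class = "fhn_params")
}

#' Periodic pacing configuration
#'
#' @param period pacing period T (model time units).
#' @param pulse_duration stimulus pulse width \eqn{\Delta T} (must satisfy
#'   `0 < pulse_duration < period`).
#' @param amplitude pulse amplitude \eqn{I_0}.
#' @param n_beats number of beats to apply.
#' @return an object of class `pacing_config`.
#' @export
pacing_config <- function(period = 45, pulse_duration = 0.5, amplitude = 1.2,
                          n_beats = 500L) {
  n_beats <- as.integer(n_beats)
  if (pulse_duration <= 0 || pulse_duration >= period)
    stop("pulse_duration must lie strictly inside the pacing period")
  if (n_beats < 1L) stop("n_beats must be >= 1")
  structure(list(period = period, pulse_duration = pulse_duration,
                 amplitude = amplitude, n_beats = n_beats),
            class = "pacing_config")
}

#' Delayed-global-feedback configuration
#'
#' The stimulus amplitude of beat `n` is modulated by the previous beat's
#' global peak: \eqn{I_0 [1 + \alpha(\bar c_{n-1} - \bar c_s)]}. `alpha = 0`
#' disables the feedback. `c_ref` is the reference value \eqn{\bar c_s};
#' the default 0.77 is approximately the steady-state peak of `c` at the
#' single-unit P1-to-P2 bifurcation (see [single_unit_bifurcation_scan()]
#' to compute the value matched to the integrator in use).
#'
#' @param alpha feedback strength (signed; positive = positive feedback).
#' @param c_ref reference value \eqn{\bar c_s} for the feedback.
#' @return an object of class `feedback_config`.
#' @export
feedback_config <- function(alpha = 0, c_ref = 0.77) {
  if (!is.finite(c_ref)) stop("c_ref must be finite")
  structure(list(alpha = alpha, c_ref = c_ref), class = "feedback_config")
}

#' FHN reaction terms
#'
#' Pure kinetics of a single unit: returns the reaction part of the activator
#' rate, `f(c, w) = -c(c-1)(c-c_th) - inhibitor_weight*w`, and the inhibitor
#' rate `g(c, w) = (c - w_slope*w - w_offset)/w_timescale`. Vectorised over
#' `c` and `w`.
#'
#' @param c,w activator and inhibitor values.
#' @param params an [fhn_params()] object.
#' @return list with components `dc` (= f) and `dw` (= g).
#' @export
reaction_terms <- function(c, w, params = fhn_params()) {
  dc <- -c * (c - 1) * (c - params$c_th) - params$inhibitor_weight * w
  dw <- (c - params$w_slope * w - params$w_offset) / params$w_timescale
  list(dc = dc, dw = dw)
}

#' Discrete Laplacian with no-flux boundaries
#'
#' Interior sites receive `D*(c[j+1] + c[j-1] - 2*c[j])`; at the two ends the
#' missing neighbour is dropped (conservative zero-flux form), so the output
#' always sums to zero.
#'
#' @param c numeric vector of activator values (length >= 2).
#' @param D coupling strength.
#' @return numeric vector of the same length as `c`.
#' @export
laplacian_noflux <- function(c, D) {
  L <- length(c)
  if (L < 2L) stop("invalid lattice: need at least 2 sites")
  out <- numeric(L)
  out[1] <- D * (c[2] - c[1])
  if (L > 2L) {
    j <- 2:(L - 1)
    out[j] <- D * (c[j + 1] + c[j - 1] - 2 * c[j])
  }
  out[L] <- D * (c[L - 1] - c[L])
  out
}

#' Paced stimulus current with delayed global feedback
#'
#' Returns \eqn{I_0[1 + \alpha(\bar c_{n-1} - \bar c_s)]} while `t` lies in
#' the pulse window `[n*T, n*T + pulse_duration)` of beat `beat_index` (0
#' based) and 0 otherwise. The same current is applied to every lattice site
#' (global stimulation).
#'
#' @param t time.
#' @param beat_index beat number `n` (0-based).
#' @param prev_global_peak peak of the spatial average of `c` during beat
#'   `n - 1`.
#' @param pacing a [pacing_config()].
#' @param fb a [feedback_config()].
#' @return stimulus current (scalar, vectorised over `t`).
#' @export
stimulus <- function(t, beat_index, prev_global_peak, pacing = pacing_config(),
                     fb = feedback_config()) {
  tau <- t - beat_index * pacing$period
  amp <- pacing$amplitude * (1 + fb$alpha * (prev_global_peak - fb$c_ref))
  ifelse(tau >= 0 & tau < pacing$pulse_duration, amp, 0)
}

#' Construct a lattice state
#'
#' @param c,w numeric vectors of equal length: activator and inhibitor fields.
#' @param t current time.
#' @param beat_index current beat number (0-based).
#' @param prev_global_peak peak of the spatial-average signal during the
#'   previous beat; `NA` means "not yet paced" and [run_paced()] substitutes
#'   the feedback reference `c_ref`, making the first pulse exactly `I0`.
#' @return an object of class `lattice_state`.
#' @export
lattice_state <- function(c, w, t = 0, beat_index = 0L,
                          prev_global_peak = NA_real_) {
  if (length(c) != length(w)) stop("c and w must have identical length")
  structure(list(c = as.numeric(c), w = as.numeric(w), t = t,
                 beat_index = as.integer(beat_index),
                 prev_global_peak = prev_global_peak),
            class = "lattice_state")
}

#' Random initial lattice state
#'
#' Implements the heterogeneous initial-condition protocol: the inhibitor is
#' set to `w(j, 0) = 0.5 + delta * xi(j)` with `xi ~ Uniform[-1, 1]`, and the
#' activator starts on the rest branch at `c0` (default 0). `delta = 0` gives
#' a spatially uniform state. The standard deviation of the initial field is
#' reported as `sigma_ini = delta / sqrt(3)`.
#'
#' @param L number of lattice sites.
#' @param delta heterogeneity half-width (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @param c0 initial activator value applied uniformly.
#' @return a [lattice_state()] with attributes `seed` and `sigma_ini`.
#' @export
random_initial_state <- function(L, delta, seed = NULL, c0 = 0) {
  if (delta < 0) stop("invalid parameter: delta must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  w <- 0.5 + delta * runif(L, -1, 1)
  st <- lattice_state(rep(c0, L), w)
  attr(st, "seed") <- seed
  attr(st, "sigma_ini") <- delta / sqrt(3)
  st
}

#' Run a paced FHN lattice trial
#'
#' Integrates the coupled activator/inhibitor equations with the classical
#' fixed-step RK4 scheme, beat by beat. Within each beat window
#' `[n*T, (n+1)*T)` the per-site peak of `c` and the peak of the spatial
#' average \eqn{\bar c(t)} are recorded; after each beat the global peak
#' becomes the `prev_global_peak` that modulates the next beat's pulse.
#'
#' @param state a [lattice_state()] (see [random_initial_state()]).
#' @param params an [fhn_params()]; `params$L` must match the state.
#' @param pacing a [pacing_config()].
#' @param fb a [feedback_config()].
#' @param keep_field if `FALSE`, the per-site beat-peak field is not stored
#'   (saves memory for long scans; global peaks are always kept).
#' @param blowup_bound sanity bound: `|c|` exceeding it aborts with a
#'   divergence error naming the beat.
#' @return an object of class `fhn_trial`: list with `beat_peak_field`
#'   (`n_beats` x `L` matrix), `global_peaks` (length `n_beats`), `seed`,
#'   and the configuration objects.
#' @export
run_paced <- function(state, params, pacing, fb = feedback_config(),
                      keep_field = TRUE, blowup_bound = 100) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "fhn_params"),
            inherits(pacing, "pacing_config"), inherits(fb, "feedback_config"))
  if (length(state$c) != params$L)
    stop("state length does not match params$L")
  prev <- state$prev_global_peak
  if (is.na(prev)) prev <- fb$c_ref
  core <- .fhn_run_core(state$c, state$w, params$c_th, params$D,
                        params$inhibitor_weight, params$w_slope,
                        params$w_offset, params$w_timescale, params$dt,
                        pacing$period, pacing$pulse_duration,
                        pacing$amplitude, pacing$n_beats, fb$alpha, fb$c_ref,
                        prev, blowup_bound, keep_field)
  structure(list(beat_peak_field = if (keep_field) core$beat_peak_field else NULL,
                 global_peaks = as.numeric(core$global_peaks),
                 final_state = lattice_state(core$c_final, core$w_final,
                                             t = pacing$n_beats * pacing$period,
                                             beat_index = pacing$n_beats,
                                             prev_global_peak = tail(core$global_peaks, 1)),
                 seed = attr(state, "seed"),
                 params = params, pacing = pacing, feedback = fb,
                 boundary = "noflux"),
            class = "fhn_trial")
}

#' @export
print.fhn_trial <- function(x, ...) {
  cat(sprintf("FHN lattice trial: L = %d, T = %g, alpha = %g, %d beats\n",
              x$params$L, x$pacing$period, x$feedback$alpha,
              x$pacing$n_beats))
  gp <- tail(x$global_peaks, 2)
  cat(sprintf("  last two global peaks: %.6f %.6f (|diff| = %.3g)\n",
              gp[1], gp[2], abs(diff(gp))))
  invisible(x)
}

# steady-state consecutive-peak difference and final peak for one single-unit
# run at pacing period `period`
.single_unit_steady <- function(period, params, pacing, fb, blowup_bound = 100) {
  pac <- pacing_config(period = period, pulse_duration = pacing$pulse_duration,
                       amplitude = pacing$amplitude, n_beats = pacing$n_beats)
  st <- lattice_state(0, 0.5)
  tr <- run_paced(st, params, pac, fb, keep_field = FALSE,
                  blowup_bound = blowup_bound)
  gp <- tail(tr$global_peaks, 2)
  list(diff = abs(diff(gp)), peak = max(gp))
}

#' Locate the single-unit P1-to-P2 bifurcation in the pacing period
#'
#' Runs an uncoupled FHN unit (L = 1) across a grid of pacing periods,
#' flags periods whose steady-state consecutive-peak difference exceeds
#' `threshold` as period-2, then bisects between the largest period-2 grid
#' value and the next grid value above it to refine the transition. The
#' returned `c_peak_at_bif` is the steady-state peak of `c` just above the
#' bifurcation (the period-1 side of the final bracket); in the paper's
#' construction this value is the natural feedback reference \eqn{\bar c_s}.
#'
#' @param periods numeric grid of pacing periods spanning both regimes.
#' @param params an [fhn_params()]; only single-unit kinetics are used.
#' @param pacing a [pacing_config()] supplying the pulse shape and the number
#'   of beats used to reach steady state at each period.
#' @param fb a [feedback_config()].
#' @param threshold period-2 detection threshold on the consecutive-peak
#'   difference.
#' @param tol bisection tolerance on the period.
#' @return list with `T_bif` (critical period), `c_peak_at_bif`, and the
#'   per-grid-point diagnostics (`periods`, `diffs`).
#' @export
single_unit_bifurcation_scan <- function(periods,
                                         params = fhn_params(L = 1L),
                                         pacing = pacing_config(n_beats = 600L),
                                         fb = feedback_config(),
                                         threshold = 1e-3, tol = 0.01) {
  params <- fhn_params(L = 1L, c_th = params$c_th, D = params$D,
                       inhibitor_weight = params$inhibitor_weight,
                       w_slope = params$w_slope, w_offset = params$w_offset,
                       w_timescale = params$w_timescale, dt = params$dt)
  periods <- sort(periods)
  res <- lapply(periods, .single_unit_steady, params = params,
                pacing = pacing, fb = fb)
  diffs <- vapply(res, `[[`, numeric(1), "diff")
  p2 <- diffs > threshold
  if (!any(p2) || all(p2))
    stop("boundary not bracketed: the period grid lies entirely in one regime")
  i <- max(which(p2))
  if (i == length(periods))
    stop("boundary not bracketed: largest grid period is still period-2")
  lo <- periods[i]           # period-2 side
  hi <- periods[i + 1]       # period-1 side
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.single_unit_steady(mid, params, pacing, fb)$diff > threshold)
      lo <- mid else hi <- mid
  }
  list(T_bif = (lo + hi) / 2,
       c_peak_at_bif = .single_unit_steady(hi, params, pacing, fb)$peak,
       periods = periods, diffs = diffs)
}
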