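#' Beat-to-beat alternation profile
#'
#' Computes the spatial alternation profile
#' \deqn{\Delta c(j) = \frac{1}{m} \sum_{i=0}^{m-1} (-1)^i
#'   [c_{n-i}(j) - c_{n-i-1}(j)],}
#' the alternation-phase-aligned average of the last `m` consecutive-beat
#' differences ending at beat `n`. On an ideal period-2 field the result is
#' identical for every `m`; on noisy fields larger `m` averages the noise
#' down. `m = 1` is the plain last-pair difference.
#'
#' @param field matrix of per-beat per-site peaks (beats in rows), or an
#'   object with a `beat_peak_field` component ([run_paced()] /
#'   [run_cml()] results).
#' @param n final beat used (defaults to the last row).
#' @param m averaging depth (`n - m >= 1`).
#' @return an object of class `beat_diff_profile`: list with `delta`
#'   (length-`L` profile), `m`, `n`.
#' @export
beat_difference <- function(field, n = NULL, m = 1L) {
  if (!is.matrix(field)) field <- field$beat_peak_field
  if (is.null(n)) n <- nrow(field)
  if (m < 1L) stop("m must be >= 1")
  if (n - m < 1L || n > nrow(field))
    stop("insufficient beats for the requested (n, m)")
  delta <- numeric(ncol(field))
  for (i in 0:(m - 1))
    delta <- delta + (-1)^i * (field[n - i, ] - field[n - i - 1, ])
  structure(list(delta = delta / m, m = as.integer(m), n = as.integer(n)),
            class = "beat_diff_profile")
}

#' Classify a beat-difference profile
#'
#' Labels the spatiotemporal state of a trial: `uniform_P1` when the
#' alternation amplitude is everywhere below `eps_p1`; otherwise `Dis_P2`
#' when the profile changes sign between sites whose amplitude exceeds
#' `eps_node` (discordant domains separated by nodes), else `Con_P2`
#' (all sites alternate in phase). The label is invariant to a global flip
#' of the alternation phase.
#'
#' @param profile a [beat_difference()] result (or a plain numeric profile).
#' @param global_peaks optional per-beat global-peak series; when supplied
#'   the global P2 amplitude of the last two beats is recorded.
#' @param eps_p1 amplitude threshold below which the trial is period-1.
#' @param eps_node amplitude threshold for a site to count as alternating
#'   when looking for sign changes.
#' @return an object of class `pattern_label`: list with `label` (one of
#'   `"uniform_P1"`, `"Con_P2"`, `"Dis_P2"`), `max_amp`, `node_count`,
#'   `delta_gpeak`.
#' @export
classify_pattern <- function(profile, global_peaks = NULL, eps_p1 = 1e-4,
                             eps_node = eps_p1) {
  if (eps_p1 <= 0 || eps_node <= 0) stop("thresholds must be positive")
  delta <- if (inherits(profile, "beat_diff_profile")) profile$delta else profile
  max_amp <- max(abs(delta))
  dg <- if (!is.null(global_peaks)) global_p2_amplitude(global_peaks) else NA_real_
  if (max_amp < eps_p1) {
    label <- "uniform_P1"; nodes <- 0L
  } else {
    s <- sign(delta)[abs(delta) > eps_node]
    nodes <- sum(diff(s) != 0)
    label <- if (nodes >= 1L) "Dis_P2" else "Con_P2"
  }
  structure(list(label = label, max_amp = max_amp, node_count = as.integer(nodes),
                 delta_gpeak = dg),
            class = "pattern_label")
}

#' Detect nodes and domain sizes in a discordant profile
#'
#' A node is a site pair across which the alternation profile changes sign;
#' a domain is the run of sites between consecutive nodes, of size `l`.
#' Sites with `|delta| <= eps_node` never create nodes themselves: they are
#' attached to the preceding signed segment (a leading sub-threshold run
#' joins the first signed segment). Under `"noflux"` boundaries the terminal
#' segments count as domains; under `"periodic"` the first and last segments
#' are merged when they share a sign across the wrap. Domain sizes always
#' partition `L`.
#'
#' @param profile a [beat_difference()] result or numeric profile.
#' @param boundary `"noflux"` or `"periodic"`.
#' @param eps_node amplitude threshold for a site to carry a sign.
#' @return an object of class `domain_set`: list with `nodes` (site index of
#'   the left member of each sign-changing pair) and `domains` (integer run
#'   lengths summing to `L`).
#' @export
detect_domains <- function(profile, boundary = c("noflux", "periodic"),
                           eps_node = 1e-4) {
  boundary <- match.arg(boundary)
  delta <- if (inherits(profile, "beat_diff_profile")) profile$delta else profile
  L <- length(delta)
  s <- sign(delta) * (abs(delta) > eps_node)
  nz <- which(s != 0)
  if (!length(nz) || all(s[nz] == s[nz[1]]))
    stop("not discordant: no sign change in the alternation profile")
  s[seq_len(nz[1] - 1)] <- s[nz[1]]            # leading sub-threshold run
  for (j in seq(2, L)) if (s[j] == 0) s[j] <- s[j - 1]
  r <- rle(s)
  nodes <- cumsum(r$lengths)
  nodes <- nodes[-length(nodes)]
  domains <- r$lengths
  if (boundary == "periodic") {
    if (r$values[1] == r$values[length(r$values)] && length(domains) > 1) {
      domains[1] <- domains[1] + domains[length(domains)]
      domains <- domains[-length(domains)]
    } else {
      nodes <- c(nodes, L)                      # wrap node
    }
  }
  structure(list(nodes = as.integer(nodes), domains = as.integer(domains),
                 boundary = boundary, L = L),
            class = "domain_set")
}

#' Global period-2 amplitude
#'
#' The absolute difference between the global-peak values of the last two
#' beats, \eqn{\Delta\bar c_{peak}}. Zero for a global period-1 signal.
#'
#' @param global_peaks per-beat series of peaks of the spatial average.
#' @return a scalar.
#' @export
global_p2_amplitude <- function(global_peaks) {
  n <- length(global_peaks)
  if (n < 2) stop("need at least 2 beats")
  abs(global_peaks[n] - global_peaks[n - 1])
}

#' Ensemble statistics of spatiotemporal patterns
#'
#' Classifies each trial of an ensemble, pools the detected domain sizes of
#' discordant trials and the global P2 amplitudes into histograms, and
#' computes the fraction of discordant outcomes. The classification
#' thresholds are relative: `eps_frac` times the ensemble-median alternation
#' amplitude (floored at `eps_floor` so that an all-P1 ensemble is not
#' classified on numerical noise), which transfers between the FHN and CML
#' scales.
#'
#' @param trials list of [run_paced()] / [run_cml()] results (anything with
#'   `beat_peak_field`, `global_peaks` and a `boundary` tag).
#' @param m averaging depth for [beat_difference()].
#' @param eps_frac relative threshold (fraction of the median amplitude).
#' @param eps_floor absolute lower bound for the thresholds.
#' @param domain_breaks,amp_breaks histogram bin edges (defaults: unit bins
#'   over `0..L` for domains; 30 equal bins from 0 to just above the largest
#'   observed amplitude).
#' @return an object of class `ensemble_stats`: per-trial data frame
#'   (`seed`, `label`, `max_amp`, `node_count`, `delta_gpeak`), pooled
#'   `domains`, `domain_hist`, `amp_hist`, `fraction_dis`, thresholds used.
#' @export
ensemble_stats <- function(trials, m = 1L, eps_frac = 0.01, eps_floor = 1e-4,
                           domain_breaks = NULL, amp_breaks = NULL) {
  if (!length(trials)) stop("need at least one trial")
  profiles <- lapply(trials, beat_difference, m = m)
  amps <- vapply(profiles, function(p) max(abs(p$delta)), numeric(1))
  eps <- max(eps_frac * median(amps), eps_floor)
  L <- length(profiles[[1]]$delta)
  rows <- vector("list", length(trials))
  domains <- integer(0)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    lab <- classify_pattern(profiles[[i]], tr$global_peaks,
                            eps_p1 = eps, eps_node = eps)
    if (lab$label == "Dis_P2") {
      ds <- detect_domains(profiles[[i]],
                           boundary = if (identical(tr$boundary, "periodic"))
                             "periodic" else "noflux",
                           eps_node = eps)
      domains <- c(domains, ds$domains)
      nodes <- length(ds$nodes)
    } else nodes <- lab$node_count
    rows[[i]] <- data.frame(
      seed = if (is.null(tr$seed)) NA_integer_ else tr$seed,
      label = lab$label, max_amp = lab$max_amp, node_count = nodes,
      delta_gpeak = lab$delta_gpeak)
  }
  df <- do.call(rbind, rows)
  if (is.null(domain_breaks)) domain_breaks <- seq(0.5, L + 0.5, by = 1)
  if (is.null(amp_breaks))
    amp_breaks <- seq(0, max(c(df$delta_gpeak, 0.01), na.rm = TRUE) * 1.001,
                      length.out = 31)
  dh <- if (length(domains))
    graphics::hist(domains, breaks = domain_breaks, plot = FALSE) else NULL
  ah <- graphics::hist(df$delta_gpeak[!is.na(df$delta_gpeak)],
                       breaks = amp_breaks, plot = FALSE)
  structure(list(trials = df, domains = domains, domain_hist = dh,
                 amp_hist = ah, fraction_dis = mean(df$label == "Dis_P2"),
                 eps_p1 = eps, eps_node = eps, L = L),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  tab <- table(x$trials$label)
  cat(sprintf("Pattern ensemble: %d trials (L = %d)\n", nrow(x$trials), x$L))
  for (nm in names(tab)) cat(sprintf("  %-10s %d\n", nm, tab[[nm]]))
  cat(sprintf("  Dis-P2 fraction: %.3f; pooled domains: %d\n",
              x$fraction_dis, length(x$domains)))
  invisible(x)
}

#' Synthetic planted-pattern beat-peak field
#'
#' Builds a test fixture `c_n(j) = base + s(j) * amplitude * (-1)^n + noise`
#' where the sign profile `s(j)` starts at +1 and flips after each planted
#' node, together with its ground-truth domain decomposition.
#'
#' @param L lattice size.
#' @param node_positions strictly increasing site indices in `1..L-1` (left
#'   member of each sign-flipping pair); empty for a concordant field.
#' @param amplitude alternation amplitude `a`.
#' @param base baseline level `b`.
#' @param n_beats number of beats (rows).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed optional seed for the noise.
#' @return list with `field` (`n_beats` x `L` matrix), `truth` (a
#'   `domain_set` under no-flux reading), `sign_profile`.
#' @export
make_synthetic_pattern <- function(L, node_positions = integer(0),
                                   amplitude = 0.3, base = 0.7,
                                   n_beats = 10L, noise_sd = 0, seed = NULL) {
  node_positions <- as.integer(node_positions)
  if (length(node_positions) &&
      (any(diff(node_positions) <= 0) || any(node_positions < 1L) ||
       any(node_positions > L - 1L)))
    stop("node positions must be strictly increasing within 1..L-1")
  if (!is.null(seed)) set.seed(seed)
  sgn <- rep(1, L)
  for (p in node_positions) sgn[(p + 1):L] <- -sgn[p]
  field <- matrix(base, n_beats, L)
  for (n in seq_len(n_beats))
    field[n, ] <- base + sgn * amplitude * (-1)^n +
      if (noise_sd > 0) rnorm(L, 0, noise_sd) else 0
  sizes <- diff(c(0L, node_positions, L))
  truth <- structure(list(nodes = node_positions, domains = as.integer(sizes),
                          boundary = "noflux", L = L),
                     class = "domain_set")
  list(field = field, truth = truth, sign_profile = sgn)
}
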