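#' Coupled map lattice parameters
#'
#' Parameters of the discrete-time lattice in which the state `c_n(j)` is the
#' per-beat peak signal of unit `j` and one iteration corresponds to one
#' pacing beat. The single-unit map is the decreasing sigmoid
#' \deqn{f(c) = 0.2 + 0.8 / (1 + e^{(c - \gamma)/\mu}),}
#' spatial coupling uses a normalised Gaussian kernel of half-length `M` and
#' width `sigma_k`, and the delayed global feedback subtracts
#' \eqn{\alpha[f(\bar c_{n-1}) - f(\bar c_s)]} from every site. Boundaries
#' are periodic (Fourier modes are then exact eigenmodes of the
#' linearisation).
#'
#' @param gamma map midpoint.
#' @param L lattice size.
#' @param mu map slope scale (> 0).
#' @param M coupling half-length (`1 <= M < L/2`).
#' @param sigma_k Gaussian kernel width (> 0).
#' @param alpha feedback strength.
#' @return an object of class `cml_params`.
#' @export
cml_params <- function(gamma, L = 128L, mu = 0.1, M = 15L, sigma_k = 3,
                       alpha = 0) {
  L <- as.integer(L); M <- as.integer(M)
  if (mu <= 0) stop("mu must be positive")
  if (sigma_k <= 0) stop("sigma_k must be positive")
  if (M < 1L || M >= L / 2) stop("need 1 <= M < L/2")
  structure(list(gamma = gamma, L = L, mu = mu, M = M, sigma_k = sigma_k,
                 alpha = alpha, boundary = "periodic"),
            class = "cml_params")
}

#' Sigmoidal single-unit map
#'
#' `f(c) = 0.2 + 0.8/(1 + exp((c - gamma)/mu))`: strictly decreasing with
#' range (0.2, 1). The exponent is clamped against overflow.
#'
#' @param c input value(s).
#' @param gamma map midpoint.
#' @param mu slope scale (> 0).
#' @return mapped value(s) in (0.2, 1).
#' @export
map_f <- function(c, gamma, mu = 0.1) {
  z <- pmin(pmax((c - gamma) / mu, -700), 700)
  0.2 + 0.8 / (1 + exp(z))
}

#' Derivative of the single-unit map
#'
#' Analytic derivative of [map_f()]: with `u = (f(c) - 0.2)/0.8` it equals
#' `-(0.8/mu) * u * (1 - u)`, which is negative everywhere.
#'
#' @inheritParams map_f
#' @return derivative value(s), always < 0.
#' @export
map_f_prime <- function(c, gamma, mu = 0.1) {
  u <- (map_f(c, gamma, mu) - 0.2) / 0.8
  -(0.8 / mu) * u * (1 - u)
}

#' Gaussian spatial coupling kernel
#'
#' Weights `w_m` proportional to `exp(-m^2 / (2 sigma_k^2))` for
#' `m = -M, ..., M`, normalised so that they sum to 1 (the coupling term is
#' then a convex smoothing of the mapped field).
#'
#' @param M half-length (>= 1).
#' @param sigma_k Gaussian width (> 0).
#' @return an object of class `coupling_kernel`: list with `m` (offsets),
#'   `weights` (normalised), and `half_weights` (`w_m` for `m = 1..M`, used
#'   by the eigenvalue formulas).
#' @export
coupling_kernel <- function(M = 15L, sigma_k = 3) {
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  if (sigma_k <= 0) stop("sigma_k must be positive")
  m <- -M:M
  w <- exp(-m^2 / (2 * sigma_k^2))
  w <- w / sum(w)
  structure(list(m = m, weights = w, half_weights = w[M + 1 + (1:M)],
                 M = M, sigma_k = sigma_k),
            class = "coupling_kernel")
}

# periodic neighbour index matrix (L x (2M+1)), computed once per trajectory
.cml_index <- function(L, M) {
  outer(seq_len(L) - 1L, -M:M, function(j, m) (j + m) %% L + 1L)
}

#' One iteration of the coupled map lattice
#'
#' Applies
#' \deqn{c_n(j) = f[c_{n-1}(j)] + \sum_{m=-M}^{M} w_m \{f[c_{n-1}(j+m)] -
#'   f[c_{n-1}(j)]\} - \alpha[f(\bar c_{n-1}) - f(\bar c_s)]}
#' with periodic index arithmetic. \eqn{\bar c_{n-1}} is the spatial mean of
#' the incoming state. A uniform state at the fixed point `c_s` is invariant.
#'
#' @param c numeric vector: the incoming state `c_{n-1}(j)`.
#' @param params a [cml_params()].
#' @param kernel a [coupling_kernel()]; defaults to the one implied by
#'   `params`.
#' @param c_s fixed point of the map (`c_s = f(c_s)`); computed via
#'   [fixed_point()] when omitted.
#' @param idx optional precomputed neighbour index matrix (internal reuse).
#' @return the next state (numeric vector of the same length).
#' @export
cml_step <- function(c, params, kernel = NULL, c_s = NULL, idx = NULL) {
  L <- length(c)
  if (is.null(kernel)) kernel <- coupling_kernel(params$M, params$sigma_k)
  if (is.null(c_s)) c_s <- fixed_point(params$gamma, params$mu)$c_s
  if (is.null(idx)) idx <- .cml_index(L, kernel$M)
  fc <- map_f(c, params$gamma, params$mu)
  smoothed <- as.vector(matrix(fc[idx], nrow = L) %*% kernel$weights)
  smoothed - params$alpha *
    (map_f(mean(c), params$gamma, params$mu) - map_f(c_s, params$gamma, params$mu))
}

#' Iterate the coupled map lattice
#'
#' Runs [cml_step()] for `n_iters` beats and records the full field. The
#' result is pipeline-compatible with the FHN trials: `beat_peak_field` holds
#' the states (the CML state *is* the beat-peak field) and `global_peaks`
#' the spatial-mean series.
#'
#' @param initial numeric vector: initial state `c_0(j)`.
#' @param params a [cml_params()].
#' @param n_iters number of iterations (>= 1).
#' @param kernel optional [coupling_kernel()].
#' @param keep_field if `FALSE`, only the final state and mean series are
#'   kept.
#' @return an object of class `cml_trajectory`: `beat_peak_field`
#'   (`n_iters` x `L`), `global_peaks` (spatial means), `final_state`,
#'   `initial`, `params`.
#' @export
run_cml <- function(initial, params, n_iters, kernel = NULL,
                    keep_field = TRUE) {
  stopifnot(inherits(params, "cml_params"))
  if (n_iters < 1L) stop("n_iters must be >= 1")
  L <- length(initial)
  if (L != params$L) stop("initial state length does not match params$L")
  if (is.null(kernel)) kernel <- coupling_kernel(params$M, params$sigma_k)
  c_s <- fixed_point(params$gamma, params$mu)$c_s
  idx <- .cml_index(L, kernel$M)
  field <- if (keep_field) matrix(NA_real_, n_iters, L) else NULL
  means <- numeric(n_iters)
  cur <- as.numeric(initial)
  for (n in seq_len(n_iters)) {
    cur <- cml_step(cur, params, kernel, c_s, idx)
    if (keep_field) field[n, ] <- cur
    means[n] <- mean(cur)
  }
  structure(list(beat_peak_field = field, global_peaks = means,
                 final_state = cur, initial = as.numeric(initial),
                 params = params, c_s = c_s, boundary = "periodic",
                 seed = attr(initial, "seed")),
            class = "cml_trajectory")
}

#' Random initial condition for the CML
#'
#' `c(j, 0) = c_s + delta * xi(j)` with `xi ~ Uniform[-1, 1]`, the analogue
#' of the FHN random-inhibitor protocol.
#'
#' @param params a [cml_params()].
#' @param delta heterogeneity half-width (>= 0).
#' @param seed optional integer seed.
#' @return numeric vector of length `params$L` with attribute `seed`.
#' @export
random_initial_cml <- function(params, delta, seed = NULL) {
  if (delta < 0) stop("invalid parameter: delta must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  c_s <- fixed_point(params$gamma, params$mu)$c_s
  x <- c_s + delta * runif(params$L, -1, 1)
  attr(x, "seed") <- seed
  x
}

#' Seeded discordant-P2 initial fields
#'
#' Constructs candidate Dis-P2 states used to probe the stability of
#' discordant patterns: block patterns with `2`, `4` and `8` equal domains
#' alternating between the two-cycle values of the scalar DGF map, plus one
#' random-node pattern per seed. When the scalar map has no two-cycle at
#' these parameters, the blocks alternate `c_s +/- 0.15` instead.
#'
#' @param params a [cml_params()].
#' @param seeds integer vector; one random-node pattern is added per seed.
#' @return list of numeric vectors of length `params$L`.
#' @export
dis_p2_seed_fields <- function(params, seeds = 1L) {
  L <- params$L
  orb <- tryCatch(p2_orbit(params$gamma, params$mu, params$alpha),
                  error = function(e) NULL)
  if (is.null(orb)) {
    c_s <- fixed_point(params$gamma, params$mu)$c_s
    v <- c(c_s - 0.15, c_s + 0.15)
  } else v <- c(orb$c1, orb$c2)
  block <- function(ndom) {
    sizes <- rep(L %/% ndom, ndom)
    sizes[ndom] <- L - sum(sizes[-ndom])
    rep(v[rep_len(1:2, ndom)], times = sizes)
  }
  fields <- lapply(c(2L, 4L, 8L), block)
  for (s in seeds) {
    set.seed(s)
    nnode <- sample(3:8, 1)
    nodes <- sort(sample(seq_len(L - 1), nnode))
    sizes <- diff(c(0, nodes, L))
    fields <- c(fields, list(rep(v[rep_len(1:2, length(sizes))], times = sizes)))
  }
  fields
}
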