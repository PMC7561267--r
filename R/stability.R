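#' Fixed point of the single-unit map
#'
#' Solves `c_s = f(c_s)` on `[0.2, 1]`. The map is strictly decreasing and
#' maps the interval into itself, so the crossing is unique; it is located
#' by bracketed root finding to a residual below 1e-12.
#'
#' @param gamma map midpoint.
#' @param mu slope scale (> 0).
#' @return list with `c_s` and `f_prime_at_cs` (the derivative there).
#' @export
fixed_point <- function(gamma, mu = 0.1) {
  r <- uniroot(function(c) c - map_f(c, gamma, mu), c(0.2, 1),
               tol = 1e-14)$root
  list(c_s = r, f_prime_at_cs = map_f_prime(r, gamma, mu))
}

#' Scalar map with delayed global feedback
#'
#' For a single (uncoupled) unit the lattice equation reduces to
#' \deqn{c_n = f(c_{n-1}) - \alpha[f(c_{n-1}) - f(c_s)]
#'        = (1-\alpha) f(c_{n-1}) + \alpha f(c_s).}
#' At `alpha = 1` the map is constant at `c_s`; the fixed point `c_s` is
#' preserved for every `alpha`.
#'
#' @param c input value(s).
#' @param gamma,mu map parameters.
#' @param alpha feedback strength.
#' @param c_s fixed point (computed if omitted).
#' @return mapped value(s).
#' @export
scalar_dgf_map <- function(c, gamma, mu = 0.1, alpha = 0, c_s = NULL) {
  if (is.null(c_s)) c_s <- fixed_point(gamma, mu)$c_s
  (1 - alpha) * map_f(c, gamma, mu) + alpha * map_f(c_s, gamma, mu)
}

#' Eigenvalue of the uncoupled unit with feedback
#'
#' `lambda = (1 - alpha) * f'(c_s)`. Since `f' < 0`, negative `alpha`
#' increases `|lambda|` (destabilises) and positive `alpha` decreases it.
#'
#' @inheritParams scalar_dgf_map
#' @return the eigenvalue (scalar).
#' @export
uncoupled_eigenvalue <- function(gamma, mu = 0.1, alpha = 0) {
  (1 - alpha) * fixed_point(gamma, mu)$f_prime_at_cs
}

# spatial factor s_k = 1 - 4 * sum_{m=1}^{M} w_m sin^2(pi m k / L), k = 0..L-1
.spatial_factors <- function(kernel, L) {
  k <- 0:(L - 1)
  m <- seq_len(kernel$M)
  s2 <- outer(k, m, function(k, m) sin(pi * m * k / L)^2)
  1 - 4 * as.vector(s2 %*% kernel$half_weights)
}

.new_spectrum <- function(lambda, kind, pars) {
  L <- length(lambda)
  structure(list(k = 0:(L - 1), lambda = lambda, kind = kind,
                 stable = all(abs(lambda) < 1),
                 argmax_k = which.max(abs(lambda)) - 1L,
                 max_abs_lambda = max(abs(lambda)), params = pars),
            class = "cml_spectrum")
}

#' @export
print.cml_spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum, L = %d: max|lambda| = %.6f at k = %d (%s)\n",
              x$kind, length(x$lambda), x$max_abs_lambda, x$argmax_k,
              if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' Eigenvalue spectrum of the spatially uniform P1 state
#'
#' Linearising the lattice about the uniform fixed point gives, for Fourier
#' wave number `k`,
#' \deqn{\lambda_0 = (1-\alpha) f', \qquad
#'   \lambda_k = \Big(1 - 4\sum_{m=1}^{M} w_m \sin^2(\pi m k/L)\Big) f'
#'   \quad (k \ge 1),}
#' with `f'` evaluated at `c_s`. The feedback enters only the `k = 0` mode:
#' the uniform state itself does not depend on `alpha`, so all non-zero
#' modes are `alpha`-independent.
#'
#' @param gamma,mu map parameters.
#' @param alpha feedback strength.
#' @param kernel a [coupling_kernel()].
#' @param L lattice size (must exceed `2 * M`).
#' @return a `cml_spectrum` object with eigenvalues for `k = 0..L-1`.
#' @export
p1_spectrum <- function(gamma, mu = 0.1, alpha = 0,
                        kernel = coupling_kernel(), L = 128L) {
  if (L <= 2 * kernel$M) stop("need L > 2M")
  fp <- fixed_point(gamma, mu)$f_prime_at_cs
  lam <- .spatial_factors(kernel, L) * fp
  lam[1] <- (1 - alpha) * fp
  .new_spectrum(lam, "P1", list(gamma = gamma, mu = mu, alpha = alpha, L = L))
}

#' Two-cycle of the scalar feedback map
#'
#' Finds the period-2 orbit of [scalar_dgf_map()] by scanning
#' `F(F(c)) - c` on a 2001-point grid over (0.2, 1), bracketing sign
#' changes, refining each with bracketed root finding, and discarding roots
#' within 1e-6 of the fixed point. Errors (class `dgfpace_no_orbit`) when
#' the parameters are in the period-1 region.
#'
#' @inheritParams scalar_dgf_map
#' @return an object of class `p2_orbit`: `c1`, `c2` (the two-cycle,
#'   `c1 < c2`), and `f1_prime`, `f2_prime` (derivatives of the *raw* map
#'   `f` at the orbit, as used by the P2 spectrum).
#' @export
p2_orbit <- function(gamma, mu = 0.1, alpha = 0) {
  c_s <- fixed_point(gamma, mu)$c_s
  Fa <- function(c) scalar_dgf_map(c, gamma, mu, alpha, c_s)
  G <- function(c) Fa(Fa(c)) - c
  grid <- seq(0.2 + 1e-4, 1 - 1e-4, length.out = 2001)
  v <- G(grid)
  roots <- numeric(0)
  for (i in which(diff(sign(v)) != 0))
    roots <- c(roots, uniroot(G, grid[c(i, i + 1)], tol = 1e-13)$root)
  roots <- roots[abs(roots - c_s) > 1e-6]
  if (length(roots) < 2)
    stop(structure(class = c("dgfpace_no_orbit", "error", "condition"),
                   list(message = sprintf(
                     "no period-2 orbit at gamma = %g, alpha = %g (period-1 region)",
                     gamma, alpha), call = sys.call(-1))))
  c1 <- min(roots)
  c2 <- Fa(c1)
  if (abs(Fa(c2) - c1) > 1e-8)
    stop("two-cycle verification failed (non-converged root)")
  structure(list(c1 = c1, c2 = c2,
                 f1_prime = map_f_prime(c1, gamma, mu),
                 f2_prime = map_f_prime(c2, gamma, mu),
                 gamma = gamma, mu = mu, alpha = alpha, c_s = c_s),
            class = "p2_orbit")
}

#' Eigenvalue spectrum of the concordant P2 state
#'
#' The two-beat return map about the spatially uniform two-cycle gives
#' \deqn{\lambda_0 = (1-\alpha)^2 f_1' f_2', \qquad
#'   \lambda_k = \Big(1 - 4\sum_{m=1}^{M} w_m \sin^2(\pi m k/L)\Big)^2
#'   f_1' f_2' \quad (k \ge 1),}
#' where `f1'`, `f2'` are the derivatives of `f` at the two-cycle of the
#' scalar feedback map. The spatial factor is squared (two beats), so every
#' `k >= 1` eigenvalue carries the sign of `f1' f2' > 0`.
#'
#' @inheritParams p1_spectrum
#' @return a `cml_spectrum` object.
#' @export
p2_spectrum <- function(gamma, mu = 0.1, alpha = 0,
                        kernel = coupling_kernel(), L = 128L) {
  if (L <= 2 * kernel$M) stop("need L > 2M")
  orb <- p2_orbit(gamma, mu, alpha)
  ff <- orb$f1_prime * orb$f2_prime
  lam <- .spatial_factors(kernel, L)^2 * ff
  lam[1] <- (1 - alpha)^2 * ff
  .new_spectrum(lam, "P2", list(gamma = gamma, mu = mu, alpha = alpha, L = L))
}

.new_boundary <- function(df, which) {
  structure(df, class = c("boundary_curve", "data.frame"), which = which)
}

# upper-branch root of |(1-alpha) f'(c_s(gamma))| = 1 in gamma.
# |f'(c_s(gamma))| attains its maximum 0.8/(4 mu) at gamma = 0.6 and decreases
# on either side; the "upper" root lies at gamma > 0.6.
.gamma_at_abs_fprime <- function(target, mu, lower = 0.6, upper = 3) {
  h <- function(g) abs(fixed_point(g, mu)$f_prime_at_cs) - target
  if (h(lower) < 0 || h(upper) > 0)
    stop("root not bracketed: |f'| target outside attainable range")
  uniroot(h, c(lower, upper), tol = 1e-10)$root
}

#' Stability boundary of P1 in an uncoupled unit
#'
#' For each feedback strength, finds the upper `gamma` at which
#' `|(1 - alpha) f'(c_s)| = 1` (the period-doubling point of the scalar
#' feedback map). At `alpha = 0` the curve passes through `gamma` close to
#' 1.057.
#'
#' @param alpha_grid numeric vector of feedback strengths (`alpha < 1` with
#'   `|1 - alpha| * 0.8/(4 mu) > 1` required for a crossing).
#' @param mu map slope scale.
#' @return a `boundary_curve` data frame with columns `alpha`, `gamma`,
#'   `max_abs_lambda` (root residual check), `argmax_k`.
#' @export
boundary_uncoupled_p1 <- function(alpha_grid, mu = 0.1) {
  gam <- vapply(alpha_grid, function(a)
    .gamma_at_abs_fprime(1 / abs(1 - a), mu), numeric(1))
  lam <- vapply(seq_along(alpha_grid), function(i)
    abs(uncoupled_eigenvalue(gam[i], mu, alpha_grid[i])), numeric(1))
  .new_boundary(data.frame(alpha = alpha_grid, gamma = gam,
                           max_abs_lambda = lam, argmax_k = 0L),
                "uncoupled_p1")
}

#' Spatial stability boundary of the uniform P1 state
#'
#' Finds the single `gamma` at which the most unstable non-zero Fourier mode
#' of [p1_spectrum()] reaches `|lambda_k| = 1`. Because non-zero modes are
#' independent of `alpha`, the boundary is a horizontal line in the
#' (`alpha`, `gamma`) plane. The most unstable mode is the long-wavelength
#' `k = 1` (it minimises the smoothing sum for a positive kernel), so the
#' boundary lies strictly below the uncoupled value near 1.057.
#'
#' @param kernel a [coupling_kernel()].
#' @param L lattice size.
#' @param mu map slope scale.
#' @return list with `gamma`, the maximising wave number `k`, and the
#'   spatial factor `s_k` there.
#' @export
boundary_uniform_p1_spatial <- function(kernel = coupling_kernel(), L = 128L,
                                        mu = 0.1) {
  s <- .spatial_factors(kernel, L)[-1]
  k_star <- which.max(abs(s))
  s_max <- max(abs(s))
  list(gamma = .gamma_at_abs_fprime(1 / s_max, mu), k = k_star, s_k = s_max)
}

#' Stability boundary of the concordant P2 state
#'
#' For each `alpha`, finds the `gamma` at which the most unstable non-zero
#' mode of [p2_spectrum()] crosses `|lambda| = 1`. The two-cycle (and hence
#' `f1' f2'`) depends on `alpha`, so unlike the uniform-P1 spatial boundary
#' this curve is not horizontal. For `alpha <= 0` the spectrum stays inside
#' the unit circle below the period-doubling point and no boundary exists;
#' those grid entries return `NA` with a warning.
#'
#' @param alpha_grid numeric vector of feedback strengths.
#' @param kernel a [coupling_kernel()].
#' @param L lattice size.
#' @param mu map slope scale.
#' @param gamma_min lower end of the search window.
#' @return a `boundary_curve` data frame (`alpha`, `gamma`,
#'   `max_abs_lambda`, `argmax_k`), `NA` rows where no crossing exists.
#' @export
boundary_con_p2 <- function(alpha_grid, kernel = coupling_kernel(),
                            L = 128L, mu = 0.1, gamma_min = 0.3) {
  one <- function(a) {
    g_bif <- tryCatch(.gamma_at_abs_fprime(1 / abs(1 - a), mu),
                      error = function(e) NA_real_)
    if (is.na(g_bif)) return(c(NA_real_, NA_real_, NA_real_))
    h <- function(g) {
      sp <- p2_spectrum(g, mu, a, kernel, L)
      max(abs(sp$lambda[-1])) - 1
    }
    # just below the period-doubling point the orbit exists; scan down for a
    # sign change of max|lambda_k>=1| - 1
    gs <- seq(g_bif - 1e-4, gamma_min, length.out = 60)
    vals <- vapply(gs, function(g) tryCatch(h(g), error = function(e) NA_real_),
                   numeric(1))
    ok <- which(!is.na(vals))
    sc <- ok[which(diff(sign(vals[ok])) != 0)]
    if (!length(sc)) return(c(NA_real_, NA_real_, NA_real_))
    i <- sc[1]; j <- ok[ok > i][1]
    root <- uniroot(h, c(gs[j], gs[i]), tol = 1e-10)$root
    sp <- p2_spectrum(root, mu, a, kernel, L)
    c(root, sp$max_abs_lambda, sp$argmax_k)
  }
  res <- t(vapply(alpha_grid, one, numeric(3)))
  if (anyNA(res[, 1]))
    warning("no Con-P2 stability crossing for some alpha values (NA rows)")
  .new_boundary(data.frame(alpha = alpha_grid, gamma = res[, 1],
                           max_abs_lambda = res[, 2], argmax_k = res[, 3]),
                "con_p2")
}

#' Numerically determined stability boundary of discordant P2 states
#'
#' The stability of discordant patterns has no closed form; it is probed by
#' simulation. For each `gamma`, seeded Dis-P2 fields ([dis_p2_seed_fields()])
#' are iterated to steady state and classified; the boundary is located by
#' bisection on `alpha` as the smallest feedback strength at which any
#' seeded discordant pattern survives. Away from the point where all phase
#' boundaries meet, the result is close to `alpha = 0`: discordant patterns
#' decay for negative feedback.
#'
#' @param gamma_grid numeric vector of map midpoints.
#' @param alpha_bracket length-2 bracket straddling the transition.
#' @param kernel a [coupling_kernel()].
#' @param L lattice size.
#' @param seeds seeds for the random-node members of the seed library.
#' @param n_iters iteration budget per probe.
#' @param tol bisection tolerance on `alpha`.
#' @param mu map slope scale.
#' @return a `boundary_curve` data frame with columns `alpha`, `gamma`.
#' @export
boundary_dis_p2_numeric <- function(gamma_grid, alpha_bracket = c(-0.1, 0.1),
                                    kernel = coupling_kernel(), L = 128L,
                                    seeds = 1L, n_iters = 1000L, tol = 0.005,
                                    mu = 0.1) {
  survives <- function(gamma, alpha) {
    par <- cml_params(gamma = gamma, L = L, mu = mu, M = kernel$M,
                      sigma_k = kernel$sigma_k, alpha = alpha)
    for (f0 in dis_p2_seed_fields(par, seeds)) {
      tr <- run_cml(f0, par, n_iters, kernel, keep_field = FALSE)
      nxt <- cml_step(tr$final_state, par, kernel)
      d <- nxt - tr$final_state
      if (max(abs(d)) > 1e-3) {
        s <- sign(d)[abs(d) > 0.01 * max(abs(d))]
        if (any(diff(s) != 0) || s[1] != s[length(s)]) return(TRUE)
      }
    }
    FALSE
  }
  one <- function(gamma) {
    lo <- alpha_bracket[1]; hi <- alpha_bracket[2]
    if (survives(gamma, lo) || !survives(gamma, hi))
      stop("boundary not bracketed: seeded Dis-P2 fields do not change ",
           "stability across the alpha bracket at gamma = ", gamma)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (survives(gamma, mid)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  .new_boundary(data.frame(alpha = vapply(gamma_grid, one, numeric(1)),
                           gamma = gamma_grid), "dis_p2_numeric")
}
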