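test_that("fixed point and scalar feedback map behave as expected", {
  fp <- fixed_point(0.6)
  expect_equal(fp$c_s, 0.6, tolerance = 1e-10)      # midpoint symmetry
  expect_equal(fp$f_prime_at_cs, -2, tolerance = 1e-9)
  expect_lt(abs(fixed_point(1.057)$f_prime_at_cs + 1), 1e-2)
  # residual of the root
  for (g in c(0.5, 0.8, 1.1))
    expect_lt(abs(fixed_point(g)$c_s - map_f(fixed_point(g)$c_s, g)), 1e-10)
  # scalar map: alpha = 0 reduces to f; c_s is preserved; alpha = 1 collapses
  expect_equal(scalar_dgf_map(0.43, 0.8, alpha = 0), map_f(0.43, 0.8))
  cs8 <- fixed_point(0.8)$c_s
  for (a in c(-0.5, 0, 0.3, 1))
    expect_equal(scalar_dgf_map(cs8, 0.8, alpha = a), cs8, tolerance = 1e-10)
  expect_equal(scalar_dgf_map(0.31, 0.8, alpha = 1), cs8, tolerance = 1e-10)
})

test_that("uncoupled eigenvalue matches theory and a numeric Jacobian", {
  expect_equal(uncoupled_eigenvalue(0.6, alpha = 0), -2, tolerance = 1e-9)
  expect_equal(uncoupled_eigenvalue(0.6, alpha = 0.5), -1, tolerance = 1e-9)
  h <- 1e-7
  for (g in c(0.7, 1.0)) for (a in c(-0.2, 0, 0.3)) {
    cs <- fixed_point(g)$c_s
    fd <- (scalar_dgf_map(cs + h, g, alpha = a) -
           scalar_dgf_map(cs - h, g, alpha = a)) / (2 * h)
    expect_equal(uncoupled_eigenvalue(g, alpha = a), fd, tolerance = 1e-6)
  }
})

test_that("P1 spectrum: k = 0 carries the feedback, k >= 1 does not", {
  kern <- coupling_kernel()
  sp <- lapply(c(-0.2, 0, 0.2), function(a)
    p1_spectrum(1.057, alpha = a, kernel = kern, L = 64L))
  for (i in 1:3)
    expect_equal(sp[[i]]$lambda[1],
                 uncoupled_eigenvalue(1.057, alpha = c(-0.2, 0, 0.2)[i]))
  # non-zero modes identical across alpha
  expect_identical(sp[[1]]$lambda[-1], sp[[2]]$lambda[-1])
  expect_identical(sp[[2]]$lambda[-1], sp[[3]]$lambda[-1])
  # reflection symmetry lambda_k = lambda_{L-k}
  lam <- sp[[2]]$lambda
  expect_equal(lam[2:64], rev(lam[2:64]))
})

test_that("P1 spectrum matches one-step growth of seeded Fourier modes", {
  L <- 32L
  g <- 0.95
  kern <- coupling_kernel()
  cs <- fixed_point(g)$c_s
  eps <- 1e-7
  for (a in c(0, 0.25)) {
    par <- cml_params(gamma = g, L = L, alpha = a)
    sp <- p1_spectrum(g, alpha = a, kernel = kern, L = L)
    for (k in c(0L, 1L, 2L, L / 2L)) {
      mode <- if (k == 0L) rep(1, L) else cos(2 * pi * k * (0:(L - 1)) / L)
      out <- cml_step(cs + eps * mode, par, kern, cs)
      growth <- sum((out - cs) * mode) / (eps * sum(mode * mode))
      expect_equal(growth, sp$lambda[k + 1], tolerance = 1e-4)
    }
  }
})

test_that("the two-cycle of the scalar map is found and verified", {
  orb <- p2_orbit(0.6, alpha = 0)
  # antisymmetry about the midpoint forces a symmetric two-cycle
  expect_equal(orb$c1 + orb$c2, 1.2, tolerance = 1e-9)
  Fa <- function(c) scalar_dgf_map(c, 0.6, alpha = 0)
  expect_lt(abs(Fa(orb$c1) - orb$c2), 1e-10)
  expect_lt(abs(Fa(orb$c2) - orb$c1), 1e-10)
  # brute-force iteration lands on the same attractor
  x <- 0.31
  for (i in 1:2000) x <- Fa(x)
  expect_equal(sort(c(x, Fa(x))), sort(c(orb$c1, orb$c2)), tolerance = 1e-8)
  # feedback-dependent orbit: definition check at alpha = 0.3
  orb3 <- p2_orbit(0.7, alpha = 0.3)
  Fa3 <- function(c) scalar_dgf_map(c, 0.7, alpha = 0.3)
  expect_lt(abs(Fa3(orb3$c1) - orb3$c2), 1e-10)
  expect_lt(abs(Fa3(orb3$c2) - orb3$c1), 1e-10)
  # period-1 side: no orbit
  expect_error(p2_orbit(1.2, alpha = 0), "no period-2 orbit")
})

test_that("P2 spectrum composes the two per-step multipliers", {
  kern <- coupling_kernel()
  for (a in c(0, 0.3)) {
    orb <- p2_orbit(0.7, alpha = a)
    sp <- p2_spectrum(0.7, alpha = a, kernel = kern, L = 64L)
    expect_equal(sp$lambda[1],
                 (1 - a) * orb$f1_prime * (1 - a) * orb$f2_prime)
    # squared spatial factor: all k >= 1 eigenvalues share the sign of f1'f2'
    expect_true(all(sp$lambda[-1] > 0))
    expect_equal(sp$lambda[2:64], rev(sp$lambda[2:64]))
  }
})

test_that("P2 spectrum matches the two-step Jacobian of the lattice", {
  L <- 32L
  g <- 0.7
  kern <- coupling_kernel()
  eps <- 1e-7
  for (a in c(0, 0.3)) {
    par <- cml_params(gamma = g, L = L, alpha = a)
    orb <- p2_orbit(g, alpha = a)
    sp <- p2_spectrum(g, alpha = a, kernel = kern, L = L)
    cs <- fixed_point(g)$c_s
    for (k in c(0L, 1L, 2L, L / 2L)) {
      mode <- if (k == 0L) rep(1, L) else cos(2 * pi * k * (0:(L - 1)) / L)
      x <- orb$c1 + eps * mode
      x <- cml_step(x, par, kern, cs)
      x <- cml_step(x, par, kern, cs)
      growth <- sum((x - orb$c1) * mode) / (eps * sum(mode * mode))
      expect_equal(growth, sp$lambda[k + 1], tolerance = 1e-4)
    }
  }
})

test_that("the uncoupled P1 boundary passes through the reference point", {
  b <- boundary_uncoupled_p1(c(-0.2, 0, 0.2, 0.4))
  g0 <- b$gamma[b$alpha == 0]
  expect_equal(g0, 1.057, tolerance = 0.01)
  # each point sits on |lambda| = 1
  for (i in seq_len(nrow(b)))
    expect_lt(abs(abs(uncoupled_eigenvalue(b$gamma[i], alpha = b$alpha[i])) - 1),
              1e-8)
  # stronger positive feedback tolerates a steeper map: gamma decreases
  expect_true(all(diff(b$gamma) < 0))
  # alpha = 0.5 cannot bracket (|1 - alpha| |f'|max = 1 exactly)
  expect_error(boundary_uncoupled_p1(0.6), "not bracketed")
})

test_that("the spatial P1 boundary is alpha-independent and below the uncoupled one", {
  kern <- coupling_kernel()
  b <- boundary_uniform_p1_spatial(kern, L = 128L)
  expect_identical(b$k, 1L)  # long-wavelength mode is the most unstable
  g0 <- boundary_uncoupled_p1(0)$gamma
  expect_lt(b$gamma, g0)
  sp <- p1_spectrum(b$gamma, kernel = kern, L = 128L)
  expect_lt(abs(max(abs(sp$lambda[-1])) - 1), 1e-8)
  # alpha never enters: same non-zero-mode maximum for any alpha
  sp2 <- p1_spectrum(b$gamma, alpha = 0.4, kernel = kern, L = 128L)
  expect_identical(sp$lambda[-1], sp2$lambda[-1])
})

test_that("the Con-P2 boundary depends on alpha and meets the others", {
  kern <- coupling_kernel()
  b <- boundary_con_p2(c(0.1, 0.2, 0.3), kernel = kern, L = 128L)
  expect_false(anyNA(b$gamma))
  expect_gt(diff(range(b$gamma)), 0.02)  # genuinely non-horizontal
  for (i in seq_len(nrow(b)))
    expect_lt(abs(b$max_abs_lambda[i] - 1), 1e-8)
  # near alpha -> 0+ all boundaries approach a common meeting point
  bsmall <- boundary_con_p2(0.02, kernel = kern, L = 128L)
  gspatial <- boundary_uniform_p1_spatial(kern, L = 128L)$gamma
  guncoupled <- boundary_uncoupled_p1(0.02)$gamma
  expect_lt(abs(bsmall$gamma - gspatial), 0.02)
  expect_lt(abs(bsmall$gamma - guncoupled), 0.02)
})

test_that("the numeric Dis-P2 boundary sits at alpha close to zero", {
  kern <- coupling_kernel()
  b <- boundary_dis_p2_numeric(0.7, alpha_bracket = c(-0.08, 0.08),
                               kernel = kern, L = 64L, seeds = 1L,
                               n_iters = 400L, tol = 0.01)
  expect_lt(abs(b$alpha), 0.03)
  # negative feedback: every seeded discordant field decays
  par_neg <- cml_params(gamma = 0.7, L = 64L, alpha = -0.05)
  for (f0 in dis_p2_seed_fields(par_neg, seeds = 1L)) {
    tr <- run_cml(f0, par_neg, 400L, kern)
    expect_false(label_fx(tr) == "Dis_P2")
  }
})
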