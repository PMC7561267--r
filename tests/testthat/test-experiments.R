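test_that("experiment configurations validate and round-trip through JSON", {
  cfg <- experiment_config(model = "cml", alpha_grid = c(0, 0.3),
                           gamma_grid = 0.7, n_ic = 3L, n_beats = 200L,
                           delta = 0.2, L = 64L, base_seed = 42L)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg2 <- do.call(experiment_config,
                  back[intersect(names(back), names(formals(experiment_config)))])
  expect_equal(unclass(cfg), unclass(cfg2))
})

test_that("CML phase sweep matches the sign-of-feedback region structure", {
  cfg <- experiment_config(model = "cml", alpha_grid = c(-0.2, 0.3),
                           gamma_grid = 0.7, n_ic = 4L, n_beats = 400L,
                           delta = 0.2, L = 64L, base_seed = 1L)
  pd <- sweep_phase_diagram(cfg)
  neg <- pd[pd$alpha == -0.2, ]
  pos <- pd[pd$alpha == 0.3, ]
  expect_equal(neg$n_dis, 0)         # negative feedback: no discordant P2
  expect_gt(pos$n_dis, 0)            # positive feedback: discordant present
  expect_false(any(pd$flagged))
})

test_that("FHN phase sweep separates negative and positive feedback", {
  cfg <- experiment_config(model = "fhn", alpha_grid = c(-0.2, 0.2),
                           period_grid = 45, n_ic = 5L, n_beats = 250L,
                           delta = 3, L = 64L, base_seed = 1L)
  pd <- sweep_phase_diagram(cfg)
  expect_equal(pd$n_dis[pd$alpha == -0.2], 0)
  expect_identical(pd$label[pd$alpha == -0.2], "ConP2_only")
  # both pattern types obtainable with different initial conditions
  expect_identical(pd$label[pd$alpha == 0.2], "Con_or_Dis_P2")
})

test_that("sweeps are bit-reproducible", {
  cfg <- experiment_config(model = "cml", alpha_grid = 0.3, gamma_grid = 0.7,
                           n_ic = 3L, n_beats = 200L, delta = 0.2, L = 64L,
                           base_seed = 7L)
  pd1 <- sweep_phase_diagram(cfg)
  pd2 <- sweep_phase_diagram(cfg)
  expect_identical(as.data.frame(pd1), as.data.frame(pd2))
})

test_that("negative feedback excludes discordant patterns across an ensemble", {
  # 50 random-IC trials in the P2 regime at alpha = -0.2, maximal
  # heterogeneity: concordant only, independent of initial conditions
  labs <- vapply(1:50, function(s)
    label_fx(fhn_trial_fx(alpha = -0.2, period = 45, delta = 3, seed = s,
                          L = 64L, n_beats = 250L)), character(1))
  expect_identical(sum(labs == "Dis_P2"), 0L)
  expect_true(all(labs %in% c("uniform_P1", "Con_P2")))
})

test_that("discordant fraction grows with initial heterogeneity", {
  cfg <- experiment_config(model = "fhn", alpha_grid = 0, period_grid = 45,
                           n_beats = 300L, delta = 0.15, L = 128L,
                           base_seed = 3L)
  curve <- dis_p2_fraction_curve(cfg, delta_grid = c(0.15, 1.5, 3),
                                 n_per_level = 50L)
  expect_equal(curve$sigma_ini, c(0.15, 1.5, 3) / sqrt(3))
  expect_equal(curve$fraction_dis[1], 0)         # tiny heterogeneity: none
  expect_gt(curve$fraction_dis[3], 0)            # strong heterogeneity: some
  # non-decreasing trend (soft check within binomial uncertainty)
  expect_true(all(diff(curve$fraction_dis) >= -0.05))
})

test_that("histogram ensembles and domain support behave as expected", {
  cfg <- experiment_config(model = "fhn", alpha_grid = 0, period_grid = 45,
                           n_trials = 20L, n_beats = 300L, delta = 3,
                           L = 128L, base_seed = 101L)
  st <- histogram_experiment(cfg)
  expect_equal(nrow(st$trials), 20L)
  if (length(st$domains)) {
    # without feedback, domains avoid the extremes: a minimum domain size
    # l_min is enforced by diffusive coarsening
    expect_true(all(st$domains >= 3))
    expect_true(all(st$domains <= 128 - 3))
  }
  # per-trial domains partition the lattice
  dis_rows <- which(st$trials$label == "Dis_P2")
  expect_equal(length(st$domains) - sum(st$trials$node_count[dis_rows] + 1) ,
               0)
})

test_that("trial serialisation round-trips through CSV and JSON", {
  tr <- fhn_trial_fx(alpha = 0.2, delta = 0.5, seed = 2, L = 16L,
                     n_beats = 30L)
  prefix <- file.path(tempdir(), "trial_a")
  paths <- write_trial_result(tr, prefix)
  expect_true(all(file.exists(paths)))
  f <- read_beat_peak_field(paste0(prefix, "_field.csv"))
  expect_equal(unname(f), unname(tr$beat_peak_field), tolerance = 1e-12)
  cfg <- jsonlite::read_json(paste0(prefix, "_config.json"),
                             simplifyVector = TRUE)
  expect_equal(cfg$pacing$period, 45)
  expect_equal(cfg$feedback$alpha, 0.2)
  # ensemble outputs
  st <- ensemble_stats(list(tr, fhn_trial_fx(alpha = 0.2, delta = 0.5,
                                             seed = 3, L = 16L,
                                             n_beats = 30L)))
  out <- write_ensemble_stats(st, file.path(tempdir(), "ens_out"))
  expect_true(all(file.exists(out)))
})

test_that("the CLI classifies a field file and reports boundaries", {
  syn <- make_synthetic_pattern(32, c(16), amplitude = 0.3, base = 0.7,
                                n_beats = 8)
  path <- file.path(tempdir(), "field.csv")
  f <- syn$field
  colnames(f) <- paste0("site_", 1:32)
  write.csv(as.data.frame(f), path, row.names = FALSE)
  lab <- dgfpace_cli(c("classify", path))
  expect_identical(lab$label, "Dis_P2")
  # simulate-cml subcommand writes the three sidecar files
  cfgp <- file.path(tempdir(), "cfg.json")
  jsonlite::write_json(list(gamma_grid = 0.7, alpha_grid = 0.3, L = 32,
                            n_beats = 50, delta = 0.2),
                       cfgp, auto_unbox = TRUE)
  outp <- file.path(tempdir(), "cml_run")
  res <- dgfpace_cli(c("simulate-cml", "--config", cfgp, "--seed", "4",
                       "--out", outp))
  expect_true(file.exists(paste0(outp, "_global_peaks.csv")))
  expect_s3_class(res, "cml_trajectory")
})
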