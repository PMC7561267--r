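# Shared fixtures: small, fast configurations used across test files.

# one FHN lattice trial with the standard kinetics
fhn_trial_fx <- function(alpha = 0, period = 45, delta = 0.15, seed = 1,
                         L = 64L, n_beats = 250L, c_ref = 0.77,
                         keep_field = TRUE) {
  st <- random_initial_state(L, delta, seed = seed)
  run_paced(st, fhn_params(L = L),
            pacing_config(period = period, n_beats = n_beats),
            feedback_config(alpha = alpha, c_ref = c_ref),
            keep_field = keep_field)
}

# label a trial the way the experiment drivers do
label_fx <- function(tr, m = 1L) {
  prof <- beat_difference(tr, m = m)
  eps <- max(0.01 * max(abs(prof$delta)), 1e-4)
  classify_pattern(prof, tr$global_peaks, eps_p1 = eps, eps_node = eps)$label
}

# one CML trajectory from a random initial condition
cml_trial_fx <- function(gamma = 0.7, alpha = 0, delta = 0.2, seed = 1,
                         L = 128L, n_iters = 800L) {
  par <- cml_params(gamma = gamma, L = L, alpha = alpha)
  run_cml(random_initial_cml(par, delta, seed = seed), par, n_iters)
}
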