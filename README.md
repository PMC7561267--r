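# dgfpace

Delayed global feedback (DGF) in periodically paced excitable media: models,
stability theory and pattern statistics.

## The problem

Paced excitable media — calcium release units inside a cardiac myocyte,
coupled myocytes in tissue, clustered neurons — respond to fast pacing with
period-2 rhythms ("alternans"): the excitation amplitude alternates
large/small beat to beat. Spatially the alternation can be **concordant**
(Con-P2, all sites in phase) or **discordant** (Dis-P2, out-of-phase domains
separated by nodes). Because the units are driven by a *global* signal
(voltage, contraction) that the previous beat helped shape, the medium sits
inside a delayed global feedback loop with delay equal to the pacing period
*T*. The sign of that feedback decides which patterns can exist:

* no feedback (α = 0): Con-P2 and spatially random Dis-P2, depending on
  initial conditions;
* negative feedback (α < 0): concordant patterns only;
* positive feedback (α > 0): both, but discordant patterns must keep the
  *global* signal period-1, which bounds every domain by L/2.

## Models

**FHN lattice** — a 1D array of diffusively coupled FitzHugh–Nagumo units,

    dc_j/dt = -c_j(c_j-1)(c_j-0.5) - 0.1 w_j + D (c_{j+1}+c_{j-1}-2c_j) + I(t)
    dw_j/dt = (c_j - 0.25 w_j - 0.3)/10,

paced by a square pulse whose amplitude carries the feedback,
`I0 [1 + α (c̄_{n-1} − c̄s)]` during `[nT, nT+ΔT)` (I0 = 1.2, ΔT = 0.5),
with `c̄_{n-1}` the previous beat's peak of the spatial average. Integration:
fixed-step RK4 (dt = 0.01) in compiled code.

**Coupled map lattice (CML)** — one iteration per beat,

    c_n(j) = f[c_{n-1}(j)] + Σ_m w_m {f[c_{n-1}(j+m)] − f[c_{n-1}(j)]}
             − α [f(c̄_{n-1}) − f(c̄s)],

with the decreasing sigmoid `f(c) = 0.2 + 0.8/(1+exp((c−γ)/μ))` (μ = 0.1)
and a normalised Gaussian kernel (M = 15, σ = 3). Closed-form eigenvalue
spectra for the uniform P1 state, `λ_0 = (1−α) f'`,
`λ_k = (1 − 4 Σ_m w_m sin²(πmk/L)) f'`, and for the concordant P2 state
(squared spatial factor times `f1' f2'`) give the phase-boundary curves; the
Dis-P2 boundary is located by simulation.

A pattern pipeline classifies beat-peak fields (uniform P1 / Con-P2 /
Dis-P2), detects nodes and domain sizes, and aggregates ensemble histograms;
experiment drivers sweep phase diagrams and heterogeneity curves with fully
seeded, bit-reproducible protocols.

## Worked example

```r
library(dgfpace)

# where does the single paced FHN unit period-double?
scan <- single_unit_bifurcation_scan(seq(40, 52, by = 4),
                                     pacing = pacing_config(n_beats = 600))
scan$T_bif          # 46.1367 -- alternans onset as T decreases
scan$c_peak_at_bif  # 0.8156  -- steady-state peak there (the natural c̄s)

# a discordant pattern under positive feedback: global signal is period-1
st <- random_initial_state(128, delta = 3, seed = 1001)
tr <- run_paced(st, fhn_params(L = 128),
                pacing_config(period = 45.5, n_beats = 600),
                feedback_config(alpha = 0.4, c_ref = scan$c_peak_at_bif))
prof <- beat_difference(tr)
classify_pattern(prof, tr$global_peaks, 5e-3, 5e-3)$label  # "Dis_P2"
detect_domains(prof, "noflux", 5e-3)$domains               # 25 24 38 41
global_p2_amplitude(tr$global_peaks)                       # 7.8e-04 (~0)

# CML stability: the period-doubling point of the map
boundary_uncoupled_p1(0)$gamma                             # 1.0591
p1_spectrum(1.0, alpha = 0.2, kernel = coupling_kernel(), L = 128)
# P1 spectrum, L = 128: max|lambda| = 1.194157 at k = 1 (unstable)
```

The domain sizes partition L = 128 and each is ≤ L/2 = 64, and the global
alternation amplitude is ~1e-3 of the site amplitude — the positive-feedback
selection rule at work.

## Command line

```sh
inst/cli/dgfpace simulate-fhn  --config cfg.json --seed 1 --out runs/trial
inst/cli/dgfpace sweep         --config cfg.json --out runs/sweep
inst/cli/dgfpace classify runs/trial_field.csv
```
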