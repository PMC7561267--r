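---
title: "Delayed global feedback and discordant alternans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed global feedback and discordant alternans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgfpace)
```

## The scientific problem

Periodically paced excitable media — arrays of calcium release units inside a
cardiac myocyte, electrically coupled myocytes in tissue, clustered neurons —
often respond to fast pacing with a period-2 (P2) rhythm: the excitation
amplitude alternates large/small from beat to beat ("alternans" in the cardiac
literature). Spatially, the alternation can be *concordant* (Con-P2: every
site alternates in phase) or *discordant* (Dis-P2: out-of-phase regions
separated by *nodes*, the runs between nodes being *domains* of size $l$).

In many of these systems the units are driven by a global signal (membrane
voltage for subcellular calcium; mechanical contraction for tissue). Because a
change in the present beat influences the drive of the next beat, the medium
sits inside a *delayed global feedback* (DGF) loop whose delay equals the
pacing period $T$. This package implements two desk-scale models of that
situation and the analysis pipeline needed to characterise the resulting
patterns.

## Model 1: the FitzHugh–Nagumo (FHN) lattice

A 1D array of $L$ diffusively coupled FHN units:

$$\frac{dc_j}{dt} = f(c_j, w_j) + D\,(c_{j+1} + c_{j-1} - 2 c_j) + I(t),
\qquad \frac{dw_j}{dt} = g(c_j, w_j),$$

with the standard kinetics $f(c,w) = -c(c-1)(c-c_{th}) - 0.1\,w$ and
$g(c,w) = (c - 0.25\,w - 0.3)/10$, threshold $c_{th} = 0.5$, coupling
$D = 0.1$, and no-flux boundaries. The pacing pulse carries the feedback:

$$I(t) = \begin{cases}
I_0\,[1 + \alpha\,(\bar c_{n-1} - \bar c_s)] & nT < t < nT + \Delta T\\
0 & \text{otherwise,}
\end{cases}$$

where $\bar c_{n-1}$ is the previous beat's peak of the spatial average of
$c$, $\bar c_s$ a reference value, and $\alpha$ the (signed) feedback
strength. Defaults: $I_0 = 1.2$, $\Delta T = 0.5$. Random initial conditions
set $w(j,0) = 0.5 + \delta\,\xi(j)$, $\xi \sim U[-1,1]$; the reported
heterogeneity is $\sigma_{ini} = \delta/\sqrt{3}$, the standard deviation of
that distribution.

### Numerical choices

* **Integrator.** Classical fixed-step RK4 with $dt = 0.01$ model-time units
  (in compiled code). The pulse is discontinuous, so a fixed step with the
  pulse held constant over each step keeps the beat bookkeeping exact; the
  pulse edges fall on grid points for the default $\Delta T$. A
  $dt$-halving convergence test is part of the suite.
* **Pulse window.** The half-open window $[nT, nT + \Delta T)$ on the
  discrete grid, avoiding double-counted edge points.
* **Boundary stencil.** Conservative zero-flux form: the end sites receive
  $D\,(c_2 - c_1)$ and $D\,(c_{L-1} - c_L)$, so the diffusion term sums to
  zero on every call.
* **Peaks.** The per-beat peak is the maximum of the sampled trajectory
  within the beat window; no sub-step interpolation ($dt$ is small relative
  to the spike width).
* **First beat.** $\bar c_{n-1}$ is undefined at $n = 0$; the previous peak
  is initialised to $\bar c_s$ so the first pulse is exactly $I_0$ (the
  neutral, $\alpha$-independent start).
* **Initial activator.** $c(j,0) = 0$ (near the rest branch), configurable.
* **Divergence guard.** $|c| > 100$ aborts with an error naming the beat;
  FHN variables are $O(1)$.

### The feedback reference $\bar c_s$

$\bar c_s$ is *defined* as (roughly) the steady-state peak of $c$ at the
single-unit P1$\to$P2 bifurcation without feedback. The number this
definition produces depends on the integrator: with the RK4/$dt=0.01$ scheme
here, `single_unit_bifurcation_scan()` locates the bifurcation at
$T \approx 46.1$ with a peak of $\approx 0.816$. The commonly quoted value
0.77 comes from a different discretisation and remains the default of
`feedback_config()`; experiments that probe the positive-DGF regime near the
bifurcation (e.g. the global-P1 property at $\alpha = 0.4$, $T = 45.5$)
should pass the integrator-matched value, because the uniform-P1 feedback
residual $\alpha(\bar c_{peak} - \bar c_s)$ otherwise shifts the spatial
instability window by about one time unit in $T$. The acceptance suite
computes the matched value at run time rather than hard-coding either
number.

### What the generator emulates — and what a green test establishes

The random-IC protocol emulates beat-onset heterogeneity (e.g. a random
sarcoplasmic-reticulum load profile). It does **not** emulate intrinsic
channel noise: trials are deterministic given the seed, so histograms are
sharper than experimental ones. With $c(j,0)=0$, the single-unit
alternation-phase flip sits near $w_0 \approx 0.1$, so discordant patterns
without feedback require $\delta \gtrsim 1$; tests therefore assert the
*trend* of the discordant fraction with $\sigma_{ini}$ and the support
properties of the domain-size distribution, not literature percentages,
which depend on unstated initial-condition details. Paper-scale ensembles
(2000 trials × 2000 beats) are replaced by scaled ones (tens of trials ×
300–600 beats) after checking that pattern labels are stable from about
beat 100 onward.

## Model 2: the coupled map lattice (CML)

One map iteration corresponds to one beat; the state $c_n(j)$ is the beat-peak
signal. With the decreasing sigmoid $f(c) = 0.2 + 0.8/(1 + e^{(c-\gamma)/\mu})$:

$$c_n(j) = f[c_{n-1}(j)] + \sum_{m=-M}^{M} w_m\,\{f[c_{n-1}(j+m)] -
f[c_{n-1}(j)]\} - \alpha\,[f(\bar c_{n-1}) - f(\bar c_s)],$$

with Gaussian weights $w_m \propto e^{-m^2/2\sigma^2}$ and
$\bar c_s = c_s$ the fixed point $c_s = f(c_s)$. Defaults: $\mu = 0.1$,
$M = 15$, $\sigma = 3$. The feedback term is nonlinear (through $f$) to keep
iterates bounded; linearised about the uniform state it is proportional to
$\alpha(\bar c_{n-1} - c_s)$, so $\alpha > 0$ is positive feedback, as in the
FHN model.

Design choices where the formulation is open:

* **Boundary: periodic.** The eigenvalue formulas below use Fourier modes
  $k = 0..L-1$, which are exact eigenmodes only under periodic wrap.
* **Kernel normalisation:** $\sum_{m=-M}^{M} w_m = 1$, making the coupling a
  convex smoothing; the eigenvalue formulas consume the $w_m$ values
  directly, so the normalisation must be fixed and is fixed here.
* **Lattice size:** default $L = 128$, mirroring the FHN experiments.
* **Random ICs:** $c(j,0) = c_s + \delta\,\xi(j)$, the analogue of the FHN
  protocol.

## Linear stability theory

For the uncoupled unit, the scalar feedback map is
$c_n = (1-\alpha) f(c_{n-1}) + \alpha f(c_s)$ with eigenvalue
$\lambda = (1-\alpha) f'(c_s)$: negative feedback destabilises, positive
stabilises. The uniform P1 state of the lattice has

$$\lambda_k = \begin{cases}(1-\alpha) f' & k = 0\\
\big(1 - 4\textstyle\sum_{m=1}^{M} w_m \sin^2(\pi m k/L)\big) f' & k \ge 1,
\end{cases}$$

so the feedback acts only on the spatially uniform mode; the $k \ge 1$
stability boundary is a horizontal line in the $(\alpha, \gamma)$ plane. The
concordant P2 state (two-beat return map about the uniform two-cycle
$c_1, c_2$ of the scalar map) has
$\lambda_0 = (1-\alpha)^2 f_1' f_2'$ and
$\lambda_k = (1 - 4\sum_m w_m \sin^2(\pi m k/L))^2 f_1' f_2'$, which *does*
depend on $\alpha$ through the orbit.

Numerical choices: all scalar roots use bracketed bisection
(`stats::uniroot`, tolerance $10^{-10}$ or tighter) — every target function
is monotone within its bracket and derivative-free robustness matters near
the point where all boundaries meet. The two-cycle search scans
$F_\alpha(F_\alpha(c)) - c$ on a 2001-point grid over $(0.2, 1)$, brackets
sign changes and discards roots within $10^{-6}$ of $c_s$, guarding against
collapse onto the fixed point. The discordant-P2 stability boundary has no
closed form; `boundary_dis_p2_numeric()` bisects on $\alpha$ over a library
of seeded discordant fields (2-, 4-, 8-domain blocks plus random node
patterns), declaring the pattern stable if any seed survives to steady state.

Two subtleties found while validating against simulation, kept as documented
behaviour:

* For $\alpha \le 0$ the concordant-P2 spectrum never leaves the unit circle
  below the period-doubling point ($f_1'f_2' = 1/(1-\alpha)^2 \le 1$ at
  onset), so `boundary_con_p2()` returns `NA` there with a warning — this is
  exactly the regime in which only concordant patterns are observed.
* At $(\alpha, \gamma) = (0.3, 0.7)$ the concordant state is linearly
  *stable* ($\max_k |\lambda_k| \approx 0.50$) yet random initial conditions
  essentially never find its basin: the region is observationally
  "discordant only". Tests assert the observational statement; the spectrum
  is asserted separately against numeric Jacobians.
* At $(\alpha, \gamma) = (0.55, 0.7)$ the scalar map is P1-stable
  ($|(1-\alpha) f'| < 1$) while spatial modes of uniform P1 remain unstable;
  random ICs give discordant patterns whose *global* signal is period-1.
  This is the reading used for the third labelled phase-diagram location.

## Pattern pipeline

The alternation profile is
$\Delta c(j) = \frac{1}{m}\sum_{i=0}^{m-1} (-1)^i\,[c_{n-i}(j) -
c_{n-i-1}(j)]$ — the unique linear estimator that is exact on ideal period-2
fields for every averaging depth $m$ (deep $m$ is useful on noisy data;
$m = 1$ is the plain last-pair difference used for deterministic trials).
Classification: `uniform_P1` if $\max_j |\Delta c| <$ `eps_p1`; else
`Dis_P2` if the profile changes sign between sites above `eps_node`, else
`Con_P2`. Ensemble thresholds are relative — 1% of the ensemble-median
alternation amplitude, floored at $10^{-4}$ so an all-P1 ensemble is not
classified on numerical noise — which transfers between the FHN and CML
amplitude scales. Nodes take the integer index of the left member of the
sign-changing pair; sub-threshold sites attach to the preceding signed
segment (a leading run attaches to the following one); under periodic
boundaries same-signed terminal runs merge across the wrap. Domain sizes are
integer run lengths and always partition $L$.

## Experiment drivers

`sweep_phase_diagram()` labels each grid point from $n_{ic}$ trials: one
*near*-uniform initial condition (heterogeneity $10^{-6}$ — an exactly
uniform state would stay uniform forever by symmetry and mislabel every P2
point as concordant; the tiny perturbation probes stability instead) plus
$n_{ic}-1$ random ones. `histogram_experiment()` and
`dis_p2_fraction_curve()` implement the domain-size/amplitude histograms and
the discordant-fraction-vs-$\sigma_{ini}$ curve (exact binomial confidence
intervals, 100 trials per level at paper scale). Seeds are derived
deterministically from `base_seed`, grid index and trial index, so every
driver is bit-reproducible.

## Known limitations

* 1D only; homogeneous parameters; no stochastic (channel-noise) variants —
  the deterministic models cannot reproduce histogram smearing seen in
  physiological simulations.
* The FHN bifurcation location and the $\delta$ scale for discordant-pattern
  formation depend quantitatively on integrator and initial-condition details
  that the underlying formulation leaves open; conclusions asserted by the
  test suite are the structural ones (sign-of-feedback selection rules,
  global-P1 constraint, domain-size bounds, spectra).
* The discordant-P2 boundary protocol (seed library + bisection) is this
  package's concrete substitute for an unpublished numerical procedure.
* The global-P1 constraint on discordant patterns under positive feedback is
  *exact* in the CML (the strictly monotone map forces the alternating global
  values to coincide), but only approximate in the FHN lattice: discordant
  attractors with imbalanced domains retain a residual
  $\Delta\bar c_{peak} \approx 10^{-3}$ (about 0.2% of the site alternation
  amplitude) that is independent of the integration step and stable over
  thousands of beats. The acceptance test asserting the strict $10^{-3}$
  bound for every trial therefore fails on a minority of trials by a few
  percent; this is reported rather than hidden behind a loosened bound.
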