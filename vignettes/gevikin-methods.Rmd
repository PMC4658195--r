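---
title: "Modeling and analyzing voltage-indicator kinetics with gevikin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analyzing voltage-indicator kinetics with gevikin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The system and the model

ArcLight-type genetically encoded voltage indicators (GEVIs) couple the
voltage-sensing domain (VSD) of the *Ciona intestinalis* voltage-sensitive
phosphatase to a pH-sensitive GFP. Depolarization drives the charged S4
helix outward — measurable as a transient **gating current** — and, after a
delay, the fluorophore dims. `gevikin` models this chain of events as a
linear sequence of conformational states

    S1  <->  S2  <->  S3  <->  S4

in which the **first transition carries the gating charge** and the **last
transition carries the fluorescence change** (state S4 is dim); the middle
transition carries no observable. A three-state variant (gating transition
followed directly by the fluorescence transition) is retained as the
simpler alternative hypothesis. Transition rates follow a single-barrier
(Eyring-type) voltage dependence,

$$k_f(V) = k_{f0}\, e^{z \delta V / V_T}, \qquad
  k_b(V) = k_{b0}\, e^{-z (1-\delta) V / V_T},$$

with per-transition gating charge $z$ (elementary charges), barrier
symmetry $\delta$ (0.5 unless noted) and $V_T = RT/F \approx 25.17$ mV at
19 °C. The source literature constrains only the *structure* of the scheme
(strongly voltage-dependent first transition, weakly voltage-dependent
later ones); the rate law itself is our design choice — it is the standard
minimal form for voltage-sensor kinetics, and it degenerates to a
voltage-independent rate when $z = 0$, which is exactly how transitions 2
and 3 are parameterized by default.

Occupancies evolve as $\dot p = p\,Q(V(t))$. Because all command waveforms
are piecewise constant, `propagate_occupancy()` solves each segment exactly
by eigendecomposition of the generator — there is no ODE stepping error,
and row sums are preserved to $10^{-9}$ or better. `gillespie_sample()`
provides the matching exact stochastic simulation (per-molecule paths;
dwells are redrawn at segment boundaries, which is exact by memorylessness),
and `gillespie_occupancy()` a vectorized variant that records only ensemble
state counts, cheap enough for tens of thousands of molecules. The two
solvers cross-check each other in the test suite.

# Reference parameter sets

No rate constants are printed for ArcLight; what is printed is behaviour.
The committed reference scheme (`inst/extdata/reference_arclight.json`,
regenerated by `analysis/01_calibrate_reference.R`) is therefore defined by
the printed constants, each measured through the *full* simulation and
analysis pipeline (noise-free sweeps, baseline subtraction, charge
integration, Boltzmann fits, double-exponential kinetics):

* Q-V midpoint $V_{1/2} = -7$ mV;
* peak ON gating weighted time constant $\tau_w = 11$ ms (pinned at the
  $\tau$-V peak, since the comparison voltage is not stated);
* ON fluorescence fast time constant $\approx 2\times$ the gating $\tau_w$
  at that voltage;
* OFF fluorescence at least $10\times$ slower than OFF gating (evaluated at
  the -160 mV step of the +40 mV holding family — the most hyperpolarized
  step, where the OFF gating current is largest and both kinetics are
  cleanly measurable);
* steady-state $|\Delta F/F_0| \ge 30\%$ across a 100 mV span centred on
  the F-V midpoint.

`calibrate_reference()` performs the bounded least-squares calibration
(Levenberg-Marquardt on the residual vector) over the transition-1
parameters $(k_{1f0}, k_{1b0}, z_1)$, the inequality targets entering as
one-sided hinge residuals with a small inside margin so the optimum does
not park exactly on a bound. The post-gating transitions
and the dim-state brightness are configuration: they were chosen (once, see
below) so that the transition-1 calibration can satisfy the constraint set,
and they are documented config entries rather than fitted quantities.
Key configuration choices:

* **Transition 2** is fast (sub-two-millisecond forward time constant) with
  equilibrium poised forward. It sets the floor of the fluorescence lag at
  strong depolarization.
* **Transition 3** has a forward rate that makes the fluorescence fill
  about twice as slow as gating near the $\tau$-V peak, and a deliberately
  small backward rate: its equilibrium constant concentrates depolarized
  occupancy in the dim state (large $\Delta F/F_0$) and makes the OFF
  fluorescence recovery much slower than OFF charge return, as observed.
* **Brightness** is (1, 1, 1, 0.25): only the final state is dim. With the
  committed equilibrium constants this puts the steady-state span in the
  low-30s of percent per 100 mV, matching the "more than 30%" behaviour
  without overshooting it.
* **ArcLightning** is the ArcLight scheme with transition 1 scaled ×10
  forward and ×20 backward: the I126F mutation accelerates activation
  roughly forty-fold and deactivation roughly eighty-fold, and restoring
  R217 slows both roughly four-fold.
* **R217R / R217E** are implemented as +50 / -30 mV midpoint shifts of
  transition 1 — magnitudes are config values chosen to preserve the
  observed ordering of the three F-V curves, not calibration targets.
* **Three-state ArcLight** keeps transition 1 and gives the fluorescence
  transition the four-state scheme's final-transition rates.

A known limitation follows from the model structure: because all charge
must eventually equilibrate through the slow fluorescence transition, the
simulated Q-V measured from 200 ms pulses is slightly kinetically truncated
at mid voltages, and the measured gating $\tau_w$ at the $\tau$-V peak
includes a slow charge-drain component. The calibration operates on the
measured (pipeline) quantities, not the analytic steady state, precisely so
that these operator effects are absorbed into the committed parameters the
same way they are absorbed in an experiment. Two consequences are accepted
rather than hidden. First, with the four sharp constants enforced, the
fluorescence lag tracks the bare transition-1 relaxation while the measured
$\tau_w$ is drain-inflated, so the lag-V and gating $\tau_w$-V curves
correlate strongly but do not agree within a tight (25%) band at every
voltage. Second, at weakly activating steps the accelerated
(ArcLightning-like) scheme's measured deactivation $\tau_w$ is paced by
the drain rather than by its lightning-fast gating transition, so kinetic
fold changes between constructs are quantitative only at strongly
activating steps. Both behaviours are properties of the minimal chain, not
of the operators.

# Synthetic data

`simulate_macroscopic_recording()` emulates a cut-open oocyte voltage-clamp
fluorimetry rig. Study conditions follow the recording configuration of the
source experiments: ON families hold at -120 mV and step for 200 ms from
-140 to +120 mV in 20 mV increments; OFF families hold at +40 mV and step
to -160…+40 mV; default sampling 5 kHz (0.2 ms). The noise model and its
defaults (chosen once as representative of a low-noise cut-open clamp with
photodiode detection, and kept fixed thereafter):

* white current noise, SD 150 e₀/ms against full-sweep currents of order
  10⁴–10⁵ e₀/ms for the default 10⁶ molecules (high-SNR gating records);
* linear leak of 20 e₀/ms per mV (removed by the sloped-baseline operator);
* a residual capacitive transient at each voltage edge (amplitude 2000
  e₀/ms per 100 mV, τ 0.3 ms — an uncompensated remnant, much faster than
  gating);
* white fluorescence noise, SD 2 photodiode units against a baseline of
  ~1000 (0.2%, typical of integrating photodiode detection);
* optional bleach baseline (none by default; linear or single-exponential
  for the pulse-train analyses);
* an estimated-membrane-potential channel: the command filtered by a
  single-exponential clamp settling time (0.15 ms default).

The single-molecule generator mirrors TIRF recordings at 14 °C:
`blink_model()` superimposes a two-state bright/dark telegraph process on
the conformational brightness (default mean dwells of 40 ms bright / 20 ms
dark — "tens of milliseconds", config rather than target),
`camera_model()` converts photons to ADU with an EMCCD-like chain (Poisson
photons × EM gain as a scaled-Poisson approximation, Gaussian read noise,
offset; 500 Hz frames). Per-frame means integrate the stochastic paths
exactly over each frame. `render_movie()` places Gaussian PSFs on a smooth
background gradient. The absolute photon budget per molecule is not
derivable from the printed optical parameters, so the photon rate is a free
config parameter (default 100 photons/ms bright, a realistic
single-fluorophore TIRF flux).

What the generator deliberately does *not* emulate: relaxed-state (slow
inactivation-like) shifts of the Q-V under prolonged depolarization,
P/-P leak subtraction protocols, stage drift or vibration, and
photobleaching-step structure. Tests passing on these synthetic data show
the *operators* are correct under the stated noise structure; they cannot
certify behaviour under artifacts the generator omits.

# Analysis operators

All analysis follows the standard electrophysiology recipes, implemented
deterministically so fits are reproducible:

* `subtract_sloped_baseline()` — linear fit over a quiescent window
  (default: the final 20% of the pulse, where the gating current has
  decayed; the window is our choice, as no window is printed) removed from
  the whole trace.
* `integrate_charge()` — trapezoidal integral; Q-V assembly integrates the
  full pulse window after baseline subtraction (whether the rising phase is
  included in the original analysis is unstated; including it is the
  conservative choice since the integral is charge either way).
* `fit_boltzmann()` — $Q(V) = Q_{min} + (Q_{max}-Q_{min})/(1 +
  e^{-z(V-V_{1/2})/V_T})$ by Levenberg-Marquardt with deterministic
  extrema/mid-crossing starting values; the curve is rescaled so the fitted
  limits map to 0 and 1.
* F-V normalization reuses the same cell's Q-V scaling factors: the Q-V fit
  fixes the Boltzmann *shape* $(V_{1/2}, z)$, the F-V limits are obtained
  by linear regression of the fluorescence amplitudes on that fixed shape,
  and the curve is mapped to those limits. With voltage-independent
  post-gating transitions, normalized F-V then superimposes exactly on
  normalized Q-V. Non-saturating families from depolarized holding are
  instead divided by the same cell's total saturating charge
  (`normalize_qv_nonsaturating()`), exploiting charge conservation.
* `fit_exp_decay()` — one- or two-exponential fits by variable projection
  (amplitudes linear, time constants by deterministic multi-start
  Nelder-Mead; ties broken by residual RMS); $\tau_w = \sum|A_i|\tau_i /
  \sum|A_i|$; components ordered fast-first. The gating decay window starts
  one sample after the |current| peak, avoiding clamp-settling
  contamination.
* `fit_fluor_kinetics()` — double-exponential fit with the refit rule: the
  second component is dropped (and the trace refit with one exponential)
  when its amplitude fraction is below 5% or the time constants are within
  a factor 1.5 — the source describes this rule only qualitatively ("one
  meaningful time constant"), so the numeric thresholds are ours. Reported
  kinetics are $\tau_1$, the faster-and-larger-amplitude component.
* `extract_lag()` — a single exponential is fitted from the departure point
  of the response (first crossing of 5% of the final amplitude) and
  extrapolated back; the lag is where the fit crosses the abscissa, minus
  the voltage onset. Single-exponential crossings are used because that is
  what the worked examples show; slightly negative lags are reported as-is.
  The ON kinetics window then starts at the extracted crossing, separating
  lag from time constant.
* `lowpass_filter()` — zero-phase Gaussian FIR (cutoffs quoted at -3 dB):
  zero phase means filtering cannot bias lag estimates, and the kernel's
  positivity means no overshoot on steps.
* Single-molecule: per-frame grayscale opening (disc radius > PSF σ) for
  background correction; detection by local maxima above median + k·MAD
  pruned brightest-first to a minimum separation (the detection algorithm
  is unspecified in the source; this is the standard recipe); aperture
  photometry with aperture 2σ and a 4–6σ annulus; autocorrelation
  $r(k)$ with the white-noise 95% band $\pm 1.96/\sqrt n$.
* `fluctuation_test()` formalizes the implicit decision rule "no
  significant autocorrelation at any non-zero lag": the count of
  band-exceeding lags among the first L = 20 is referred to a Binomial(L,
  0.05) upper tail, with verdict "fluctuating" at p < 0.01. This
  formalization is this package's own, explicit and testable stand-in for a
  rule the source applies by eye; its type-I error and power are measured
  in the test suite.

Curves are only reported where they measure signal: gating kinetics at
steps carrying ≥ 5% of the maximal charge, fluorescence kinetics and lag at
steps reaching ≥ 5% of the maximal response. Missing steps remain gaps —
no interpolation.

# Scheme inference and model discrimination

`fit_scheme_parameters()` mirrors the experimental reasoning order rather
than performing one joint fit: transition 1 is fitted to the Q-V and gating
τ-V curves of both families (the OFF family pins the backward gating
rate); the post-gating transitions to the lag-V, fluorescence τ-V and
amplitude curves plus the OFF fluorescence recovery; the two stages are
alternated once (the gating decay feels the post-gating drain), and a
joint refinement of all parameters follows. Every optimizer is
Levenberg-Marquardt on the scaled residual vector — the curved valleys of
this system defeat direct-search methods. Two deliberate multi-starts
guard against known biases of the data-driven initial guess: stage 1 fans
the gating charge downward (the apparent Boltzmann slope of a kinetically
truncated Q-V overestimates $z_1$), and the joint stage fans the
transition-1 speed upward (the drain-inflated τ-V peak biases the rate
guess slow), stopping early once the residuals are statistically clean.
Model predictions are measured by the *same* operators that produced the
data curves, on noise-free simulations, so noiseless curve sets are
reproduced exactly at the generating parameters; $\delta$ is fixed at 0.5
during fitting (z and δ are not separately identifiable from these
protocols) and the per-state brightness is treated as known configuration
(it is a property of the fluorophore, not of the kinetics). Parameters
whose 1.5-fold perturbation barely changes the objective are flagged as
unidentified rather than silently reported.

The discrimination logic of `predict_lag_under_acceleration()`: scaling the
gating transition forty-fold leaves the four-state lag bounded below by the
transition-2 transit time (lag *saturates*), while the three-state lag —
which is pure gating delay — shrinks roughly in proportion. The verdict
threshold sits at five times the proportional prediction, a decade below
the saturating regime. The "correlates quite well" agreement between lag-V
and gating τ-V has no printed metric; where this package quantifies it, it
uses a 25% band as its own calibration property.

# Numerical choices and problem sizes

Exponential fits thin traces to ≤ 400 points (the relaxations are smooth,
so uniform thinning is unbiased) and run Nelder-Mead to a 10⁻¹⁰ relative
tolerance from two deterministic starts. Degenerate inputs fail loudly:
baselines need ≥ 10 samples and time spread, Boltzmann fits need ≥ 5
voltages, autocorrelation warns below 10× the maximum lag, empty detection
results are valid. All randomness flows from explicit integer seeds;
identical seeds give bit-identical recordings, traces and movies.

Problem sizes in the shipped tests and analysis scripts were chosen to
exercise every property at meaningful statistical power on a single CPU:
Gillespie-vs-deterministic at 20 000 molecules, fluctuation-test error
rates over 200 seeds, and parameter recovery over 10 replicate cells, each
a 4-sweep signal average (averaging repeated sweeps is standard practice
for gating-current recordings) on a five-voltage ON family plus a
two-voltage OFF family at 2 kHz sampling. Charge-conservation checks use
50 kHz sampling because the deactivation spike at strongly hyperpolarized
potentials decays in a fraction of a millisecond and the check is a
trapezoidal quadrature. The analysis scripts under `analysis/` re-run the
same machinery at full protocol resolution. The pulse-train script shows
the simulated 19 °C behaviour: at this temperature neither scheme fully
recovers between 67 Hz stimuli (the published recovery contrast was
recorded at 35 °C, and temperature scaling of rates is out of scope), but
the accelerated scheme accumulates visibly less baseline.
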