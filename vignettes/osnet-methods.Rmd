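---
title: "Methods: simulating and solving orientation selectivity in random inhibition-dominated networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and solving orientation selectivity in random inhibition-dominated networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(osnet)
```

This vignette is the package's own account of its science: the model,
the rate theory, the numerical choices, what the shipped presets emulate
and what they do not, and the known limitations.

## 1. The scientific question

In rodent primary visual cortex, neighbouring neurons prefer unrelated
stimulus orientations ("salt-and-pepper" organisation), yet individual
neurons are sharply tuned and their tuning width barely changes with
stimulus contrast. `osnet` implements the minimal circuit model in which
these properties emerge without any feature-specific wiring: a random
recurrent network of integrate-and-fire neurons whose only
orientation-specific ingredient is a weak cosine modulation of the
feedforward input, with a preferred angle assigned to each neuron
independently and uniformly at random.

The mechanism under study is linear common-mode suppression plus
rectification. With fixed in-degrees `k_exc`, `k_inh` and Dale-compliant
weights `J` and `-gJ`, every row of the weight matrix sums to
`w = J (k_exc - g k_inh)`. When `g k_inh > k_exc` (inhibition
dominance), the untuned part of the drive is attenuated by
`dV / (dV + |w|)` (with `dV = V_th - V_reset`) while the spatially
random orientation-tuned modulation is passed with gain `~ 1/dV`; both
the suppressed baseline and the modulation scale linearly with
contrast, which is the root of contrast invariance. Rectification of
negative rates — silent neurons dropping out of the recurrent field —
adds sharpening of tuning curves and extra suppression of the
modulation, and is treated self-consistently by the nonlinear solvers.

## 2. Neuron and network model

* **Subthreshold dynamics.** LIF:
  `tau_m dV/dt = -(V - V_rest) + tau_m I(t)`; PIF: the leak-free limit
  (implemented by disabling the decay factor, equivalent to
  `tau_m -> Inf` for the drift while `tau_m` retains its role as the
  unit conversion between input rate and potential). Synapses are
  delta pulses: each presynaptic spike deposits its full PSP amplitude
  instantaneously.
* **Spiking.** Threshold test `V >= V_th` at the end of each step (no
  within-step crossing interpolation — consistent with jump-like PSPs);
  reset to `V_reset = V_rest`; absolute refractory period `tau_ref`
  during which the potential is clamped and all synaptic input is
  shunted (discarded). The discarded charge is *accounted* per neuron
  (`shunt_rate`), which makes the free-membrane-potential
  reconstruction exact (section 7).
* **Exact integration.** Between events the linear dynamics are
  propagated in closed form, `V <- V_rest + (V - V_rest) exp(-dt/tau_m)`
  with the decay factor computed once; the trajectory of a silenced
  neuron therefore matches the analytic exponential to accumulated
  floating-point rounding only (about `1e-13` mV over 1000 steps, the
  scale at which the test suite pins it).
* **Topology.** Fixed in-degree per target, sources drawn uniformly
  without replacement, self-contacts and multiple contacts excluded —
  the simplest scheme consistent with random sampling from the local
  network. Note that a population of size `n` can supply at most
  `n - 1` distinct sources to one of its own members; configurations
  violating this raise an error naming the offending population.
* **Delays.** Per-synapse transmission delays, either drawn uniformly
  from `[0.5, 3]` ms (desynchronising; the asynchronous-irregular
  preset) or all identical at 1.5 ms (the synchronous preset), rounded
  to integer multiples of the step and delivered through a ring buffer.
  Delays that round below one step are rejected.

External input is a superposition of two Poisson processes per neuron —
an untuned background (total rate `s_bkg`, efficacy `j_bkg`) and the
tuned feedforward drive `s_i = s_max C (1 + m cos 2(theta - po_i))`
(efficacy `j_ffw`) — realised as per-step Poisson event counts. The
convergent thalamic population is collapsed into this single process,
and the contrast-to-baseline map is linear, `s_b = s_max C`, with
default contrasts `{1/3, 2/3, 1}` spanning a three-fold range.

## 3. The rate theory

Averaging the PIF dynamics under stationarity gives
`dV r = W r + h`, `h_i = j_ffw s_i + j_bkg s_bkg` (mV/s).

* **Linear layer** (`linear_rates`): direct sparse solve of
  `(dV I - W) r = h`. Negative components are reported as such — this
  layer does not rectify. A power-iteration estimate of the spectral
  radius of `W/dV` guards against unstable configurations.
* **Rectified layer** (`rectified_fixed_point`): damped Picard
  iteration for `r = [(W r + h)/dV]+`. After convergence the active set
  is *polished* by one exact solve restricted to its support, giving
  residuals at machine precision and exact support identification; an
  exhaustive enumeration over all `2^N` supports on small random
  systems serves as the oracle in the tests (uniqueness is guaranteed
  there by keeping `dV I - W` strictly diagonally dominant).
* **Siegert layer** (`lif_fixed_point`): replaces the threshold-linear
  transfer by the LIF first-passage rate of the input moments
  `mu_i = V_rest + tau_m (W r + h)_i` and
  `sigma_i^2 = (tau_m/2) (W^2 r + h2)_i` (entrywise-squared weights;
  rates per ms). The `tau_m/2` prefactor makes `sigma` the *stationary
  standard deviation* of the free potential, which is validated against
  a Monte-Carlo variance oracle; consequently the first-passage
  integral is written in the OU diffusion scale `sqrt(2) sigma`:

  `1/r = tau_ref + tau_m sqrt(pi) * Int_{y(V_reset)}^{y(V_th)} e^{u^2}(1 + erf u) du`,
  `y(V) = (V - mu) / (sqrt(2) sigma)`.

  The two conventions (variance prefactor and integral scale) must be
  paired consistently; pairing the `tau_m/2` prefactor with limits
  `(V - mu)/sigma` underestimates rates by a factor of 2–3 in the
  fluctuation-driven regime, an error the single-neuron Monte-Carlo
  oracle catches immediately.
* **Refractory correction.** The PIF layers solve the
  refractoriness-free equations and apply `r' = r/(1 + r tau_ref)`
  afterwards (the correction for shunted refractoriness); the Siegert
  formula carries `tau_ref` natively as a dead time.

### Numerical choices

* **Siegert quadrature.** The integrand equals `erfcx(-u)`, evaluated
  overflow-free; for `u > 0` the identity
  `erfcx(-u) = 2 e^{u^2} - erfcx(u)` splits off an exactly integrable
  part (`erfi`). The remaining smooth integrand is handled by
  fixed-order Gauss–Legendre panels, with the slowly decaying
  `~1/(u sqrt(pi))` tail integrated in log space so accuracy is uniform
  over arbitrarily wide limits (tiny `sigma`). `erfcx` switches to its
  asymptotic expansion beyond `x = 25`, where the library
  implementation overflows. Agreement with adaptive quadrature is at
  machine precision; rates below `~1e-40` spikes/s (upper limit beyond
  10 diffusion scales) are returned as 0.
* **Damping.** Picard damping defaults to `alpha = 0.5`, but the
  iteration matrix eigenvalue of the common mode is `1 - alpha(1 + |w|/dV)`;
  for the inhibition-dominated presets (`|w|/dV = 4`) stability
  requires `alpha < 0.4`, so those presets ship `alpha = 0.25`. The
  residual (RMS of successive iterates, tolerance `1e-6` spikes/s,
  cap 10 000 iterations) is recorded per iteration; non-convergence
  raises an error carrying the trace.
* **Lookup table.** For sweeps, the Siegert evaluation optionally runs
  through a precomputed `(mu, sigma)` grid (240 x 120; linear in `mu`,
  log-spaced in `sigma`) with bilinear interpolation. In `"auto"` mode
  the solver observes the moment ranges during a short direct warm-up,
  pads them, builds the table once and reuses it across conditions;
  out-of-grid points fall back to direct evaluation.

## 4. Tuning statistics

OSI and PO are the length and half-angle of the circular resultant of
the tuning curve at doubled angles. F0 is the curve mean and F2 the
second-harmonic amplitude in the convention that recovers
`r = F0 + F2 cos 2(theta - phi)` exactly, so `OSI = F2/(2 F0)` is an
identity for positive curves (tested to `1e-12`). The von Mises fit
uses the 3-parameter family `A exp(kappa cos 2(theta - phi))` without
additive offset — the tuning-width statistic keys on `kappa` alone, and
the offset-free family keeps it identifiable on 12-point grids.
Levenberg–Marquardt fits are multi-started around the resultant PO; the
error index is the RMS residual as a percentage of the curve mean, and
fits above a configurable threshold (default 5%) are flagged and
excluded from fit-derived statistics. Strongly rectified curves
genuinely depart from the von Mises family, so analyses that want the
width of *every* curve should pass `max_error_index = Inf` and treat
the flag as a quality annotation.

Tuning width is the half width at half height between the fitted
curve's minimum and maximum, `TW = acos(ln(cosh kappa)/kappa)/2`,
which tends to 45° as `kappa -> 0` — the unrectified-cosine reference
that makes the sharpening coefficient `SC = TW_out / TW_in` equal 1 for
a linear network. `dPO` maps the 180°-periodic difference to
`[-90, 90)` with the ambiguous ±90° case assigned to −90. Curve-shape
comparisons across contrasts use `aligned_population_curve`, which
subtracts each neuron's spontaneous rate (clipped at zero), aligns on
the input PO and averages; subtracting the spontaneous (background-
driven, contrast-independent) component before normalising is the
standard procedure, and without it the contrast-independent background
floor masquerades as a contrast-dependent shape change.

## 5. The presets: what they emulate

The four presets realise the studied regimes at a reduced "desk" scale
(N = 1250, i.e. 1000 excitatory + 250 inhibitory neurons) chosen so a
full 3-contrast × 12-orientation sweep with 5 s per condition runs in a
few minutes on one CPU. The full-scale reference conditions
(N = 12 500, 80/20 split, 10% connectivity, J = 0.2 mV) remain
available through the config system; `generate_fixture` scales any
config down (populations with `scale`, in-degrees with `sqrt(scale)` to
roughly preserve input statistics, duration with `sqrt(scale)`).

* `pif_linear` — PIF, in-degrees 40/10, `J = 0.2`, `g = 4`: exactly
  balanced (`g k_inh = k_exc`), so the linear solution is positive and
  rectification never engages. Stimulus `m = 0.5`, `s_max = 5000`,
  `s_bkg = 400` puts rates near 27 spikes/s with a modulation spread
  that dominates the Poisson counting error of a 5 s estimate — at this
  reduced scale a very weak modulation would disappear into counting
  noise, which is why the desk-scale stimulus is more strongly
  modulated than a full-scale experiment would choose.
* `pif_rectified` — PIF, in-degrees 320/80, `J = 0.25`, `g = 8`:
  row sum `w = -80` mV, five-fold common-mode suppression; roughly a
  third of linear rates are negative at each orientation, so the
  rectified solver is required and sharpening (`SC < 1`) is strong.
* `lif` — the same network with leaky neurons (`tau_m = 20` ms,
  threshold 20 mV). Stimulus `s_max = 24 000`, `s_bkg = 10 000`,
  `m = 0.4` was calibrated (once, via the fixed point) to the regime
  conditions of the study: spontaneous activity of a few spikes/s,
  evoked mean rates ~14/23/31 spikes/s at the three contrasts, and
  fluctuation-driven flanks with mean-driven peaks (`sigma` ~ 5–8 mV).
* `lif_synchronous` — identical weights, all recurrent delays fixed at
  1.5 ms: the network enters a more synchronous dynamical state while
  the same Siegert fixed point continues to predict its rates — the
  state-robustness check.

Simulation defaults: `dt = 0.1` ms, 5 s per condition, initial
potentials uniform on `[V_reset, V_th)` to suppress startup synchrony,
first 200 ms excluded from all stationary estimates, per-condition
seeds derived deterministically from one master seed.

## 6. What the synthetic conditions do and do not show

All inputs are generated internally; there is no recorded data. The
presets emulate the *mechanism* — common-mode suppression,
amplification of modulation, rectification-induced sharpening, contrast
invariance, state robustness — under idealised assumptions: Poisson
externals, delta synapses, homogeneous parameters, uniform random POs,
and connection probabilities (up to 0.32 in the inhibition-dominated
presets) well above cortical estimates because the in-degrees shrink
more slowly than the population when scaling down. Passing tests
therefore demonstrate internal consistency of simulator, theory and
statistics in this model class, not quantitative agreement with
biological cortex: conductance synapses, synaptic filtering,
distance-dependent or like-to-like connectivity, and correlated
thalamic input are all outside the model (and the package's scope).

Known quantitative caveats at desk scale:

* Shared-input correlations (high connection probability) produce a
  small bias between the mean-field prediction and simulation —
  visible, for example, as a ~0.2 mV residual in the
  free-membrane-potential comparison after the reset and shunt
  corrections.
* The clock-driven threshold test underestimates fluctuation-driven
  rates by a discretisation term that grows with `sigma sqrt(dt)`; the
  single-neuron Monte-Carlo checks therefore run at `dt = 0.02` ms
  with 0.05 mV PSPs, where the bias is far below the Monte-Carlo
  standard error. Network presets keep `dt = 0.1` ms, adequate because
  their comparisons are correlation-based.
* A PIF neuron with near-zero net drift shows slowly decaying
  fluctuation-driven firing that the rectified theory assigns rate 0;
  over a 4.8 s window this smears the rectification foot by ~1 spike/s.

## 7. Free-membrane-potential reconstruction

The time-averaged potential of a spiking neuron underestimates the
potential its input would produce in a free (non-spiking) membrane,
because every spike removes `dV` and relaxes back, and because input
arriving during the refractory period is shunted. Balancing the reset
flux over non-refractory time gives the correction implemented in
`free_membrane_potential`:

`v_free = V_rest + (1 - x)(v_meas - V_rest) + tau_m (dV r + L)`

with `x = r tau_ref` the refractory time fraction and `L` the measured
shunted-charge rate. The simulator reports both the non-refractory mean
potential and `L`; the reconstruction from the net input
(`reconstruct_free_potential`, the `mu` of the input moments, using
*simulated* presynaptic rates) then agrees to a fraction of a
millivolt. Omitting `L` is accurate only at low rates — in the
inhibition-dominated network the input arriving during refractoriness
is systematically inhibitory (the same population event that made the
neuron fire recruits delayed inhibition), so the shunted charge is not
mean-zero.

## 8. Design decisions on genuinely open points

* Sources are drawn independently per target (no degree correlations);
  weights take exactly two values `{J, -gJ}`.
* The iteration starts from the zero rate vector, so degenerate (zero
  drive) inputs converge trivially; persistent cycling across the
  rectification boundary is surfaced as a non-convergence error rather
  than silently accepted.
* The von Mises family carries no additive offset (section 4); the
  fit-exclusion threshold defaults to 5% error index.
* The refractory correction of the PIF layers is applied after
  convergence, not inside the iteration; at preset rates the
  difference is second order (a few percent of the recurrent term).
* The sharpening analysis evaluates the theory layers' tuning curves
  (the rectified fixed point is itself validated against simulation);
  this keeps the statistic free of counting noise.
* Desk-scale problem sizes used by the tests and the acceptance script:
  N = 1250 networks, 5 s per condition, 100 s single-neuron
  Monte-Carlo runs, 100-replicate fit-recovery studies, and 100 random
  systems (N ≤ 10) for the exhaustive rectification oracle.

## 9. Limitations

Event-driven simulation, conductance synapses, synaptic kernels,
plasticity, distance- or feature-dependent connectivity, direction
selectivity (360°-periodic statistics), and pairwise-correlation
analyses are out of scope. The spectral-radius guard is a power-method
estimate, not a certified bound. The lookup-table fixed point is
accurate to the bilinear interpolation error of its grid (~0.05
spikes/s at the default resolution); pass `lookup = NULL` for direct
evaluation when that matters.
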