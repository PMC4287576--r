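# osnet — orientation selectivity in inhibition-dominated spiking networks

How can neurons in rodent visual cortex be sharply tuned to stimulus
orientation when their neighbours prefer entirely different orientations
and the local wiring is random?  `osnet` is a toolkit for studying this
question in recurrent networks of integrate-and-fire neurons *without*
feature-specific connectivity: weakly orientation-tuned feedforward
input, a random Dale-compliant recurrent network dominated by
inhibition, and nothing else.  The package provides

* a clock-driven spiking simulator (C++ core) for networks of **perfect
  (PIF)** and **leaky (LIF) integrate-and-fire neurons** with delta
  synapses, exact subthreshold integration, per-synapse transmission
  delays, an absolute refractory period, and orientation-tuned Poisson
  drive;
* an **analytical firing-rate theory** that predicts every neuron's
  stationary rate from the weight matrix and the drive — a linear
  solution, a rectified (threshold-linear) fixed point, and a fixed
  point of the Siegert first-passage transfer function for LIF neurons;
* a **tuning-statistics toolkit**: orientation selectivity index (OSI)
  and preferred orientation (PO) from circular statistics, von Mises
  fits and tuning width (TW), F0/F2 components, sharpening coefficient,
  CV of inter-spike intervals, population PSTHs, and
  free-membrane-potential reconstruction;
* **experiment orchestration**: validated configs (YAML/JSON), four
  presets (`pif_linear`, `pif_rectified`, `lif`, `lif_synchronous`),
  deterministic orientation-by-contrast sweeps, and result bundles
  (gdf spike text, CSV rate tables, JSON manifest), plus a thin CLI at
  `inst/cli/osnet.R`.

## The model

Each neuron integrates `tau_m dV/dt = -(V - V_rest) + tau_m I(t)` (PIF:
no leak) with pulse PSPs of amplitude `J` (excitatory) and `-gJ`
(inhibitory); at `V_th` a spike is emitted and `V` resets for a
refractory period `tau_ref`.  Neuron *i* receives feedforward Poisson
input of intensity

```
s_i(theta, C) = s_max * C * (1 + m * cos 2(theta - po_i))
```

plus an untuned background.  Averaging over time, stationarity ties the
rate vector to the drive through the weight matrix `W`:

```
(V_th - V_reset) r  =  W r + h          (linear layer)
r = [ (W r + h) / (V_th - V_reset) ]+   (rectified fixed point)
r_i = F_siegert(mu_i(r), sigma_i(r))    (LIF fixed point)
```

Because the fixed in-degree recurrence is inhibition-dominated, the
untuned common mode of the input is strongly suppressed while the
orientation-tuned modulation passes through — producing selective,
contrast-invariant tuning out of weakly tuned input.  Rectification of
negative rates adds sharpening and extra modulation suppression, which
the rectified and Siegert layers capture exactly.

## Worked example

An inhibition-dominated PIF network (1250 neurons, in-degrees 320/80,
IPSPs eight times the 0.25 mV EPSPs), simulated for 5 s at one stimulus
orientation and solved analytically across the full orientation grid:

```r
library(osnet)

cfg    <- preset_config("pif_rectified")
stim   <- do.call(stimulus_config, cfg$stimulus)
neuron <- do.call(neuron_params, cfg$neuron)
net    <- build_network(1000, 250, 320, 80, j_epsp = 0.25, g = 8)

drive  <- build_drive(net$po, theta = 0, C = 1, stim = stim)
spikes <- simulate_network(net, drive, neuron, duration = 5000, seed = 42)
theory <- rectified_fixed_point(net, drive, neuron, damping = 0.25)

curves <- vapply(theta_grid(stim), function(th)
  rectified_fixed_point(net, build_drive(net$po, th, 1, stim), neuron,
                        damping = 0.25)$rates, numeric(net$n))
stats <- tuning_stats(curves, theta_grid(stim), po_in = net$po,
                      tw_in = input_tuning_width(stim, 1),
                      max_error_index = Inf)
```

Output:

```
mean rate: sim 14.7 / theory 13.9 spikes/s; r = 0.995; silent 40%
median OSI 0.68 | median TW 28.0 deg (input 39.4 deg) | median SC 0.71
median |dPO| 8.6 deg
```

Reading: the rectified theory predicts the simulated per-neuron rates
almost perfectly (Pearson r = 0.995) even though 40% of the population
is driven below threshold at this orientation.  The input modulation
ratio is only 0.4 (input tuning width 39.4°), yet output tuning is sharp
(median OSI 0.68) and narrowed (median TW 28.0°, sharpening coefficient
0.71 < 1), with output preferred orientations inherited from the input
(median |dPO| ≈ 9°, i.e. about half a 15° grid step).

A full orientation-by-contrast sweep with bundle output:

```r
bundle <- run_orientation_sweep(preset_config("lif"), outdir = "out")
compare_sim_theory(bundle, "lif")
```

or from the shell:

```sh
Rscript inst/cli/osnet.R run --preset lif --outdir out --seed 1
Rscript inst/cli/osnet.R compare --bundle out --theory lif
```

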