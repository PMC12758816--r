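---
title: "Modelling seizure dynamics and low-frequency stimulation with epistim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seizure dynamics and low-frequency stimulation with epistim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epistim)
```

## The model

`epistim` simulates a four-variable neural mass model of seizure-like
events in hippocampal tissue perfused with high-potassium solution, a
modified form of the Epileptor-2 family of ion-concentration models. The
state comprises the population-average membrane potential of pyramidal
cells $V$ (mV), a synaptic depression resource $x_D \in [0,1]$, the
extracellular potassium concentration $[K^+]_o$ (mM) and the
intracellular sodium concentration $[Na^+]_i$ (mM):

$$
\begin{aligned}
\tau_m \dot V &= u(V, x_D, K_o) - V + R_{stim} I_{stim}(t), \\
\dot x_D &= \frac{1 - x_D}{\tau_x} - \delta_x\, x_D\, \nu(V), \\
\dot K_o &= \frac{K_{bath} - K_o}{\tau_K} - 2\gamma I_{pump} + \delta_K\, \nu(V), \\
\dot{Na}_i &= \frac{Na_{i0} - Na_i}{\tau_{Na}} - 3 I_{pump} + \delta_{Na}\, \nu(V),
\end{aligned}
$$

with a sigmoid population rate $\nu(V) = \nu_{max} / (1 + e^{V_{th} - V})$,
a saturating Na-K pump flux
$I_{pump} = \rho \, [ (1 + e^{3.5 - K_o}) (1 + e^{(25 - Na_i)/3}) ]^{-1}$,
and a membrane drive combining a Nernst-type potassium depolarization,
current-based excitation and conductance-based shunting inhibition,

$$
u = \hat g_K\, 26.6\,\mathrm{mV} \cdot \ln\!\frac{K_o}{K_{o0}}
  + \hat g_{exc}\, \nu(V)\, x_D + \hat g_{inh} (V_{inh} - V).
$$

All conductances are expressed relative to the leak conductance, so the
drive is in millivolts. Two unit conventions deserve a note, because the
model is usually stated with them left implicit:

* the sigmoid exponents are dimensionless with implicit per-mV and
  per-mM scalings of one, and $\hat g_{exc}$ carries units of mV·s so
  that rate times resource yields millivolts — this makes the shipped
  parameter tables usable verbatim;
* the 26.6 mV prefactor is $RT/F$ at 34 °C, which is the Nernst
  prefactor for the *natural* logarithm, so the log term uses `log()`.

The fast-subsystem reduction freezes the two ion concentrations and
studies the $(V, x_D)$ dynamics alone; one published form of the frozen
membrane equation carries a leak factor on the $-V$ term that is
inconsistent with the full system at the frozen-ion limit, and the
package resolves this in favour of $u - V$ (all conductances being
relative to leak).

The mechanism the package exists to explore: potassium diffusing from
the bath slowly charges the tissue; when $K_o$ exceeds a fold of the
fast subsystem the population jumps to a depolarized, rapidly firing
state (the seizure); firing loads the cell with sodium until the Na-K
pump activates, pulls potassium back down, and terminates the event.
Low-frequency stimulation delivered between seizures drives brief firing
bursts that keep the pump engaged, locking the system onto a small
stimulation-paced cycle that blocks the interictal potassium build-up —
and thereby defers the next seizure.

## Parameters and presets

`epi_params()` carries the full parameter set with reference defaults;
`slice_preset("slice0")` … `"slice4"` provide the shipped presets. They
differ only in bath potassium `K_bath` (5.3–9.5 mM), firing threshold
`V_th` (2.4–14 mV), maximum rate `nu_max` (35–80 Hz) and inhibitory
coupling `g_inh_rel` (0.05 / 0.1686): the axes along which individual
slices differ in excitability. The shared constants (time constants,
increments per spike, pump capacity $\rho = 0.1142$ mM/s, volume ratio
$\gamma = 10$) are documented field by field in `?epi_params`.

Parameters that matter most in practice:

* **`K_bath`** (mM) — the slow drive. Below a threshold the model is
  silent; in an intermediate band it produces recurrent seizures whose
  ISI shortens as `K_bath` rises; at high values it locks into a
  persistently depolarized state (the model analogue of status
  epilepticus). `run_kbath_step_protocol()` exposes this regime ladder.
* **`V_th`, `nu_max`** (mV, Hz) — population excitability; these set the
  ISI/duration balance and were the fitting knobs for the slice presets.
* **`R_stim`** (mV/mA) — each stimulation pulse, idealized as an
  impulse, displaces $V$ by `R_stim * amplitude` instantaneously. The
  200 µs experimental pulse is far shorter than every model timescale,
  which justifies the impulse idealization. With `R_stim = 1`, a 15 mA
  pulse produces a 15 mV jump, commensurate with the firing thresholds;
  the alternative reading that divides by $\tau_m$ would produce
  kilovolt-scale jumps and is rejected on physical grounds.

## Numerical scheme

The integrator (`simulate_epileptor()`) is a fixed-step classical
Runge-Kutta (RK4) scheme written in C++, with pulses applied as exact
state jumps at grid-snapped pulse times. Defaults: `dt = 1e-4` s
($\tau_m/20$); a guard rejects `dt` above $\tau_m/10$. Trajectories are
recorded at 1 kHz by default. The scheme is deterministic — identical
inputs give bit-identical output — and step-halving changes a 50 s
solution by less than $10^{-6}$ relative (asserted in the test suite).
State validity ($K_o, Na_i > 0$, finite $V$) is checked every step and
violations abort with a diagnostic.

For slow-passage analysis the two ion equations can be scaled by a
factor `epsilon`; at `epsilon = 0.003` the trajectory hugs the
fast-subsystem equilibrium surface and its jump points land within a few
thousandths of a mM of the computed fold and Hopf potassium values
(`overlay_slow_trajectory()`; one full cycle then spans roughly 25 000
model seconds, which is why that check uses `dt = 2e-4` and a long
horizon).

## Seizure detection

Detection mirrors the analysis applied to the recordings: the signal
(model $V$ as the LFP proxy — the match to data is in temporal
structure, not amplitude) is smoothed with a centered 1 s moving
average; seizure *offsets* are local minima with topographic prominence
of at least half the signal span of the analyzed segment, thinned to a
minimum separation of 20 s in order of decreasing prominence (ties to
the earlier trough); each *onset* is the changepoint of a two-piece
linear least-squares fit in a window of up to 30 s before the offset
(clipped at the previous offset). The ISI is offset-to-next-onset.
Design choices that the procedure leaves open and the package fixes:

* prominence is computed topographically on the inverted signal, and
  the span is that of the analyzed segment, so detection is invariant
  under adding constants and positive rescaling (asserted as a
  property test);
* a changepoint whose two-piece fit improves on a single line by less
  than 1% is flagged low-confidence;
* detected events shorter than 2 s are discarded as artifacts —
  seizure-like events last tens of seconds, and near-flat segments
  otherwise produce spurious span-relative troughs.

## Stimulation experiments

`steady_state_cycle()` burns the model in, discards everything before
the second detected offset, and stores the exact state at that offset;
the control ISI is then measured by replaying the cycle *through the
same trial pipeline* with amplitude zero, which makes the
zero-amplitude trial reproduce a relative delay of exactly 0%.
`run_lfes_trial()` restarts from that state with a pulse train and
measures the stimulated ISI; a seizure fired by the train ends the ISI
even while stimulation continues. Labels: `immediate-seizure` when the
first onset falls within two pulse periods of the train start,
`delayed`/`shortened` beyond a ±1% delay, `no-effect` otherwise.

The critical (capture) amplitude grows with `V_th`: about 13.5 mA for
the reference preset and 15.5–18 mA for the fitted slices, because a
pulse must push $V$ from its interictal baseline across the firing
threshold to ignite the resource-limited burst that feeds the pump.
Above the threshold the outcome is amplitude-insensitive (asserted
between 16 and 30 mA), so the sweep helpers default to 20 mA, which is
supra-critical for every shipped preset.

A structural consequence of the mechanism, asserted as an invariant in
the tests: once the train captures the system, the forced cycle is
strictly stationary, so every additional second of stimulation defers
the next seizure by one second and the slope of relative delay versus
duration equals $100/\mathrm{ISI}_{ctrl}$ %/s. Reported slopes should be
read with that identity in mind — they are a measurement of the control
ISI as much as of the stimulation.

## Fast-subsystem analysis

Because the resource nullcline gives $x_D^*(V)$ in closed form, the
frozen-ion equilibria reduce to roots of a scalar function of $V$;
`equilibria_at()` brackets them on a dense grid over $[-30, 60]$ mV and
refines to residuals below $10^{-8}$, with stability from the 2×2
Jacobian. `trace_branches()` locates the two folds by bisection on
root-count changes and the Hopf point by bisection on the real part of
the complex eigenvalue pair along the depolarized branch (tolerance
$10^{-4}$ mM). Dense scanning replaces pseudo-arclength continuation
deliberately: for a scalar root problem it is simpler and as robust.
For the reference preset the structure is LP2 ≈ 5.281 mM < HB1 ≈
5.432 mM < LP1 ≈ 6.253 mM, a non-empty bistable window in which the
regime is set by history (`classify_region()`). Periodic-orbit
continuation beyond the Hopf point is out of scope.

## Synthetic recordings

`generate_recording()` wraps a simulation into a surrogate LFP:
additive zero-mean Gaussian noise (default 0.5 mV against a ~30 mV
signal) and a slow sinusoidal baseline drift (default 1 mV, 120 s),
sampled at 1 kHz by default, with ground-truth events carried from the
clean trajectory. This emulates what the detection stage must survive —
broadband noise and slow drift — and deliberately nothing else: no
high-frequency ictal waveform content, no electrode physics. Passing
tests therefore certify the detection *procedure*, not performance on
real electrophysiology. `generate_trial_table()` emulates the paired
control/stimulated ISI design: control ISIs of 56 ± 5 s (the scale of
the recorded slices), stimulation lengths uniform on 15–60 s, relative
delays on a line of 1 %/s with 5% Gaussian scatter — numbers chosen
once to match the magnitudes reported for the in vitro experiment. At
zero scatter the pipeline returns the generating slope exactly; with
scatter, the fitted slope covers the truth within two standard errors
in ≥93% of seeded replicates (Monte-Carlo-checked).

## Statistics

`relative_delay()` is the percentage change of the stimulated ISI over
its matched control. `spearman()` uses average ranks; its two-sided
p-value is an exhaustive permutation enumeration below 10 pairs and the
t-approximation from there on (`cor.test` is the independent oracle in
the tests, never the implementation). `delay_stats()` reports the
regression and correlation twice, with and without outliers flagged at
|studentized residual| > 3 — mirroring dual reporting practice when a
single extreme trial dominates a small table; the cut at 3 is this
package's choice, as the original criterion was visual.

## Problem sizes and known limitations

The shipped tests and the acceptance script run whole experiments at
the scale of a few hundred model seconds per trial and some eighty
trials in total, a few minutes on one CPU; the slow-passage overlay is
the single heaviest computation (~30 s). Limitations worth keeping in
mind: the model is a single homogeneous population with no spatial
structure, no plasticity (so only short-term stimulation effects), no
depolarization block (the rate saturates instead), and the stimulation
electrode's field physics is abstracted into a single coupling
constant, so model amplitudes in mA are not directly comparable to
experimental stimulator settings.
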