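# epistim

Ion-dynamics modelling of recurrent seizure-like events and the
seizure-delaying effect of low-frequency electrical stimulation (LFES),
for computational neuroscientists and epilepsy researchers studying the
high-potassium in vitro model of ictogenesis.

The core is a four-variable neural mass model (a modified Epileptor-2):
membrane potential *V*, synaptic depression resource *x_D*,
extracellular potassium *[K⁺]o* and intracellular sodium *[Na⁺]i*,

    τ_m V̇   = u(V, x_D, K_o) − V + R_stim·I_stim(t)
    ẋ_D     = (1 − x_D)/τ_x − δ_x·x_D·ν(V)
    K̇_o     = (K_bath − K_o)/τ_K − 2γ·I_pump + δ_K·ν(V)
    Ṅa_i    = (Na_i0 − Na_i)/τ_Na − 3·I_pump + δ_Na·ν(V)

with sigmoid firing rate ν(V) = ν_max/(1 + e^(V_th − V)), Na-K pump flux
I_pump = ρ/[(1 + e^(3.5 − K_o))(1 + e^((25 − Na_i)/3))], and drive
u = ĝ_K·26.6 mV·ln(K_o/K_o0) + ĝ_exc·ν·x_D + ĝ_inh·(V_inh − V).
Potassium diffusing from the bath slowly charges the tissue until the
fast subsystem folds into a depolarized, rapidly firing state (the
seizure); firing loads the cells with sodium until the Na-K pump
activates, pulls potassium down, and ends the event. 1 Hz pulse trains
delivered between seizures keep the pump engaged and lock the system
onto a small stimulation-paced cycle that defers the next seizure.

The package provides:

* a deterministic compiled RK4 integrator with impulsive stimulation
  and time-varying bath potassium (`simulate_epileptor`, `stim_train`,
  `kbath_schedule`), plus step/ramp protocols
  (`run_kbath_step_protocol`, `run_kbath_ramp_with_probing`);
* seizure onset/offset detection with ISI extraction, mirroring the
  prominence-plus-changepoint procedure used on slice recordings
  (`detect_events`, `extract_isis`);
* LFES experiment designs: single trials, duration sweeps,
  onset-by-amplitude sweeps, critical-onset search and forced-attractor
  characterization (`run_lfes_trial`, `duration_sweep`,
  `onset_amplitude_sweep`, `find_critical_onset`,
  `characterize_forced_attractor`);
* fast-subsystem bifurcation analysis: equilibrium branches, folds and
  Hopf point, hysteresis classification, slow-passage overlays
  (`equilibria_at`, `trace_branches`, `classify_region`,
  `overlay_slow_trajectory`);
* delay statistics (relative delay, Spearman with exact small-sample
  permutation p-values, regressions with dual outlier reporting) and a
  synthetic-LFP generator with ground truth for end-to-end testing
  (`delay_stats`, `generate_recording`, `generate_trial_table`);
* five named parameter presets, `"slice0"`–`"slice4"`, plus a thin
  command-line layer (`epistim_cli`, installed as `exec/epistim`).

## Worked example

```r
library(epistim)

p <- slice_preset("slice0")          # reference parameter set
cyc <- steady_state_cycle(p)         # burn in to the seizure cycle
cyc
#> epi_cycle: control ISI 57.40 s, seizure duration 19.14 s

# 1 Hz, 20 mA train for 50 s, starting 5 s after a seizure offset
tr <- run_lfes_trial(cyc, onset = 5, duration = 50, amplitude = 20)
tr
#> LFES trial (20 mA, onset 5 s, 50 s at 1 Hz): ISI 57.40 -> 102.53 s,
#>   delay +78.6% [delayed]

trace_branches(p)
#> Fast-subsystem bifurcation structure:
#>   LP2 at K_o = 5.2809 mM, HB1 at 5.4315 mM, LP1 at 6.2527 mM
#>   bistable window: (5.2809, 6.2527) mM
```

Read: unstimulated, this preset seizes every 57.4 s. The train captures
the system onto the pump-active forced cycle and the next seizure
arrives 45 s late (+78.6% of the control interval). The potassium
seizure threshold of the fast subsystem is LP1 ≈ 6.25 mM; between
LP2 ≈ 5.28 mM and LP1 the ictal and interictal states coexist and the
realized regime depends on history.

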