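#' Burn the model in to its steady-state seizure cycle
#'
#' Simulates the unstimulated model, detects seizure events, and captures
#' the full state at the second detected seizure offset (everything before
#' it is discarded as transient). The control inter-seizure interval is
#' then measured by replaying the cycle from that state with no
#' stimulation, through the same detection pipeline used for stimulated
#' trials, so that control and stimulated ISIs are directly comparable.
#'
#' @param params An [epi_params()] object.
#' @param t_max Burn-in simulation length (s).
#' @param dt Integration step (s).
#' @return An object of class `epi_cycle`: reference state, control ISI
#'   (s), mean seizure duration (s), and the generating parameters.
#' @export
steady_state_cycle <- function(params, t_max = 500, dt = 1e-4) {
  traj <- simulate_epileptor(params, t_end = t_max, dt = dt)
  ev <- detect_events(traj)
  if (attr(ev, "regime") != "periodic" || nrow(ev) < 3)
    stop("no steady-state seizure cycle: regime is '", attr(ev, "regime"),
         "' with ", nrow(ev), " event(s)")
  ref <- ev$offset[2]
  idx <- which.min(abs(traj$time - ref))
  state <- c(V = traj$V[idx], x_D = traj$x_D[idx], K_o = traj$K_o[idx],
             Na_i = traj$Na_i[idx])
  rough_isi <- mean(extract_isis(ev))
  seiz_dur <- mean(ev$duration)
  cyc <- structure(list(state = state, params = params, dt = dt,
                        rough_isi = rough_isi, seiz_duration = seiz_dur,
                        ref_time = traj$time[idx]),
                   class = "epi_cycle")
  # control ISI through the identical trial pipeline, amplitude 0
  ctrl <- measure_trial_isi(cyc, onset = 0, duration = 0, amplitude = 0,
                            frequency = 1)
  cyc$isi_ctrl <- ctrl$isi
  cyc
}

#' @export
print.epi_cycle <- function(x, ...) {
  cat(sprintf("epi_cycle: control ISI %.2f s, seizure duration %.2f s\n",
              x$isi_ctrl, x$seiz_duration))
  invisible(x)
}

# Simulate one trial from the cycle's reference offset state and measure
# the time to the next detected seizure onset.
measure_trial_isi <- function(cycle, onset, duration, amplitude, frequency,
                              keep_trajectory = FALSE) {
  isi0 <- cycle$isi_ctrl %||% cycle$rough_isi
  t_end <- onset + duration + 2 * isi0 + 3 * cycle$seiz_duration + 40
  stim <- if (amplitude != 0 && duration >= 0)
    stim_train(onset = onset, duration = duration, amplitude = amplitude,
               frequency = frequency)
  traj <- simulate_epileptor(cycle$params, t_end = t_end, dt = cycle$dt,
                             init = cycle$state, stim = stim)
  ev <- detect_events(traj)
  ons <- ev$onset[ev$onset > 0.2]
  if (!length(ons))
    stop("no seizure detected within ", round(t_end), " s trial window")
  list(isi = ons[1], events = ev,
       trajectory = if (keep_trajectory) traj else NULL)
}

#' Run a single LFES trial
#'
#' Applies a 1 Hz (by default) pulse train starting `onset` seconds after
#' a steady-state seizure offset and measures the stimulated ISI: the
#' time from that offset to the next detected seizure onset. If the
#' stimulation itself triggers a seizure, that onset ends the ISI even
#' while the train continues. The relative seizure delay is
#' `100 * (ISI_stim - ISI_ctrl) / ISI_ctrl`.
#'
#' Outcome labels: `"immediate-seizure"` when the first seizure onset
#' falls at the start of the train (within two pulse periods),
#' `"delayed"` / `"shortened"` for a relative delay beyond +/-1%, and
#' `"no-effect"` otherwise.
#'
#' @param cycle An [steady_state_cycle()] object.
#' @param onset Train onset after the reference seizure offset (s).
#' @param duration Train duration (s).
#' @param amplitude Pulse amplitude (mA).
#' @param frequency Pulse rate (Hz).
#' @param keep_trajectory Keep the simulated trajectory in the result.
#' @return An object of class `lfes_trial`: list with `isi_ctrl`,
#'   `isi_stim`, `delay_pct`, `premature`, `label`, the stimulation
#'   parameters, and optionally `trajectory`.
#' @export
run_lfes_trial <- function(cycle, onset = 0, duration = 30, amplitude = 15,
                           frequency = 1, keep_trajectory = FALSE) {
  stopifnot(inherits(cycle, "epi_cycle"), onset >= 0, duration >= 0)
  m <- measure_trial_isi(cycle, onset, duration, amplitude, frequency,
                         keep_trajectory)
  isi_ctrl <- cycle$isi_ctrl
  delay <- relative_delay(m$isi, isi_ctrl)
  immediate <- amplitude != 0 &&
    (m$isi - onset) >= -2 && (m$isi - onset) <= 2 / frequency + 1
  label <- if (immediate) "immediate-seizure"
    else if (delay > 1) "delayed"
    else if (delay < -1) "shortened"
    else "no-effect"
  structure(list(isi_ctrl = isi_ctrl, isi_stim = m$isi, delay_pct = delay,
                 premature = m$isi < isi_ctrl, label = label,
                 onset = onset, duration = duration, amplitude = amplitude,
                 frequency = frequency, events = m$events,
                 trajectory = m$trajectory),
            class = "lfes_trial")
}

#' @export
print.lfes_trial <- function(x, ...) {
  cat(sprintf("LFES trial (%g mA, onset %g s, %g s at %g Hz): ISI %.2f -> %.2f s, delay %+.1f%% [%s]\n",
              x$amplitude, x$onset, x$duration, x$frequency,
              x$isi_ctrl, x$isi_stim, x$delay_pct, x$label))
  invisible(x)
}

#' Relative seizure delay versus stimulation duration
#'
#' Runs one LFES trial per duration and fits an ordinary least-squares
#' line of relative delay (%) against duration (s), restricted to
#' durations above 10 s: short trains are ineffective, and beyond this
#' point the delay grows linearly with the train length.
#'
#' @param cycle An [steady_state_cycle()] object.
#' @param durations Train durations to test (s).
#' @param amplitude Pulse amplitude (mA); default 15 mA (supra-critical).
#' @param onset Train onset after the reference offset (s).
#' @param frequency Pulse rate (Hz).
#' @return List with `trials` (data frame: duration, isi_stim, delay_pct,
#'   label), `slope` (% per s) and `intercept`; slope is `NA` when fewer
#'   than 3 effective durations remain.
#' @export
duration_sweep <- function(cycle, durations, amplitude = 15, onset = 0,
                           frequency = 1) {
  rows <- lapply(durations, function(d) {
    tr <- run_lfes_trial(cycle, onset = onset, duration = d,
                         amplitude = amplitude, frequency = frequency)
    data.frame(duration = d, isi_stim = tr$isi_stim,
               delay_pct = tr$delay_pct, label = tr$label)
  })
  trials <- do.call(rbind, rows)
  eff <- trials[trials$duration > 10, , drop = FALSE]
  if (nrow(eff) >= 3 && length(unique(eff$duration)) >= 3) {
    fit <- linear_fit(eff$duration, eff$delay_pct)
    slope <- fit$slope; intercept <- fit$intercept
  } else {
    slope <- NA_real_; intercept <- NA_real_
  }
  list(trials = trials, slope = slope, intercept = intercept,
       isi_ctrl = cycle$isi_ctrl)
}

#' Onset-by-amplitude LFES sweep
#'
#' Runs one LFES trial per grid cell at fixed duration and tabulates the
#' relative delay and outcome label of each cell.
#'
#' @param cycle An [steady_state_cycle()] object.
#' @param onsets Train onsets (s).
#' @param amplitudes Pulse amplitudes (mA).
#' @param duration Train duration (s); default 50 s.
#' @param frequency Pulse rate (Hz).
#' @return Data frame (long format) with columns `onset`, `amplitude`,
#'   `duration`, `delay_pct`, `label`, of class `lfes_sweep`.
#' @export
onset_amplitude_sweep <- function(cycle, onsets, amplitudes, duration = 50,
                                  frequency = 1) {
  stopifnot(length(onsets) > 0, length(amplitudes) > 0)
  grid <- expand.grid(onset = onsets, amplitude = amplitudes)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tr <- run_lfes_trial(cycle, onset = grid$onset[i], duration = duration,
                         amplitude = grid$amplitude[i], frequency = frequency)
    data.frame(onset = grid$onset[i], amplitude = grid$amplitude[i],
               duration = duration, delay_pct = tr$delay_pct,
               label = tr$label)
  })
  structure(do.call(rbind, rows), class = c("lfes_sweep", "data.frame"))
}

#' Largest effective stimulation onset
#'
#' Sweeps the train onset on a 1 s grid (matching the 1 Hz pulse clock)
#' at fixed supra-critical amplitude and duration, and returns the
#' largest onset whose trial is labeled `"delayed"`: a positive relative
#' delay without an immediate stimulus-triggered seizure. Beyond this
#' critical onset the first pulses land too close to the next expected
#' seizure and trigger it instead.
#'
#' @param cycle An [steady_state_cycle()] object.
#' @param amplitude Pulse amplitude (mA).
#' @param duration Train duration (s).
#' @param onsets Onset grid (s).
#' @param frequency Pulse rate (Hz).
#' @return The critical onset (s), with the sweep table as attribute
#'   `sweep`; `NA` when no onset yields a delayed trial.
#' @export
find_critical_onset <- function(cycle, amplitude = 20, duration = 50,
                                onsets = 0:25, frequency = 1) {
  sweep <- onset_amplitude_sweep(cycle, onsets = onsets,
                                 amplitudes = amplitude,
                                 duration = duration, frequency = frequency)
  delayed <- sweep$onset[sweep$label == "delayed"]
  out <- if (length(delayed)) max(delayed) else NA_real_
  attr(out, "sweep") <- sweep
  out
}

#' Characterize the stimulation-forced attractor
#'
#' During sustained effective LFES the system settles onto a small
#' stimulation-locked cycle at elevated Na-K pump activity: each pulse
#' nudges sodium and potassium up, and the active pump pulls both back
#' down. This function measures the ion and pump ranges over the late
#' part of the stimulation window, after transients.
#'
#' @param cycle An [steady_state_cycle()] object.
#' @param amplitude Pulse amplitude (mA); must be supra-critical.
#' @param duration Train duration (s); at least 150 s by default.
#' @param onset Train onset (s).
#' @param settle_fraction Fraction of the stimulation window discarded as
#'   transient; ranges are taken over the remaining final part.
#' @param frequency Pulse rate (Hz).
#' @return List with `Na_range`, `K_range` (mM), `pump_range` (mM/s),
#'   the measurement `window` (s) and the underlying `trial`.
#' @export
characterize_forced_attractor <- function(cycle, amplitude = 30,
                                          duration = 150, onset = 5,
                                          settle_fraction = 2 / 3,
                                          frequency = 1) {
  stopifnot(duration > 0, settle_fraction > 0, settle_fraction < 1)
  tr <- run_lfes_trial(cycle, onset = onset, duration = duration,
                       amplitude = amplitude, frequency = frequency,
                       keep_trajectory = TRUE)
  stim_end <- onset + duration
  if (tr$isi_stim < stim_end)
    stop("premature seizure at ", round(tr$isi_stim, 1),
         " s: the trial is not in the delayed regime")
  w_lo <- onset + settle_fraction * duration
  traj <- tr$trajectory
  sel <- traj$time >= w_lo & traj$time <= stim_end
  Ip <- pump_current(traj$K_o[sel], traj$Na_i[sel], cycle$params)
  list(Na_range = range(traj$Na_i[sel]), K_range = range(traj$K_o[sel]),
       pump_range = range(Ip), window = c(w_lo, stim_end), trial = tr)
}
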