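#' Bath-potassium step protocol
#'
#' Runs the model under a piecewise-constant bath potassium schedule
#' (each level held for `dwell` seconds) and classifies the dynamical
#' regime at each level: `"silent"` (no seizures), `"periodic"`
#' (recurrent seizure-like events) or `"persistent-depolarized"` (the
#' membrane locks at a high value, the model analogue of status
#' epilepticus). Seizures appear only above a bath-potassium threshold,
#' then shorten their ISIs with rising levels until the depolarized state
#' takes over.
#'
#' @param params An [epi_params()] object.
#' @param levels Bath potassium levels (mM), visited in order.
#' @param dwell Time spent at each level (s).
#' @param dt Integration step (s).
#' @return List with the concatenated `trajectory` and a `levels` data
#'   frame (level, regime, n_events, mean ISI, mean seizure duration).
#' @export
run_kbath_step_protocol <- function(params, levels, dwell = 200, dt = 1e-4) {
  stopifnot(all(levels > 0), dwell > 0)
  n <- length(levels)
  kb <- kbath_schedule("step", times = (seq_len(n) - 1) * dwell,
                       values = levels)
  traj <- simulate_epileptor(params, t_end = n * dwell, dt = dt, kbath = kb)
  rate <- 1 / traj$record_dt
  res <- lapply(seq_len(n), function(i) {
    t_lo <- (i - 1) * dwell; t_hi <- i * dwell
    sel <- traj$time >= t_lo & traj$time < t_hi
    seg_par <- update(params, K_bath = levels[i])
    ev <- detect_events(structure(list(V = traj$V[sel], time = traj$time[sel],
                                       record_dt = traj$record_dt,
                                       params = seg_par),
                                  class = "epi_trajectory"))
    isis <- extract_isis(ev)
    data.frame(K_bath = levels[i], regime = attr(ev, "regime"),
               n_events = nrow(ev),
               mean_isi = if (length(isis)) mean(isis) else NA_real_,
               mean_duration = if (nrow(ev)) mean(ev$duration) else NA_real_)
  })
  list(trajectory = traj, levels = do.call(rbind, res))
}

#' Bath-potassium ramp with probing stimulation
#'
#' Emulates the experimental potassium-addition protocol: bath potassium
#' rises linearly from `K_start` at `ramp_rate` while short probing pulse
#' trains are delivered at the given times. At low extracellular
#' potassium a probe elicits only a transient depolarization artifact; at
#' elevated potassium the first pulse of a probe triggers a full seizure.
#'
#' @param params An [epi_params()] object.
#' @param ramp_rate Bath potassium increase (mM/s).
#' @param probe_times Times of the probes (s).
#' @param probe_amplitude Probe amplitude (mA); default 15 mA.
#' @param probe_duration Length of each probe train (s); the default 0
#'   delivers a single spike per probe, as in the experimental protocol.
#' @param probe_frequency Probe pulse rate (Hz).
#' @param K_start Initial bath potassium (mM).
#' @param t_end Simulation length (s).
#' @param dt Integration step (s).
#' @return List with `trajectory` and a `probes` data frame (time,
#'   K_o at probe, whether a seizure followed within `response_window`).
#' @export
run_kbath_ramp_with_probing <- function(params, ramp_rate = 0.01,
                                        probe_times = numeric(0),
                                        probe_amplitude = 15,
                                        probe_duration = 0,
                                        probe_frequency = 1,
                                        K_start = 3, t_end = 400,
                                        dt = 1e-4) {
  stopifnot(ramp_rate > 0)
  kb <- kbath_schedule("ramp", times = c(0, t_end),
                       values = c(K_start, K_start + ramp_rate * t_end))
  stim <- lapply(probe_times, function(t0)
    stim_train(onset = t0, duration = probe_duration,
               amplitude = probe_amplitude, frequency = probe_frequency))
  init <- c(V = 0, x_D = 1, K_o = K_start, Na_i = params$Na_i0)
  traj <- simulate_epileptor(params, t_end = t_end, dt = dt, init = init,
                             stim = stim, kbath = kb)
  ev <- detect_events(traj)
  # A probe "triggers" a seizure when the population keeps firing well
  # after the train has ended; a mere stimulation artifact (burst per
  # pulse) dies out within a couple of seconds of the last pulse.
  rate_tr <- firing_rate(traj$V, params)
  probes <- do.call(rbind, lapply(probe_times, function(t0) {
    i <- findInterval(t0, traj$time)
    w <- traj$time >= t0 + probe_duration + 3 &
      traj$time <= t0 + probe_duration + 10
    triggered <- any(w) && mean(rate_tr[w]) > params$nu_max / 4
    data.frame(time = t0, K_o = traj$K_o[max(i, 1L)],
               triggered_seizure = triggered)
  }))
  list(trajectory = traj, events = ev, probes = probes)
}
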