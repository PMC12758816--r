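# Synthetic surrogate recordings with the statistical structure of the in
# vitro LFP experiment: recurrent seizure-like events separated by tens of
# seconds, corrupted by additive Gaussian noise and slow baseline drift,
# with ground-truth event annotations carried from the noise-free model
# trajectory. These make the detection and statistics stages testable
# without any experimental data.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a synthetic LFP-like recording
#'
#' Simulates the model, takes the membrane potential as the LFP proxy,
#' and corrupts it with zero-mean Gaussian noise and a slow sinusoidal
#' baseline drift before decimating to the target sampling rate. The
#' ground-truth event table is obtained by running the detection pipeline
#' on the clean trajectory. Identical seeds give bit-identical
#' recordings.
#'
#' @param params An [epi_params()] object; default reference preset.
#' @param t_end Recording length (s).
#' @param noise_sd Gaussian noise standard deviation (mV).
#' @param drift_amplitude Amplitude of the sinusoidal baseline drift (mV).
#' @param drift_period Drift period (s).
#' @param decimate_to Target sampling rate (Hz); must divide 1 kHz.
#' @param seed Integer seed for the noise.
#' @param stim Optional [stim_train()] (or list) applied to the model.
#' @param dt Integration step (s).
#' @return An object of class `synthetic_recording`: `time`, `trace`,
#'   `rate`, `events_truth`, `stim`, `seed`, `params`.
#' @export
generate_recording <- function(params = slice_preset("slice0"), t_end = 300,
                               noise_sd = 0.5, drift_amplitude = 1,
                               drift_period = 120, decimate_to = 1000,
                               seed = 1, stim = NULL, dt = 1e-4) {
  stopifnot(noise_sd >= 0, drift_amplitude >= 0)
  base_rate <- 1000
  if (base_rate %% decimate_to != 0)
    stop("decimate_to must divide ", base_rate, " Hz")
  traj <- simulate_epileptor(params, t_end = t_end, dt = dt, stim = stim,
                             record_dt = 1 / base_rate)
  truth <- detect_events(traj)
  k <- base_rate %/% decimate_to
  idx <- seq(1L, length(traj$time), by = k)
  time <- traj$time[idx]
  clean <- traj$V[idx]
  trace <- with_seed(seed, {
    drift <- if (drift_amplitude > 0)
      drift_amplitude * sin(2 * pi * time / drift_period) else 0
    noise <- if (noise_sd > 0) stats::rnorm(length(clean), 0, noise_sd) else 0
    clean + drift + noise
  })
  structure(list(time = time, trace = trace, rate = decimate_to,
                 events_truth = truth, stim = stim, seed = seed,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 params = params),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("synthetic_recording: %.0f s at %g Hz, noise %.2g mV, %d true event(s), seed %s\n",
              max(x$time), x$rate, x$noise_sd, nrow(x$events_truth),
              format(x$seed)))
  invisible(x)
}

#' Compare detected events against ground truth
#'
#' An event counts as recovered when its detected onset and offset both
#' fall within `tol` seconds of a ground-truth event.
#'
#' @param detected,truth `epi_events` tables.
#' @param tol Matching tolerance (s).
#' @return List with `recall`, `precision` and the number of matches.
#' @export
event_recovery <- function(detected, truth, tol = 2) {
  if (!nrow(truth))
    return(list(recall = NA_real_,
                precision = if (nrow(detected)) 0 else NA_real_,
                n_matched = 0L))
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    any(abs(detected$onset - truth$onset[i]) <= tol &
          abs(detected$offset - truth$offset[i]) <= tol)
  }, logical(1))
  matched_det <- vapply(seq_len(nrow(detected)), function(i) {
    any(abs(truth$onset - detected$onset[i]) <= tol &
          abs(truth$offset - detected$offset[i]) <= tol)
  }, logical(1))
  list(recall = mean(matched),
       precision = if (nrow(detected)) mean(matched_det) else NA_real_,
       n_matched = sum(matched))
}

#' Generate a synthetic paired-trial table
#'
#' Emulates the paired control/stimulated ISI design of the slice
#' experiments: each stimulated ISI is matched to a preceding control
#' ISI. Control ISIs are drawn from a normal distribution, relative
#' delays follow a linear dependence on the stimulation length plus
#' Gaussian scatter, and the stimulated ISIs are derived from both.
#'
#' @param n_trials Number of trials (at least 4).
#' @param base_isi Mean control ISI (s).
#' @param isi_sd Control ISI standard deviation (s).
#' @param slope Generating delay slope (% per s of stimulation).
#' @param scatter_sd Delay scatter around the line (%).
#' @param stim_length_range Range of stimulation lengths (s), sampled
#'   uniformly.
#' @param seed Integer seed.
#' @return Data frame of class `trial_table` with columns `stim_length`,
#'   `isi_ctrl`, `isi_stim`, `delay_pct`, and attribute `slope_true`.
#' @export
generate_trial_table <- function(n_trials = 20, base_isi = 56, isi_sd = 5,
                                 slope = 1.0, scatter_sd = 5,
                                 stim_length_range = c(15, 60), seed = 1) {
  stopifnot(n_trials >= 4, base_isi > 0, isi_sd >= 0, scatter_sd >= 0)
  with_seed(seed, {
    len <- stats::runif(n_trials, stim_length_range[1], stim_length_range[2])
    ctrl <- pmax(stats::rnorm(n_trials, base_isi, isi_sd), base_isi / 10)
    delay <- slope * len +
      if (scatter_sd > 0) stats::rnorm(n_trials, 0, scatter_sd) else 0
    stim <- ctrl * (1 + delay / 100)
    structure(data.frame(stim_length = len, isi_ctrl = ctrl,
                         isi_stim = stim, delay_pct = delay),
              class = c("trial_table", "data.frame"),
              slope_true = slope)
  })
}
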