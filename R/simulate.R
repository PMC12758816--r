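#' Low-frequency stimulation train
#'
#' Describes an LFES pulse train: pulses of amplitude `amplitude` (mA)
#' delivered at `frequency` Hz from `onset` for `duration` seconds. Each
#' pulse is an impulse that displaces the membrane potential by
#' `R_stim * amplitude` mV. Pulse times are
#' `onset + n / frequency` for `n = 0, ..., floor(duration * frequency)`.
#'
#' @param onset Time of the first pulse (s).
#' @param duration Train length (s); non-negative.
#' @param amplitude Pulse amplitude (mA).
#' @param frequency Pulse rate (Hz); default 1 Hz as in the experimental
#'   protocol.
#' @return An object of class `stim_train` with a `pulse_times` field.
#' @export
stim_train <- function(onset = 0, duration = 30, amplitude = 15,
                       frequency = 1) {
  stopifnot(duration >= 0, frequency > 0, onset >= 0)
  pulse_times <- onset + seq(0, floor(duration * frequency)) / frequency
  structure(list(onset = onset, duration = duration, amplitude = amplitude,
                 frequency = frequency, pulse_times = pulse_times),
            class = "stim_train")
}

#' @export
print.stim_train <- function(x, ...) {
  cat(sprintf("LFES train: %g mA at %g Hz, onset %g s, duration %g s (%d pulses)\n",
              x$amplitude, x$frequency, x$onset, x$duration,
              length(x$pulse_times)))
  invisible(x)
}

#' Bath potassium schedule
#'
#' Time course of the bath potassium concentration `K_bath(t)`:
#' constant, piecewise-constant steps (value held from each breakpoint),
#' or a piecewise-linear ramp through the given points.
#'
#' @param mode `"constant"`, `"step"` or `"ramp"`.
#' @param times Breakpoint times (s); first must be 0.
#' @param values Concentrations (mM) at the breakpoints; all positive.
#' @return An object of class `kbath_schedule`.
#' @export
kbath_schedule <- function(mode = c("constant", "step", "ramp"),
                           times = 0, values) {
  mode <- match.arg(mode)
  stopifnot(length(times) == length(values), all(values > 0),
            !is.unsorted(times, strictly = TRUE))
  structure(list(mode = mode, times = as.numeric(times),
                 values = as.numeric(values)), class = "kbath_schedule")
}

kbath_mode_code <- function(kb) {
  switch(kb$mode, constant = 0L, step = 1L, ramp = 2L)
}

#' Simulate the modified Epileptor-2 model
#'
#' Integrates the model with a fixed-step 4th-order Runge-Kutta scheme.
#' Stimulation pulses are applied impulsively: at each pulse time (snapped
#' to the integration grid) the membrane potential jumps by
#' `R_stim * amplitude` mV. The simulation is fully deterministic.
#'
#' @param params An [epi_params()] object.
#' @param t_end Simulation length (s).
#' @param dt Integration step (s); must satisfy `dt <= tau_m / 10`.
#'   Default 1e-4 s (`tau_m / 20` at the reference membrane time constant).
#' @param init Initial state `c(V, x_D, K_o, Na_i)`; default resting state.
#' @param stim A [stim_train()], a list of them, or `NULL`.
#' @param kbath A [kbath_schedule()] or `NULL` for constant
#'   `params$K_bath`.
#' @param epsilon Scaling of the slow (ion) equations; 1 is the standard
#'   model, small values (e.g. 0.003) produce slow-passage trajectories
#'   that hug the fast-subsystem equilibrium surface.
#' @param record_dt Sampling interval of the returned trajectory (s);
#'   must be a multiple of `dt`. Default 1e-3 s (1 kHz).
#' @return An object of class `epi_trajectory`: list with fields `time`,
#'   `V`, `x_D`, `K_o`, `Na_i`, `pulse_times`, `final_state`, `params`.
#' @examples
#' \donttest{
#' p <- slice_preset("slice0")
#' tr <- simulate_epileptor(p, t_end = 100)
#' plot(tr)
#' }
#' @export
simulate_epileptor <- function(params, t_end, dt = 1e-4, init = NULL,
                               stim = NULL, kbath = NULL, epsilon = 1,
                               record_dt = 1e-3) {
  stopifnot(inherits(params, "epi_params"), t_end > 0, epsilon > 0,
            epsilon <= 1)
  if (dt > params$tau_m / 10 + 1e-12)
    stop("dt must not exceed tau_m / 10 = ", params$tau_m / 10, " s")
  record_every <- as.integer(round(record_dt / dt))
  if (record_every < 1L || abs(record_every * dt - record_dt) > 1e-9 * record_dt)
    stop("record_dt must be a positive multiple of dt")
  n_steps <- as.integer(ceiling(round(t_end / dt, 6)))
  # round the number of steps up to a full recording interval
  n_steps <- as.integer(ceiling(n_steps / record_every) * record_every)

  if (is.null(init)) init <- default_state(params)
  init <- as.numeric(unlist(init))
  stopifnot(length(init) == 4, init[3] > 0, init[4] > 0)

  if (inherits(stim, "stim_train")) stim <- list(stim)
  pulse_t <- numeric(0); pulse_dv <- numeric(0)
  for (s in stim) {
    stopifnot(inherits(s, "stim_train"))
    pulse_t <- c(pulse_t, s$pulse_times)
    pulse_dv <- c(pulse_dv, rep(params$R_stim * s$amplitude,
                                length(s$pulse_times)))
  }
  ord <- order(pulse_t)
  pulse_t <- pulse_t[ord]; pulse_dv <- pulse_dv[ord]
  keep <- pulse_t <= n_steps * dt & pulse_dv != 0
  pulse_step <- as.integer(round(pulse_t[keep] / dt))
  pulse_dv <- pulse_dv[keep]

  if (is.null(kbath)) {
    kb_mode <- 0L; kb_t <- 0; kb_v <- params$K_bath
  } else {
    stopifnot(inherits(kbath, "kbath_schedule"))
    kb_mode <- kbath_mode_code(kbath); kb_t <- kbath$times; kb_v <- kbath$values
  }

  out <- rk4_integrate(par_vector(params), init, n_steps, dt,
                       pulse_step, pulse_dv, kb_mode, kb_t, kb_v,
                       epsilon, record_every)
  structure(list(time = out$time, V = out$V, x_D = out$x_D, K_o = out$K_o,
                 Na_i = out$Na_i, final_state = out$final_state,
                 pulse_times = pulse_step * dt, params = params,
                 dt = dt, record_dt = record_every * dt, epsilon = epsilon),
            class = "epi_trajectory")
}

#' @export
print.epi_trajectory <- function(x, ...) {
  cat(sprintf("epi_trajectory: %.1f s at %g s sampling (%d samples), %d pulses\n",
              max(x$time), x$record_dt, length(x$time), length(x$pulse_times)))
  cat(sprintf("  final state: V=%.3f mV, x_D=%.4f, K_o=%.4f mM, Na_i=%.4f mM\n",
              x$final_state[1], x$final_state[2], x$final_state[3],
              x$final_state[4]))
  invisible(x)
}

#' @export
as.data.frame.epi_trajectory <- function(x, ...) {
  stim <- rep(FALSE, length(x$time))
  if (length(x$pulse_times)) {
    idx <- findInterval(x$pulse_times, x$time)
    stim[pmax(idx, 1L)] <- TRUE
  }
  data.frame(time = x$time, V = x$V, x_D = x$x_D, K_o = x$K_o,
             Na_i = x$Na_i, stim = stim)
}

#' Plot a simulated trajectory
#'
#' @param x An `epi_trajectory`.
#' @param vars Which state variables to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.epi_trajectory <- function(x, vars = c("V", "K_o", "Na_i"), ...) {
  vars <- match.arg(vars, c("V", "x_D", "K_o", "Na_i"), several.ok = TRUE)
  old <- graphics::par(mfrow = c(length(vars), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (v in vars) {
    graphics::plot(x$time, x[[v]], type = "l", xlab = "time (s)",
                   ylab = v, ...)
    if (v == "V" && length(x$pulse_times))
      graphics::rug(x$pulse_times, col = "red")
  }
  invisible(x)
}

#' Derived signals of a trajectory
#'
#' @param x An `epi_trajectory`.
#' @return Data frame with `time`, firing `rate` (Hz) and pump flux
#'   `I_pump` (mM/s).
#' @export
trajectory_derived <- function(x) {
  stopifnot(inherits(x, "epi_trajectory"))
  data.frame(time = x$time, rate = firing_rate(x$V, x$params),
             I_pump = pump_current(x$K_o, x$Na_i, x$params))
}

#' Write a trajectory as CSV
#'
#' Columns: `time, V, x_D, K_o, Na_i, stim`.
#'
#' @param x An `epi_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
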