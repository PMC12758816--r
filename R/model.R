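#' Population firing rate
#'
#' Sigmoid rate function of the excitatory population,
#' `nu(V) = nu_max / (1 + exp(V_th - V))`, with the exponent taken per mV.
#' Strictly increasing in `V` and bounded in `(0, nu_max)`.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param params An [epi_params()] object.
#' @return Firing rate (Hz).
#' @export
firing_rate <- function(V, params) {
  params$nu_max / (1 + exp(params$V_th - V))
}

#' Na-K pump flux
#'
#' Electrogenic sodium-potassium pump activity as a saturating function of
#' extracellular potassium and intracellular sodium:
#' `rho / ((1 + exp(3.5 - K_o)) * (1 + exp((25 - Na_i)/3)))`.
#' The pump extrudes 3 Na+ and imports 2 K+ per cycle; in the model it is
#' the seizure-terminating negative feedback. Bounded in `(0, rho)` and
#' strictly increasing in both arguments.
#'
#' @param K_o Extracellular potassium (mM); vectorized.
#' @param Na_i Intracellular sodium (mM); vectorized.
#' @param params An [epi_params()] object.
#' @return Pump flux (mM/s).
#' @export
pump_current <- function(K_o, Na_i, params) {
  params$rho / ((1 + exp(3.5 - K_o)) * (1 + exp((25.0 - Na_i) / 3)))
}

#' Total synaptic and ionic drive on the membrane potential
#'
#' The input `u(V, x_D, K_o)` combines a potassium depolarizing term
#' (Nernst-type, `g_K_rel * 26.6 * ln(K_o / K_o0)`), current-based
#' excitation (`g_exc_rel * nu(V) * x_D`) and conductance-based shunting
#' inhibition (`g_inh_rel * (V_inh - V)`), all expressed relative to the
#' leak conductance so the result is in mV.
#'
#' @param V Membrane potential (mV).
#' @param x_D Synaptic resource (dimensionless, in `[0, 1]`).
#' @param K_o Extracellular potassium (mM), must be positive.
#' @param params An [epi_params()] object.
#' @return Drive `u` (mV).
#' @export
membrane_drive <- function(V, x_D, K_o, params) {
  if (any(K_o <= 0)) stop("K_o must be strictly positive")
  params$g_K_rel * params$nernst_scale * log(K_o / params$K_o0) +
    params$g_exc_rel * firing_rate(V, params) * x_D +
    params$g_inh_rel * (params$V_inh - V)
}

#' Time derivatives of the model state
#'
#' The continuous vector field of the modified Epileptor-2 model (the
#' impulsive stimulation is handled separately by the integrator):
#' \deqn{\tau_m \dot V = u - V}
#' \deqn{\dot x_D = (1 - x_D)/\tau_x - \delta_x x_D \nu(V)}
#' \deqn{\dot K_o = (K_{bath} - K_o)/\tau_K - 2\gamma I_{pump} + \delta_K \nu(V)}
#' \deqn{\dot{Na}_i = (Na_{i0} - Na_i)/\tau_{Na} - 3 I_{pump} + \delta_{Na} \nu(V)}
#'
#' @param state Numeric vector `c(V, x_D, K_o, Na_i)` or a named list.
#' @param params An [epi_params()] object.
#' @param K_bath Bath potassium (mM); defaults to `params$K_bath`.
#' @return Named numeric vector of derivatives
#'   `(mV/s, 1/s, mM/s, mM/s)`.
#' @export
model_derivatives <- function(state, params, K_bath = params$K_bath) {
  s <- as.numeric(unlist(state))
  stopifnot(length(s) == 4)
  V <- s[1]; x_D <- s[2]; K_o <- s[3]; Na_i <- s[4]
  if (K_o <= 0 || Na_i <= 0) stop("concentrations must be strictly positive")
  nu <- firing_rate(V, params)
  u <- membrane_drive(V, x_D, K_o, params)
  Ip <- pump_current(K_o, Na_i, params)
  c(dV = (u - V) / params$tau_m,
    dx_D = (1 - x_D) / params$tau_x - params$delta_x * x_D * nu,
    dK_o = (K_bath - K_o) / params$tau_K - 2 * params$gamma * Ip +
      params$delta_K * nu,
    dNa_i = (params$Na_i0 - Na_i) / params$tau_Na - 3 * Ip +
      params$delta_Na * nu)
}

# Default initial condition: resting potential, full resource, resting ions.
default_state <- function(params) {
  c(V = 0, x_D = 1, K_o = params$K_o0, Na_i = params$Na_i0)
}
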