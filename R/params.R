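#' Model parameters for the modified Epileptor-2 model
#'
#' Constructs a validated parameter set for the neural mass model of
#' seizure-like events in high-potassium hippocampal tissue. Defaults are
#' the fixed reference set ("slice0"); individual values can be overridden.
#'
#' The model tracks four state variables: the population-average membrane
#' potential `V` (mV) of pyramidal cells, a synaptic depression resource
#' `x_D` in `[0, 1]`, the extracellular potassium concentration `K_o` (mM)
#' and the intracellular sodium concentration `Na_i` (mM).
#'
#' @param gamma Extracellular/intracellular potassium volume ratio
#'   (dimensionless).
#' @param delta_K Extracellular potassium increment per spike (mM).
#' @param delta_Na Intracellular sodium increment per spike (mM).
#' @param delta_x Synaptic resource decrement per spike (dimensionless).
#' @param K_bath Potassium concentration of the perfusing bath (mM); the
#'   slow drive of the model.
#' @param K_o0 Resting extracellular potassium concentration (mM).
#' @param Na_i0 Resting intracellular sodium concentration (mM).
#' @param tau_K,tau_Na,tau_m,tau_x Time constants (s) of the potassium,
#'   sodium, membrane and synaptic-depression dynamics.
#' @param rho Maximum Na-K pump flux (mM/s).
#' @param R_stim Stimulation coupling (mV per mA): an impulse of amplitude
#'   `A` mA displaces the membrane potential by `R_stim * A` mV.
#' @param g_K_rel Potassium conductance relative to leak (dimensionless).
#' @param g_exc_rel Excitatory synaptic conductance relative to leak; carries
#'   units mV.s so that firing rate times resource yields mV.
#' @param g_inh_rel Inhibitory synaptic conductance relative to leak
#'   (dimensionless); the inhibitory population fires at a constant rate and
#'   acts through conductance-based (shunting) synapses.
#' @param V_inh Inhibitory reversal potential (mV).
#' @param V_th Firing threshold of the sigmoid rate function (mV).
#' @param nu_max Maximum population firing rate (Hz).
#' @param nernst_scale Nernst prefactor of the potassium log term (mV);
#'   26.6 mV is RT/F at 34 degrees C for the natural logarithm.
#' @param ... Ignored; present so parameter lists can be spliced.
#'
#' @return An object of class `epi_params`: a named list of parameters.
#' @seealso [slice_preset()] for the named presets fitted to individual
#'   slices.
#' @examples
#' p <- epi_params(K_bath = 9.5, V_th = 14)
#' p$K_bath
#' @export
epi_params <- function(gamma = 10, delta_K = 0.02, delta_Na = 0.03,
                       delta_x = 0.01, K_bath = 8.5, K_o0 = 3.0,
                       Na_i0 = 10.0, tau_K = 17.5, tau_Na = 35.0,
                       tau_m = 0.002, tau_x = 2.0, rho = 0.1142,
                       R_stim = 1.0, g_K_rel = 0.5, g_exc_rel = 0.3,
                       g_inh_rel = 0.1686, V_inh = -15, V_th = 10,
                       nu_max = 75, nernst_scale = 26.6, ...) {
  p <- list(gamma = gamma, delta_K = delta_K, delta_Na = delta_Na,
            delta_x = delta_x, K_bath = K_bath, K_o0 = K_o0, Na_i0 = Na_i0,
            tau_K = tau_K, tau_Na = tau_Na, tau_m = tau_m, tau_x = tau_x,
            rho = rho, R_stim = R_stim, g_K_rel = g_K_rel,
            g_exc_rel = g_exc_rel, g_inh_rel = g_inh_rel, V_inh = V_inh,
            V_th = V_th, nu_max = nu_max, nernst_scale = nernst_scale)
  validate_epi_params(p)
  structure(p, class = "epi_params")
}

validate_epi_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p))
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar")
  pos <- c("gamma", "K_bath", "K_o0", "Na_i0", "tau_K", "tau_Na", "tau_m",
           "tau_x", "rho", "nu_max", "nernst_scale")
  for (nm in pos)
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be strictly positive")
  nn <- c("g_K_rel", "g_exc_rel", "g_inh_rel", "delta_K", "delta_Na",
          "delta_x")
  for (nm in nn)
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be non-negative")
  invisible(p)
}

#' Slice-specific parameter presets
#'
#' Returns the model parameter set for one of the five named presets:
#' the reference set `"slice0"` and the sets fitted to the four recorded
#' hippocampal slices (`"slice1"` to `"slice4"`). The presets differ in
#' bath potassium `K_bath`, firing threshold `V_th`, maximum rate `nu_max`
#' and inhibitory conductance `g_inh_rel`; all other parameters are shared.
#'
#' @param name Preset name, one of `"slice0"`..`"slice4"`.
#' @param ... Parameter overrides applied on top of the preset, e.g.
#'   `g_inh_rel = 0` for the no-inhibition variant.
#' @return An [epi_params()] object.
#' @examples
#' slice_preset("slice1")$V_th # 14 mV
#' @export
slice_preset <- function(name = c("slice0", "slice1", "slice2", "slice3",
                                  "slice4"), ...) {
  name <- match.arg(name)
  spec <- switch(name,
    slice0 = list(K_bath = 8.5, V_th = 10,  nu_max = 75, g_inh_rel = 0.1686),
    slice1 = list(K_bath = 9.5, V_th = 14,  nu_max = 80, g_inh_rel = 0.05),
    slice2 = list(K_bath = 8.6, V_th = 12,  nu_max = 70, g_inh_rel = 0.05),
    slice3 = list(K_bath = 8.0, V_th = 10,  nu_max = 70, g_inh_rel = 0.05),
    slice4 = list(K_bath = 5.3, V_th = 2.4, nu_max = 35, g_inh_rel = 0.1686))
  p <- do.call(epi_params, utils::modifyList(spec, list(...)))
  attr(p, "preset") <- name
  p
}

#' Update a parameter set
#'
#' @param object An [epi_params()] object.
#' @param ... Named parameter replacements.
#' @return The modified, re-validated `epi_params` object.
#' @export
update.epi_params <- function(object, ...) {
  repl <- list(...)
  if (length(repl) == 0L) return(object)
  bad <- setdiff(names(repl), names(object))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- utils::modifyList(unclass(object), repl)
  validate_epi_params(p)
  structure(p, class = "epi_params", preset = attr(object, "preset"))
}

#' @export
print.epi_params <- function(x, ...) {
  preset <- attr(x, "preset")
  cat("Modified Epileptor-2 parameters",
      if (!is.null(preset)) paste0(" (preset '", preset, "')"), "\n", sep = "")
  v <- unlist(unclass(x))
  print(v, ...)
  invisible(x)
}

# Parameter vector in the fixed order expected by the compiled integrator.
par_vector <- function(p) {
  c(p$gamma, p$delta_K, p$delta_Na, p$delta_x, p$K_o0, p$Na_i0,
    p$tau_K, p$tau_Na, p$tau_m, p$tau_x, p$rho, p$g_K_rel, p$g_exc_rel,
    p$g_inh_rel, p$V_inh, p$V_th, p$nu_max, p$nernst_scale)
}

#' Read parameters from a YAML/flat key-value config file
#'
#' The file may name a `preset` plus any parameter overrides using the
#' field names of [epi_params()]. Overrides take precedence over the
#' preset, which defaults to `"slice0"`.
#'
#' @param path Path to a YAML file.
#' @return An [epi_params()] object.
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  preset <- cfg$preset %||% "slice0"
  cfg$preset <- NULL
  do.call(slice_preset, c(list(name = preset), cfg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
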