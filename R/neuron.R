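#' Integrate-and-fire neuron parameters
#'
#' `model = "PIF"` is the perfect integrator (no leak; the membrane time
#' constant is ignored). `model = "LIF"` is the leaky integrator with
#' time constant `tau_m`. On reaching `v_th` a spike is emitted and the
#' potential is reset to `v_reset` (equal to rest by default), where it is
#' clamped for the absolute refractory period `tau_ref`, during which all
#' synaptic input is shunted.
#'
#' @param model `"PIF"` or `"LIF"`.
#' @param tau_m membrane time constant (ms; LIF only).
#' @param v_rest,v_th,v_reset resting, threshold and reset potential (mV).
#' @param tau_ref absolute refractory period (ms, >= 0).
#' @return `osnet_neuron` object.
#' @export
neuron_params <- function(model = c("LIF", "PIF"), tau_m = 20,
                          v_rest = 0, v_th = 20, v_reset = v_rest,
                          tau_ref = 2) {
  model <- match.arg(model)
  if (model == "LIF" && tau_m <= 0) stop("tau_m must be positive for LIF")
  if (v_th <= v_reset) stop("v_th must exceed v_reset")
  if (tau_ref < 0) stop("tau_ref must be non-negative")
  structure(list(model = model, tau_m = tau_m, v_rest = v_rest,
                 v_th = v_th, v_reset = v_reset, tau_ref = tau_ref),
            class = "osnet_neuron")
}

#' One step of subthreshold propagation (exact integration)
#'
#' LIF: `v' = v_rest + (v - v_rest) * exp(-dt / tau_m)`; PIF: `v' = v`.
#' This closed-form update is error-free between input events.
#'
#' @param v membrane potential(s), mV.
#' @param neuron an [neuron_params()] object.
#' @param dt time step, ms (> 0).
#' @return propagated potential(s), mV.
#' @export
propagate_subthreshold <- function(v, neuron, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (neuron$model == "PIF") return(v)
  neuron$v_rest + (v - neuron$v_rest) * exp(-dt / neuron$tau_m)
}
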