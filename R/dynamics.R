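#' Leaky integrate-and-fire neuron parameters
#'
#' Parameter set for a current-based LIF neuron with an adaptive firing
#' threshold, post-spike reset and absolute refractory period. Membrane
#' potential leaks exponentially toward `v_rest`; excitatory and inhibitory
#' post-synaptic currents decay exponentially with their own time constants;
#' each output spike raises the threshold by `theta_plus`, and that offset
#' decays with `tau_theta` (slow homeostasis).
#'
#' Defaults are the standard values of the two-layer unsupervised-SNN
#' lineage this architecture descends from, with the post-synaptic current
#' time constants set to 2 ms (excitatory) and 1 ms (inhibitory).
#'
#' @param tau_mem Membrane time constant (ms).
#' @param v_rest Resting potential (mV).
#' @param v_reset Reset potential after a spike (mV).
#' @param theta_base Base firing threshold (mV); a neuron fires when its
#'   potential exceeds `theta_base + theta_adapt`.
#' @param theta_plus Adaptive-threshold increment per output spike (mV).
#'   Set to 0 for a fixed threshold (inhibitory population default).
#' @param tau_theta Adaptive-threshold decay time constant (ms).
#' @param t_refrac Absolute refractory period (ms).
#' @param tau_syn_e Excitatory post-synaptic current time constant (ms).
#' @param tau_syn_i Inhibitory post-synaptic current time constant (ms).
#' @return An object of class `lif_params`.
#' @seealso [lif_params_inhibitory()] for the inhibitory-population defaults,
#'   [neuron_state()] for the state container the parameters act on.
#' @export
#' @examples
#' p <- lif_params()
#' s <- neuron_state(1, p)
#' decay_state(s, p, dt = 0.5)
lif_params <- function(tau_mem = 100, v_rest = -65, v_reset = -65,
                       theta_base = -52, theta_plus = 0.05,
                       tau_theta = 1e7, t_refrac = 5,
                       tau_syn_e = 2, tau_syn_i = 1) {
  stopifnot(
    tau_mem > 0, tau_theta > 0, tau_syn_e > 0, tau_syn_i > 0,
    t_refrac >= 0, theta_plus >= 0, theta_base > v_reset
  )
  structure(
    list(tau_mem = tau_mem, v_rest = v_rest, v_reset = v_reset,
         theta_base = theta_base, theta_plus = theta_plus,
         tau_theta = tau_theta, t_refrac = t_refrac,
         tau_syn_e = tau_syn_e, tau_syn_i = tau_syn_i),
    class = "lif_params"
  )
}

#' Inhibitory-population LIF defaults
#'
#' Faster membrane, fixed threshold (no adaptation), shorter refractory
#' period. Inhibitory neurons do not compete for input representations, so
#' they carry no homeostatic threshold.
#'
#' @inheritParams lif_params
#' @return An object of class `lif_params`.
#' @export
lif_params_inhibitory <- function(tau_mem = 10, v_rest = -65, v_reset = -45,
                                  theta_base = -40, theta_plus = 0,
                                  tau_theta = 1e7, t_refrac = 2,
                                  tau_syn_e = 2, tau_syn_i = 1) {
  lif_params(tau_mem = tau_mem, v_rest = v_rest, v_reset = v_reset,
             theta_base = theta_base, theta_plus = theta_plus,
             tau_theta = tau_theta, t_refrac = t_refrac,
             tau_syn_e = tau_syn_e, tau_syn_i = tau_syn_i)
}

#' Create a population state for LIF neurons
#'
#' Vectorized state over `n` neurons: membrane potential `v_mem`, adaptive
#' threshold offset `theta_adapt`, remaining refractory time
#' `refrac_remaining`, and the excitatory/inhibitory post-synaptic currents
#' `i_exc` / `i_inh`. Currents are stored as non-negative magnitudes;
#' inhibition enters the membrane update with a negative sign.
#'
#' @param n Number of neurons.
#' @param params A [lif_params()] object supplying the initial potential.
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(n, params) {
  stopifnot(n >= 1, inherits(params, "lif_params"))
  structure(
    list(v_mem = rep(params$v_rest, n),
         theta_adapt = numeric(n),
         refrac_remaining = numeric(n),
         i_exc = numeric(n),
         i_inh = numeric(n),
         n = as.integer(n)),
    class = "neuron_state"
  )
}

#' Exponentially decay a neuron state over one time interval
#'
#' Exact exponential-decay update: `v_mem` relaxes toward `v_rest` with
#' factor `exp(-dt/tau_mem)`, the synaptic currents decay with their own
#' time constants, `theta_adapt` decays with `tau_theta`, and the
#' refractory timer is decremented (floored at zero). Exact factors avoid
#' forward-Euler step-size artifacts.
#'
#' @param state A [neuron_state()].
#' @param params A [lif_params()].
#' @param dt Time interval (ms), strictly positive.
#' @return The decayed `neuron_state`.
#' @export
decay_state <- function(state, params, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  state$v_mem <- params$v_rest + (state$v_mem - params$v_rest) * exp(-dt / params$tau_mem)
  state$i_exc <- state$i_exc * exp(-dt / params$tau_syn_e)
  state$i_inh <- state$i_inh * exp(-dt / params$tau_syn_i)
  state$theta_adapt <- state$theta_adapt * exp(-dt / params$tau_theta)
  state$refrac_remaining <- pmax(state$refrac_remaining - dt, 0)
  state
}

#' Inject weighted spike input into the post-synaptic currents
#'
#' Adds the weight-modulated presynaptic spike contributions to the
#' excitatory and inhibitory post-synaptic currents. Contributions from
#' simultaneous pre-spikes sum linearly. Both arguments are magnitudes
#' (non-negative); the inhibitory current lowers the membrane potential
#' when integrated.
#'
#' @param state A [neuron_state()].
#' @param weighted_exc_input,weighted_inh_input Per-neuron non-negative
#'   summed synaptic drive (scalar or length-`n` vector).
#' @return Updated `neuron_state`.
#' @export
inject_spikes <- function(state, weighted_exc_input, weighted_inh_input = 0) {
  if (any(weighted_exc_input < 0) || any(weighted_inh_input < 0)) {
    stop("weighted synaptic inputs must be non-negative", call. = FALSE)
  }
  state$i_exc <- state$i_exc + weighted_exc_input
  state$i_inh <- state$i_inh + weighted_inh_input
  state
}

#' Integrate the post-synaptic currents into the membrane potential
#'
#' One-step membrane update: `v_mem` gains `i_exc - i_inh` (weights are in
#' units of membrane depolarization per step). Applied after [decay_state()]
#' in the per-step contract; see [present_pattern()] for the full ordering.
#'
#' @param state A [neuron_state()].
#' @return Updated `neuron_state`.
#' @export
integrate_currents <- function(state) {
  state$v_mem <- state$v_mem + state$i_exc - state$i_inh
  state
}

#' Threshold test, spike emission, reset and refractory onset
#'
#' A neuron spikes when it is out of its refractory period and its membrane
#' potential exceeds `theta_base + theta_adapt`. Spiking neurons are reset
#' to `v_reset`, their adaptive threshold is raised by `theta_plus`, and
#' their refractory timer restarts at `t_refrac`.
#'
#' @param state A [neuron_state()].
#' @param params A [lif_params()].
#' @return A list with `spiked` (logical vector) and `state` (updated
#'   `neuron_state`).
#' @export
fire_and_reset <- function(state, params) {
  spiked <- state$refrac_remaining == 0 &
    state$v_mem > (params$theta_base + state$theta_adapt)
  if (any(spiked)) {
    state$v_mem[spiked] <- params$v_reset
    state$theta_adapt[spiked] <- state$theta_adapt[spiked] + params$theta_plus
    state$refrac_remaining[spiked] <- params$t_refrac
  }
  list(spiked = spiked, state = state)
}
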