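#' Power-law weight-dependent STDP parameters
#'
#' The weight update applied to an input synapse when its post-synaptic
#' neuron fires is
#'
#' \deqn{\Delta w = \eta \, [e^{-(t_{post}-t_{pre})/\tau} - \mathrm{offset}]
#'       \, [w_{max} - w]^{\mu}}
#'
#' Potentiation occurs while the pre/post spike-time difference satisfies
#' `exp(-dt/tau) > stdp_offset`; larger differences depress the synapse.
#' The `[w_max - w]^mu` soft bound slows growth near the ceiling.
#'
#' Task defaults used in this package: speech-like `eta = 1e-4`,
#' `stdp_offset = 0` (weights never depressed); image-like `eta = 0.005`,
#' `stdp_offset = 0.4`. Both use `tau = 15` ms, `mu = 0.9`, bounds `[0, 1]`.
#'
#' @param eta Learning rate (> 0).
#' @param tau STDP time constant (ms).
#' @param stdp_offset Offset in `[0, 1)` controlling the potentiation window.
#' @param mu Weight-dependence exponent (>= 0).
#' @param w_max,w_min Hard weight bounds, `w_min < w_max`.
#' @return An object of class `stdp_params`.
#' @export
#' @examples
#' p <- stdp_params(eta = 0.005, stdp_offset = 0.4)
#' stdp_delta(0, 0.5, p)
#' potentiation_window(p)   # -tau * log(offset)
stdp_params <- function(eta = 0.005, tau = 15, stdp_offset = 0.4,
                        mu = 0.9, w_max = 1, w_min = 0) {
  stopifnot(
    eta > 0, tau > 0,
    stdp_offset >= 0, stdp_offset < 1,
    mu >= 0, w_min < w_max
  )
  structure(
    list(eta = eta, tau = tau, stdp_offset = stdp_offset,
         mu = mu, w_max = w_max, w_min = w_min),
    class = "stdp_params"
  )
}

#' STDP weight change for a pre/post spike pair
#'
#' Evaluates the power-law weight-dependent rule for a spike-time
#' difference `dt_spike = t_post - t_pre >= 0` and current weight `w`.
#' Vectorized over `dt_spike` and `w` (recycled to common length).
#'
#' @param dt_spike Spike-time difference(s) in ms, `>= 0`.
#' @param w Current weight(s), within `[w_min, w_max]`.
#' @param p An [stdp_params()] object.
#' @return Weight change(s) `dw` (not yet clipped to the bounds).
#' @export
stdp_delta <- function(dt_spike, w, p) {
  stopifnot(inherits(p, "stdp_params"))
  if (any(dt_spike < 0)) {
    stop("`dt_spike` (t_post - t_pre) must be non-negative", call. = FALSE)
  }
  if (any(w < p$w_min | w > p$w_max)) {
    stop("`w` outside [w_min, w_max]", call. = FALSE)
  }
  p$eta * (exp(-dt_spike / p$tau) - p$stdp_offset) * (p$w_max - w)^p$mu
}

#' Width of the potentiation window
#'
#' Spike-time difference at which the STDP rule changes sign:
#' `-tau * log(stdp_offset)`. With a zero offset the rule never depresses
#' and the window is infinite.
#'
#' @param p An [stdp_params()] object.
#' @return Window edge in ms (`Inf` when `stdp_offset == 0`).
#' @export
potentiation_window <- function(p) {
  stopifnot(inherits(p, "stdp_params"))
  if (p$stdp_offset == 0) return(Inf)
  -p$tau * log(p$stdp_offset)
}

#' Apply STDP to a neuron's input synapses at a post-spike instant
#'
#' For every input synapse with a recorded pre-spike, pairs the most recent
#' pre-spike with the post-spike at `t_post`, applies [stdp_delta()], and
#' clips the result to `[w_min, w_max]`. Synapses whose input has not yet
#' spiked in the current presentation are untouched (`NA` in
#' `last_pre_spike_times`).
#'
#' @param weights Weight vector for the input synapses of one neuron.
#' @param last_pre_spike_times Per-input time of the most recent pre-spike
#'   (ms), or `NA` for inputs that have not spiked.
#' @param t_post Time of the post-synaptic spike (ms); must not precede any
#'   recorded pre-spike.
#' @param p An [stdp_params()] object.
#' @return The updated weight vector.
#' @export
apply_post_spike <- function(weights, last_pre_spike_times, t_post, p) {
  stopifnot(inherits(p, "stdp_params"),
            length(weights) == length(last_pre_spike_times))
  seen <- !is.na(last_pre_spike_times)
  if (!any(seen)) return(weights)
  if (any(last_pre_spike_times[seen] > t_post)) {
    stop("`t_post` precedes a recorded pre-spike", call. = FALSE)
  }
  dw <- stdp_delta(t_post - last_pre_spike_times[seen], weights[seen], p)
  weights[seen] <- pmin(pmax(weights[seen] + dw, p$w_min), p$w_max)
  weights
}
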