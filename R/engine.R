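#' Runtime parameters for simulating a liquid
#'
#' Bundles the neuron and plasticity parameters with the presentation
#' timing. `duration` must be a positive multiple of `t_step`.
#'
#' @param lif_e [lif_params()] for the excitatory population.
#' @param lif_i [lif_params()] for the inhibitory population (fixed
#'   threshold by default).
#' @param stdp [stdp_params()] for the plastic input synapses.
#' @param duration Presentation interval (ms): 750 for speech-like, 350 for
#'   image-like inputs.
#' @param t_step Simulation time step (ms), default 0.5.
#' @param n_tags Number of class tags per excitatory neuron at inference
#'   (1 image-like, 2 speech-like).
#' @return An object of class `run_params`.
#' @export
run_params <- function(lif_e = lif_params(), lif_i = lif_params_inhibitory(),
                       stdp = stdp_params(), duration = 350, t_step = 0.5,
                       n_tags = 1) {
  stopifnot(inherits(lif_e, "lif_params"), inherits(lif_i, "lif_params"),
            inherits(stdp, "stdp_params"), t_step > 0,
            duration > 0, abs(duration / t_step - round(duration / t_step)) < 1e-9,
            n_tags >= 1)
  structure(
    list(lif_e = lif_e, lif_i = lif_i, stdp = stdp,
         duration = duration, t_step = t_step, n_tags = as.integer(n_tags)),
    class = "run_params"
  )
}

# Transposed (post x pre) weight matrices for fast spike routing.
prepare_routing <- function(topology) {
  list(
    wt_inp = t(topology$w_inp_e),
    wt_ee = t(topology$mask_ee) * topology$w_ee,
    wt_ei = t(topology$mask_ei) * topology$w_ei,
    wt_ie = t(topology$mask_ie) * topology$w_ie,
    wt_ii = t(topology$mask_ii) * topology$w_ii
  )
}

# Summed weights onto every post neuron from the spiking pre neurons.
route_spikes <- function(wt, idx) {
  if (length(idx) == 0L) return(0)
  if (length(idx) == 1L) wt[, idx] else rowSums(wt[, idx, drop = FALSE])
}

#' Simulate one pattern presentation through a liquid
#'
#' Clock-driven simulation of `duration / t_step` steps. Per-step contract:
#' spikes emitted at step `t - 1` (and the input raster column `t`) are
#' delivered into the post-synaptic currents, the state decays by `t_step`
#' ([decay_state()]), the currents are integrated into the membrane
#' potential ([integrate_currents()]), and the threshold test fires and
#' resets neurons ([fire_and_reset()]). Liquid spikes therefore propagate
#' with a one-step delay, which breaks same-step causality cycles in the
#' recurrent graph.
#'
#' In `train` mode the plastic input weights of every excitatory neuron
#' are updated at its post-spike instants by the STDP rule, pairing each
#' input synapse's most recent pre-spike in this presentation with the
#' post-spike ([apply_post_spike()] semantics, restricted to
#' mask-supported synapses). In `test` mode all weights and the adaptive
#' thresholds are frozen. Membrane potentials, synaptic currents,
#' refractory timers and the pre-spike cache start from rest; the
#' adaptive-threshold offsets are carried in and out via `theta_adapt`.
#'
#' The input raster is sampled from `enc` with the current RNG stream.
#'
#' @param topology A [build_liquid()] result.
#' @param enc An [encode_image()]/[encode_channels()] result whose input
#'   dimension matches `topology$cfg$n_inp`.
#' @param params A [run_params()] object.
#' @param mode `"test"` (frozen weights) or `"train"` (STDP active).
#' @param theta_adapt Optional length-`n_e` vector of adaptive-threshold
#'   offsets carried over from previous presentations.
#' @param record_times Also record per-neuron spike steps (slower).
#' @param raster Optional pre-sampled logical input raster
#'   (`n_inp` x `n_steps`) overriding the Bernoulli sampling.
#' @return A list: `record` (class `spike_record`: excitatory `spike_count`,
#'   inhibitory `spike_count_i`, optional `spike_steps`, `n_steps`,
#'   `t_step`, `duration`), `topology` (updated in train mode), and
#'   `theta_adapt`.
#' @export
present_pattern <- function(topology, enc, params, mode = c("test", "train"),
                            theta_adapt = NULL, record_times = FALSE,
                            raster = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(topology, "liquid_topology"),
            inherits(enc, "encoded_input"), inherits(params, "run_params"))
  cfg <- topology$cfg
  if (enc$n_inputs != cfg$n_inp) {
    stop("encoded input dimension (", enc$n_inputs,
         ") does not match topology n_inp (", cfg$n_inp, ")", call. = FALSE)
  }
  n_steps <- as.integer(round(params$duration / params$t_step))
  if (is.null(raster)) raster <- sample_spikes(enc)
  stopifnot(nrow(raster) == cfg$n_inp, ncol(raster) >= n_steps)

  lif_e <- params$lif_e
  lif_i <- params$lif_i
  if (mode == "test") {  # freeze homeostasis during inference
    lif_e$theta_plus <- 0
    lif_e$tau_theta <- Inf
  }
  p <- params$stdp
  dt <- params$t_step
  train <- mode == "train"

  rt <- prepare_routing(topology)
  w <- topology$w_inp_e
  mask_inp <- topology$mask_inp_e

  # Flat-vector state with precomputed decay factors: one step below is
  # inject_spikes -> decay_state -> integrate_currents -> fire_and_reset
  # on each population (equivalence pinned by the replay oracle tests).
  d_v_e <- exp(-dt / lif_e$tau_mem);  d_v_i <- exp(-dt / lif_i$tau_mem)
  d_se_e <- exp(-dt / lif_e$tau_syn_e); d_se_i <- exp(-dt / lif_i$tau_syn_e)
  d_si_e <- exp(-dt / lif_e$tau_syn_i); d_si_i <- exp(-dt / lif_i$tau_syn_i)
  d_th_e <- exp(-dt / lif_e$tau_theta); d_th_i <- exp(-dt / lif_i$tau_theta)

  v_e <- rep(lif_e$v_rest, cfg$n_e); v_i <- rep(lif_i$v_rest, cfg$n_i)
  ie_e <- numeric(cfg$n_e); ii_e <- numeric(cfg$n_e)
  ie_i <- numeric(cfg$n_i); ii_i <- numeric(cfg$n_i)
  th_e <- if (is.null(theta_adapt)) numeric(cfg$n_e) else theta_adapt
  stopifnot(length(th_e) == cfg$n_e)
  th_i <- numeric(cfg$n_i)
  rf_e <- numeric(cfg$n_e); rf_i <- numeric(cfg$n_i)

  count_e <- integer(cfg$n_e)
  count_i <- integer(cfg$n_i)
  steps_e <- if (record_times) vector("list", n_steps)
  last_pre <- rep(NA_real_, cfg$n_inp)
  prev_e <- integer(0)
  prev_i <- integer(0)

  for (t in seq_len(n_steps)) {
    inp_idx <- which(raster[, t])
    if (length(inp_idx)) last_pre[inp_idx] <- t * dt

    # deliver previous-step spikes into the synaptic currents
    ie_e <- ie_e + route_spikes(rt$wt_inp, inp_idx) + route_spikes(rt$wt_ee, prev_e)
    ii_e <- ii_e + route_spikes(rt$wt_ie, prev_i)
    ie_i <- ie_i + route_spikes(rt$wt_ei, prev_e)
    ii_i <- ii_i + route_spikes(rt$wt_ii, prev_i)

    # exact exponential decay
    v_e <- lif_e$v_rest + (v_e - lif_e$v_rest) * d_v_e
    v_i <- lif_i$v_rest + (v_i - lif_i$v_rest) * d_v_i
    ie_e <- ie_e * d_se_e; ii_e <- ii_e * d_si_e
    ie_i <- ie_i * d_se_i; ii_i <- ii_i * d_si_i
    th_e <- th_e * d_th_e; th_i <- th_i * d_th_i
    rf_e <- rf_e - dt; rf_e[rf_e < 0] <- 0
    rf_i <- rf_i - dt; rf_i[rf_i < 0] <- 0

    # integrate currents, threshold test, reset
    v_e <- v_e + ie_e - ii_e
    v_i <- v_i + ie_i - ii_i
    spk_e <- rf_e == 0 & v_e > (lif_e$theta_base + th_e)
    spk_i <- rf_i == 0 & v_i > (lif_i$theta_base + th_i)
    prev_e <- which(spk_e)
    prev_i <- which(spk_i)
    if (length(prev_e)) {
      v_e[prev_e] <- lif_e$v_reset
      th_e[prev_e] <- th_e[prev_e] + lif_e$theta_plus
      rf_e[prev_e] <- lif_e$t_refrac
    }
    if (length(prev_i)) {
      v_i[prev_i] <- lif_i$v_reset
      th_i[prev_i] <- th_i[prev_i] + lif_i$theta_plus
      rf_i[prev_i] <- lif_i$t_refrac
    }
    if (length(prev_e)) {
      count_e[prev_e] <- count_e[prev_e] + 1L
      if (record_times) steps_e[[t]] <- prev_e
      if (train) {
        seen <- which(!is.na(last_pre))
        if (length(seen)) {
          f_dt <- p$eta * (exp(-(t * dt - last_pre[seen]) / p$tau) - p$stdp_offset)
          wb <- w[seen, prev_e, drop = FALSE]
          mb <- mask_inp[seen, prev_e, drop = FALSE]
          upd <- pmin(pmax(wb + f_dt * (p$w_max - wb)^p$mu, p$w_min), p$w_max)
          wb[mb] <- upd[mb]
          w[seen, prev_e] <- wb
          rt$wt_inp[prev_e, seen] <- t(wb)
        }
      }
    }
    if (length(prev_i)) count_i[prev_i] <- count_i[prev_i] + 1L
  }

  if (train) topology$w_inp_e <- w
  record <- structure(
    list(spike_count = count_e, spike_count_i = count_i,
         spike_steps = if (record_times) invert_step_list(steps_e, cfg$n_e),
         n_steps = n_steps, t_step = dt, duration = params$duration),
    class = "spike_record"
  )
  list(record = record, topology = topology, theta_adapt = th_e)
}

# per-step spiker lists -> per-neuron sorted step vectors
invert_step_list <- function(steps, n) {
  out <- rep(list(integer(0)), n)
  for (t in seq_along(steps)) {
    for (k in steps[[t]]) out[[k]] <- c(out[[k]], t)
  }
  out
}

#' Training schedule
#'
#' Presentations cycle through the base dataset in order until
#' `n_examples` presentations have been made (the unique samples are
#' replicated as needed).
#'
#' @param n_examples Total number of training presentations (>= 1).
#' @param seed RNG seed for the input-spike sampling during training
#'   (NULL: use current RNG stream).
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(n_examples, seed = NULL) {
  stopifnot(n_examples >= 1)
  structure(list(n_examples = as.integer(n_examples), seed = seed),
            class = "training_schedule")
}

#' Train one liquid with STDP and accumulate tagging statistics
#'
#' Presents `schedule$n_examples` patterns (cycling through the dataset),
#' updating the plastic input weights at excitatory post-spike instants.
#' Labels are used only to accumulate, per excitatory neuron and per true
#' class, the total training spike count — the raw material for
#' [tag_neurons()]; they never enter the weight update (unsupervised
#' contract). Adaptive thresholds persist across presentations; membrane
#' state resets between presentations.
#'
#' @param topology A [build_liquid()] result.
#' @param encoded List of `encoded_input`, the unique training samples.
#' @param labels Integer class labels (1-based) parallel to `encoded`.
#' @param schedule A [training_schedule()].
#' @param params A [run_params()].
#' @param n_classes Number of classes (default `max(labels)`).
#' @param log_every If > 0, record mean rate / mean plastic weight every
#'   this many presentations into the returned `log` data frame.
#' @return A list of class `trained_liquid`: `topology` (trained),
#'   `class_counts` (`n_e` x `n_classes` cumulative training spikes),
#'   `theta_adapt`, `schedule`, `params`, `log`.
#' @export
train_liquid <- function(topology, encoded, labels, schedule, params,
                         n_classes = max(labels), log_every = 0) {
  stopifnot(length(encoded) >= 1, length(encoded) == length(labels),
            inherits(schedule, "training_schedule"),
            inherits(params, "run_params"))
  labels <- as.integer(labels)
  stopifnot(all(labels >= 1), n_classes >= max(labels))
  n_e <- topology$cfg$n_e
  class_counts <- matrix(0, n_e, n_classes)
  theta <- NULL
  logs <- list()
  with_seed(schedule$seed, {
    for (pres in seq_len(schedule$n_examples)) {
      k <- (pres - 1L) %% length(encoded) + 1L
      out <- present_pattern(topology, encoded[[k]], params, mode = "train",
                             theta_adapt = theta)
      topology <- out$topology
      theta <- out$theta_adapt
      class_counts[, labels[k]] <- class_counts[, labels[k]] + out$record$spike_count
      if (log_every > 0 && pres %% log_every == 0) {
        logs[[length(logs) + 1L]] <- data.frame(
          presentation = pres,
          mean_rate_hz = mean(out$record$spike_count) / params$duration * 1000,
          mean_weight = mean(topology$w_inp_e[topology$mask_inp_e])
        )
      }
    }
  })
  structure(
    list(topology = topology, class_counts = class_counts,
         theta_adapt = theta, schedule = schedule, params = params,
         log = if (length(logs)) do.call(rbind, logs) else NULL),
    class = "trained_liquid"
  )
}

#' Collect test-phase spike counts for a list of patterns
#'
#' Presents each encoded pattern once in test mode (weights and adaptive
#' thresholds frozen) and returns the excitatory spike counts.
#'
#' @param topology A (trained) [build_liquid()] result.
#' @param encoded List of `encoded_input`.
#' @param params A [run_params()].
#' @param theta_adapt Adaptive-threshold offsets from training.
#' @param seed Optional seed for the input-spike sampling.
#' @return Matrix of spike counts, `length(encoded)` x `n_e`.
#' @export
collect_spike_counts <- function(topology, encoded, params,
                                 theta_adapt = NULL, seed = NULL) {
  n_e <- topology$cfg$n_e
  counts <- matrix(0L, length(encoded), n_e)
  with_seed(seed, {
    for (s in seq_along(encoded)) {
      out <- present_pattern(topology, encoded[[s]], params, mode = "test",
                             theta_adapt = theta_adapt)
      counts[s, ] <- out$record$spike_count
    }
  })
  counts
}
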