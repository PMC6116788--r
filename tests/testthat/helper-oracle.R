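# Independent scalar oracle: hand-stepped replay of the documented
# per-step contract (deliver previous-step spikes -> exact exponential
# decay -> integrate currents -> threshold/reset), written with explicit
# per-neuron / per-synapse loops and no code shared with the engine.
oracle_present <- function(topology, raster, params, mode = "test",
                           theta_adapt = NULL) {
  cfg <- topology$cfg
  le <- params$lif_e
  li <- params$lif_i
  sp <- params$stdp
  dt <- params$t_step
  n_steps <- round(params$duration / dt)
  if (mode == "test") {
    le$theta_plus <- 0
    le$tau_theta <- Inf
  }
  w <- topology$w_inp_e

  v_e <- rep(le$v_rest, cfg$n_e); th_e <- theta_adapt
  if (is.null(th_e)) th_e <- rep(0, cfg$n_e)
  rf_e <- rep(0, cfg$n_e); iexc_e <- rep(0, cfg$n_e); iinh_e <- rep(0, cfg$n_e)
  v_i <- rep(li$v_rest, cfg$n_i); th_i <- rep(0, cfg$n_i)
  rf_i <- rep(0, cfg$n_i); iexc_i <- rep(0, cfg$n_i); iinh_i <- rep(0, cfg$n_i)

  last_pre <- rep(NA_real_, cfg$n_inp)
  prev_e <- rep(FALSE, cfg$n_e); prev_i <- rep(FALSE, cfg$n_i)
  count_e <- rep(0L, cfg$n_e); count_i <- rep(0L, cfg$n_i)
  steps_e <- rep(list(integer(0)), cfg$n_e)

  for (t in seq_len(n_steps)) {
    for (n in seq_len(cfg$n_inp)) if (raster[n, t]) last_pre[n] <- t * dt
    # deliver
    for (j in seq_len(cfg$n_e)) {
      drive <- 0
      for (n in seq_len(cfg$n_inp)) {
        if (raster[n, t] && topology$mask_inp_e[n, j]) drive <- drive + w[n, j]
      }
      for (k in seq_len(cfg$n_e)) {
        if (prev_e[k] && topology$mask_ee[k, j]) drive <- drive + topology$w_ee
      }
      iexc_e[j] <- iexc_e[j] + drive
      inh <- 0
      for (k in seq_len(cfg$n_i)) {
        if (prev_i[k] && topology$mask_ie[k, j]) inh <- inh + topology$w_ie
      }
      iinh_e[j] <- iinh_e[j] + inh
    }
    for (j in seq_len(cfg$n_i)) {
      drive <- 0
      for (k in seq_len(cfg$n_e)) {
        if (prev_e[k] && topology$mask_ei[k, j]) drive <- drive + topology$w_ei
      }
      iexc_i[j] <- iexc_i[j] + drive
      inh <- 0
      for (k in seq_len(cfg$n_i)) {
        if (prev_i[k] && topology$mask_ii[k, j]) inh <- inh + topology$w_ii
      }
      iinh_i[j] <- iinh_i[j] + inh
    }
    # decay
    v_e <- le$v_rest + (v_e - le$v_rest) * exp(-dt / le$tau_mem)
    iexc_e <- iexc_e * exp(-dt / le$tau_syn_e)
    iinh_e <- iinh_e * exp(-dt / le$tau_syn_i)
    th_e <- th_e * exp(-dt / le$tau_theta)
    rf_e <- pmax(rf_e - dt, 0)
    v_i <- li$v_rest + (v_i - li$v_rest) * exp(-dt / li$tau_mem)
    iexc_i <- iexc_i * exp(-dt / li$tau_syn_e)
    iinh_i <- iinh_i * exp(-dt / li$tau_syn_i)
    th_i <- th_i * exp(-dt / li$tau_theta)
    rf_i <- pmax(rf_i - dt, 0)
    # integrate + fire
    v_e <- v_e + iexc_e - iinh_e
    v_i <- v_i + iexc_i - iinh_i
    spike_e <- rf_e == 0 & v_e > le$theta_base + th_e
    spike_i <- rf_i == 0 & v_i > li$theta_base + th_i
    for (j in which(spike_e)) {
      v_e[j] <- le$v_reset
      th_e[j] <- th_e[j] + le$theta_plus
      rf_e[j] <- le$t_refrac
      count_e[j] <- count_e[j] + 1L
      steps_e[[j]] <- c(steps_e[[j]], t)
      if (mode == "train") {
        for (n in seq_len(cfg$n_inp)) {
          if (topology$mask_inp_e[n, j] && !is.na(last_pre[n])) {
            dw <- sp$eta * (exp(-(t * dt - last_pre[n]) / sp$tau) - sp$stdp_offset) *
              (sp$w_max - w[n, j])^sp$mu
            w[n, j] <- min(max(w[n, j] + dw, sp$w_min), sp$w_max)
          }
        }
      }
    }
    for (j in which(spike_i)) {
      v_i[j] <- li$v_reset
      th_i[j] <- th_i[j] + li$theta_plus
      rf_i[j] <- li$t_refrac
      count_i[j] <- count_i[j] + 1L
    }
    prev_e <- spike_e
    prev_i <- spike_i
  }
  list(w = w, count_e = count_e, count_i = count_i, theta = th_e,
       steps_e = steps_e)
}

# tiny liquid used by several engine tests
tiny_topology <- function(seed = 5, n_inp = 4, n_e = 2, n_i = 1,
                          p = 100) {
  build_liquid(liquid_config(n_inp, n_e, n_i,
                             p_inp_e = p, p_ee = p, p_ei = p, p_ie = p, p_ii = p,
                             w_init_min = 0.05, w_init_max = 0.4, seed = seed))
}

fast_params <- function(duration = 20, n_tags = 1, stdp = stdp_params()) {
  run_params(duration = duration, n_tags = n_tags, stdp = stdp)
}
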