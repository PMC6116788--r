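test_that("an unstimulated liquid stays silent", {
  topo <- tiny_topology(seed = 1)
  enc <- encode_image(rep(0, 4), duration = 50)
  set.seed(1)
  out <- present_pattern(topo, enc, fast_params(50), mode = "test")
  expect_equal(sum(out$record$spike_count), 0)
  expect_equal(sum(out$record$spike_count_i), 0)
})

test_that("test mode is deterministic given the seed and freezes weights", {
  topo <- tiny_topology(seed = 2)
  enc <- encode_image(rep(200, 4), duration = 50)
  params <- fast_params(50)
  set.seed(11); a <- present_pattern(topo, enc, params, mode = "test")
  set.seed(11); b <- present_pattern(topo, enc, params, mode = "test")
  expect_identical(a$record$spike_count, b$record$spike_count)
  expect_identical(a$topology$w_inp_e, topo$w_inp_e)
  expect_identical(a$theta_adapt, numeric(topo$cfg$n_e))  # frozen at zero
})

test_that("input dimension mismatch is rejected", {
  topo <- tiny_topology(seed = 2)
  enc <- encode_image(rep(0, 5), duration = 10)
  expect_error(present_pattern(topo, enc, fast_params(10)), "does not match")
})

test_that("a strongly driven neuron fires at the refractory-limited rate", {
  # single input firing every step onto one excitatory neuron, weight far
  # above threshold: the output settles into a t_refrac-spaced spike train
  cfg <- liquid_config(1, 1, 1, p_inp_e = 100, p_ee = 0, p_ei = 0, p_ie = 0,
                       p_ii = 0, w_init_min = 19.999, w_init_max = 20, seed = 1)
  topo <- build_liquid(cfg)
  params <- fast_params(10)  # 20 steps
  raster <- matrix(TRUE, 1, 20)
  enc <- encode_image(255, duration = 10)
  out <- present_pattern(topo, enc, params, mode = "test", record_times = TRUE,
                         raster = raster)
  # independent scalar replay of the same 20 steps
  oracle <- oracle_present(topo, raster, params, mode = "test")
  expect_equal(out$record$spike_count, oracle$count_e)
  expect_equal(out$record$spike_steps[[1]], oracle$steps_e[[1]])
  spikes <- out$record$spike_steps[[1]]
  expect_gt(length(spikes), 1)
  expect_true(all(diff(spikes) >= params$lif_e$t_refrac / params$t_step))
})

test_that("engine training replays exactly against the scalar oracle", {
  # tiny net (4 inputs, 2 excitatory, 1 inhibitory), 2 patterns, 10
  # presentations: final weights must equal the hand-stepped replay
  topo0 <- tiny_topology(seed = 5)
  params <- fast_params(20)
  encs <- list(encode_image(c(255, 255, 0, 0), duration = 20),
               encode_image(c(0, 0, 255, 255), duration = 20))
  set.seed(33)
  rasters <- lapply(1:10, function(k) sample_spikes(encs[[(k - 1) %% 2 + 1]]))

  topo <- topo0
  theta <- NULL
  for (k in 1:10) {
    out <- present_pattern(topo, encs[[(k - 1) %% 2 + 1]], params,
                           mode = "train", theta_adapt = theta,
                           raster = rasters[[k]])
    topo <- out$topology
    theta <- out$theta_adapt
  }

  w_ref <- topo0$w_inp_e
  topo_ref <- topo0
  theta_ref <- NULL
  for (k in 1:10) {
    o <- oracle_present(topo_ref, rasters[[k]], params, mode = "train",
                        theta_adapt = theta_ref)
    topo_ref$w_inp_e <- o$w
    theta_ref <- o$theta
  }
  expect_equal(topo$w_inp_e, topo_ref$w_inp_e, tolerance = 1e-12)
  expect_equal(theta, theta_ref, tolerance = 1e-12)
})

test_that("training updates only the input synapses and ignores labels", {
  ds <- make_image_classes(synthetic_spec(2, c(6, 6), 0.1, 4, seed = 12))
  cfg <- liquid_config(36, 10, 3, p_inp_e = 60, seed = 6)
  params <- fast_params(30)
  enc <- encode_dataset(ds, params)
  topo <- build_liquid(cfg)
  sched <- training_schedule(12, seed = 17)

  fitA <- train_liquid(topo, enc, ds$labels, sched, params)
  # recurrent structure frozen
  expect_identical(fitA$topology$mask_ee, topo$mask_ee)
  expect_identical(fitA$topology$w_ee, topo$w_ee)
  expect_identical(fitA$topology$mask_inp_e, topo$mask_inp_e)
  # unsupervised contract: permuting labels changes only the bookkeeping
  fitB <- train_liquid(topo, enc, rev(ds$labels), sched, params)
  expect_identical(fitA$topology$w_inp_e, fitB$topology$w_inp_e)
  expect_false(identical(fitA$class_counts, fitB$class_counts) &&
                 sum(fitA$class_counts) > 0)
  # class-count bookkeeping sums all excitatory training spikes
  expect_identical(dim(fitA$class_counts), c(10L, 2L))
  # weights with a recorded pre-spike never exceed the bounds
  expect_true(all(fitA$topology$w_inp_e >= 0 & fitA$topology$w_inp_e <= 1))
})

test_that("full training runs are bit-reproducible from the seeds", {
  ds <- make_image_classes(synthetic_spec(2, c(6, 6), 0.1, 3, seed = 19))
  cfg <- liquid_config(36, 8, 2, p_inp_e = 50, seed = 3)
  params <- fast_params(20)
  enc <- encode_dataset(ds, params)
  run <- function() {
    train_liquid(build_liquid(cfg), enc, ds$labels,
                 training_schedule(9, seed = 55), params)
  }
  a <- run(); b <- run()
  expect_identical(a$topology$w_inp_e, b$topology$w_inp_e)
  expect_identical(a$class_counts, b$class_counts)
  expect_identical(a$theta_adapt, b$theta_adapt)
})

test_that("speech-parameter training never depresses a weight", {
  speech <- stdp_params(eta = 1e-4, tau = 15, stdp_offset = 0, mu = 0.9)
  ds <- make_temporal_classes(synthetic_spec(2, c(10, 20), 0.1, 3, seed = 20))
  params <- run_params(stdp = speech, duration = 50, n_tags = 2)
  cfg <- liquid_config(10, 12, 4, p_inp_e = 50,
                       w_init_min = 0.005, w_init_max = 0.505, seed = 4)
  topo <- build_liquid(cfg)
  enc <- encode_dataset(ds, params)
  fit <- train_liquid(topo, enc, ds$labels, training_schedule(12, seed = 2),
                      params)
  expect_true(all(fit$topology$w_inp_e >= topo$w_inp_e))
  expect_gt(sum(fit$topology$w_inp_e - topo$w_inp_e), 0)
})

test_that("liquid activity stays below the runaway bound on synthetic input", {
  ds <- make_image_classes(synthetic_spec(4, c(8, 8), 0.1, 4, seed = 28))
  cfg <- liquid_config(64, 80, 20, seed = 14)  # image-row percentages
  params <- run_params(duration = 100)
  enc <- encode_dataset(ds, params)
  fit <- train_liquid(build_liquid(cfg), enc, ds$labels,
                      training_schedule(16, seed = 9), params)
  # mean excitatory rate: total spikes / (neurons * presentations * duration)
  total_spikes <- sum(fit$class_counts)
  rate_hz <- total_spikes / (cfg$n_e * 16 * params$duration / 1000)
  expect_lt(rate_hz, 200)
})
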