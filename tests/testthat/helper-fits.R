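# Shared training runs for the end-to-end classification checks: a
# 400-neuron single liquid and a two-liquid ensemble (200 neurons per
# liquid) on the 4-class synthetic glyph set, 2,000 presentations each.
# Trained lazily once and reused across test blocks.
fit_cache <- new.env(parent = emptyenv())

acceptance_fits <- function() {
  if (!is.null(fit_cache$done)) return(as.list(fit_cache))
  params <- run_params()  # image-task defaults: 350 ms, 0.5 ms, n_tags 1
  train_ds <- make_image_classes(synthetic_spec(4, c(12, 12), 0.1, 25, seed = 42))
  test_ds <- make_image_classes(synthetic_spec(4, c(12, 12), 0.1, 10, seed = 43))
  sched <- training_schedule(2000, seed = 11)

  single_cfg <- liquid_config(144, 320, 80, seed = 7)  # image row, 4:1
  fit_single <- train_spilinc(train_ds, single_cfg, sched, params)

  parts <- partition_input(c(12, 12), "vertical-halves", 2, overlap = 4)
  ens_cfgs <- lapply(1:2, function(i) {
    liquid_config(length(parts[[i]]), 160, 40, p_inp_e = 50, seed = 7 + i)
  })
  fit_ens <- train_spilinc(train_ds, ensemble_config(parts, ens_cfgs),
                           sched, params)

  fit_cache$params <- params
  fit_cache$train_ds <- train_ds
  fit_cache$test_ds <- test_ds
  fit_cache$single <- fit_single
  fit_cache$ensemble <- fit_ens
  fit_cache$done <- TRUE
  as.list(fit_cache)
}
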