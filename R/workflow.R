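#' Encode every sample of a dataset for one liquid
#'
#' Images are flattened row-major, restricted to `partition` (indices into
#' the flattened input) and rate-coded with [encode_image()]. Channel
#' envelopes are restricted to the partition's channels and encoded with
#' [encode_channels()], the frame axis stretched over the presentation
#' interval (`frame_dt = duration / n_frames`).
#'
#' @param dataset A `spilinc_dataset` (see [make_image_classes()],
#'   [make_temporal_classes()], [read_dataset_csv()]).
#' @param params A [run_params()] supplying `duration` and `t_step`.
#' @param partition Optional integer index vector (default: whole input).
#' @return List of `encoded_input`, parallel to `dataset$x`.
#' @export
encode_dataset <- function(dataset, params, partition = NULL) {
  stopifnot(inherits(dataset, "spilinc_dataset"), inherits(params, "run_params"))
  if (dataset$kind == "image") {
    lapply(dataset$x, function(m) {
      v <- as.vector(t(m))
      if (!is.null(partition)) v <- v[partition]
      encode_image(v, duration = params$duration, t_step = params$t_step)
    })
  } else {
    n_fr <- dataset$shape[2]
    frame_dt <- params$duration / n_fr
    lapply(dataset$x, function(m) {
      if (!is.null(partition)) m <- m[partition, , drop = FALSE]
      encode_channels(m, frame_dt = frame_dt, duration = params$duration,
                      t_step = params$t_step)
    })
  }
}

#' Train a Liquid-SNN or SpiLinC model on a labeled dataset
#'
#' Builds the liquid(s) from the configuration, trains the plastic input
#' synapses with STDP over `schedule$n_examples` cyclic presentations, and
#' tags the excitatory neurons from the accumulated per-class training
#' spike counts. For an [ensemble_config()], each liquid is trained
#' independently on its input partition (liquid `i` uses schedule seed
#' `seed + i - 1` so the ensembles draw distinct spike realizations).
#'
#' @param dataset A labeled `spilinc_dataset`.
#' @param config A [liquid_config()] (single liquid) or
#'   [ensemble_config()].
#' @param schedule A [training_schedule()].
#' @param params A [run_params()].
#' @return An object of class `spilinc_fit`: `liquids` (list of
#'   [train_liquid()] results), `tags` (list of [tag_neurons()] results),
#'   `partitions`, `params`, `n_classes`.
#' @export
train_spilinc <- function(dataset, config, schedule, params) {
  stopifnot(inherits(dataset, "spilinc_dataset"),
            inherits(schedule, "training_schedule"),
            inherits(params, "run_params"))
  n_classes <- max(dataset$labels)
  if (inherits(config, "liquid_config")) {
    partitions <- if (dataset$kind == "image") list(seq_len(prod(dataset$shape)))
                  else list(seq_len(dataset$shape[1]))
    configs <- list(config)
  } else if (inherits(config, "ensemble_config")) {
    partitions <- config$partitions
    configs <- config$configs
  } else {
    stop("`config` must be a liquid_config or ensemble_config", call. = FALSE)
  }
  liquids <- vector("list", length(configs))
  tags <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    topo <- build_liquid(configs[[i]])
    enc <- encode_dataset(dataset, params, partitions[[i]])
    sched_i <- schedule
    if (!is.null(schedule$seed)) sched_i$seed <- schedule$seed + i - 1L
    liquids[[i]] <- train_liquid(topo, enc, dataset$labels, sched_i, params,
                                 n_classes = n_classes)
    tags[[i]] <- tag_neurons(liquids[[i]]$class_counts, params$n_tags)
  }
  structure(
    list(liquids = liquids, tags = tags, partitions = partitions,
         params = params, n_classes = n_classes),
    class = "spilinc_fit"
  )
}

#' Predict classes for a test dataset with a trained model
#'
#' Presents each test sample to every liquid in test mode (weights and
#' adaptive thresholds frozen), forms per-class average spike counts per
#' liquid and combines them with [predict_ensemble()] (which reduces to
#' the single-liquid rule for one liquid).
#'
#' @param object A [train_spilinc()] fit.
#' @param dataset Test `spilinc_dataset`.
#' @param seed Optional RNG seed for the test-phase spike sampling
#'   (liquid `i` uses `seed + i - 1`).
#' @param ... Unused.
#' @return A list of class `spilinc_prediction`: `predictions` data frame
#'   (`actual`, `predicted`), `res_avg` (samples x classes resultant
#'   average spike counts), `metrics` (from [confusion_and_rates()]).
#' @export
predict.spilinc_fit <- function(object, dataset, seed = NULL, ...) {
  stopifnot(inherits(dataset, "spilinc_dataset"))
  n_liquids <- length(object$liquids)
  n_samples <- length(dataset$x)
  per_liquid_avg <- vector("list", n_liquids)
  for (i in seq_len(n_liquids)) {
    enc <- encode_dataset(dataset, object$params, object$partitions[[i]])
    counts <- collect_spike_counts(
      object$liquids[[i]]$topology, enc, object$params,
      theta_adapt = object$liquids[[i]]$theta_adapt,
      seed = if (is.null(seed)) NULL else seed + i - 1L
    )
    per_liquid_avg[[i]] <- t(apply(counts, 1, average_spike_count,
                                   tags = object$tags[[i]]))
  }
  predicted <- integer(n_samples)
  res_avg <- matrix(0, n_samples, object$n_classes)
  for (s in seq_len(n_samples)) {
    pr <- predict_ensemble(lapply(per_liquid_avg, function(a) a[s, ]))
    predicted[s] <- pr$predicted_class
    res_avg[s, ] <- pr$res_avg_spike_count
  }
  metrics <- confusion_and_rates(dataset$labels, predicted, object$n_classes)
  structure(
    list(predictions = data.frame(actual = dataset$labels,
                                  predicted = predicted),
         res_avg = res_avg, metrics = metrics),
    class = "spilinc_prediction"
  )
}
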