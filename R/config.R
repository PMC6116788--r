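#' Load a run configuration from YAML
#'
#' The flat schema mirrors the shipped preset files (see
#' `system.file("presets", package = "spilinc")`): task, presentation
#' timing, `lif_e`/`lif_i`/`stdp` parameter blocks, `connectivity`
#' percentages and excitatory:inhibitory ratio, `weights` initialization
#' bounds and recurrent constants, `liquid` sizing (total neurons,
#' ensemble size, partition scheme and overlap), `synthetic` dataset
#' defaults, `train$n_examples`, and a `seed`. Every field of a preset may
#' be overridden (see [apply_overrides()]).
#'
#' @param path YAML file path.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg A `run_config` (or plain list with the same schema).
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Load a shipped task preset
#'
#' @param task `"image"` or `"speech"`.
#' @return A `run_config`.
#' @export
run_preset <- function(task = c("image", "speech")) {
  task <- match.arg(task)
  read_run_config(system.file("presets", paste0(task, ".yaml"),
                              package = "spilinc", mustWork = TRUE))
}

validate_run_config <- function(cfg) {
  need <- c("task", "duration", "t_step", "n_tags", "lif_e", "lif_i", "stdp",
            "connectivity", "weights", "liquid", "synthetic", "train", "seed")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("run config is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  config_params(cfg)  # constructor validation of lif/stdp/timing
  stopifnot(cfg$connectivity$ei_ratio > 0, cfg$liquid$n_total >= 2,
            cfg$liquid$n_liquids >= 1, cfg$train$n_examples >= 1)
  structure(cfg, class = "run_config")
}

#' Extract the simulator runtime parameters from a run config
#'
#' @param cfg A `run_config`.
#' @return A [run_params()] object.
#' @export
config_params <- function(cfg) {
  run_params(
    lif_e = do.call(lif_params, cfg$lif_e),
    lif_i = do.call(lif_params, cfg$lif_i),
    stdp = do.call(stdp_params, cfg$stdp),
    duration = cfg$duration, t_step = cfg$t_step, n_tags = cfg$n_tags
  )
}

#' Derive the liquid (or ensemble) configuration from a run config
#'
#' Splits `liquid$n_total` neurons per liquid into excitatory and
#' inhibitory counts by the configured e:i ratio, picks the single-liquid
#' or ensemble input connectivity percentage, and for `n_liquids > 1`
#' partitions the configured synthetic input shape with the configured
#' scheme and overlap. Liquid `i` of an ensemble is seeded with
#' `seed + 100 + i`.
#'
#' @param cfg A `run_config`.
#' @param input_shape Input shape (default: the config's synthetic shape;
#'   for channel data the partitionable dimension is the channel count).
#' @return A [liquid_config()] when `n_liquids == 1`, otherwise an
#'   [ensemble_config()].
#' @export
config_topology <- function(cfg, input_shape = NULL) {
  if (is.null(input_shape)) input_shape <- unlist(cfg$synthetic$shape)
  n_liquids <- cfg$liquid$n_liquids
  r <- cfg$connectivity$ei_ratio
  n_total <- cfg$liquid$n_total
  n_e <- round(n_total * r / (r + 1))
  n_i <- n_total - n_e
  part_shape <- if (cfg$task == "image") input_shape else input_shape[1]
  p_inp <- if (n_liquids == 1) cfg$connectivity$p_inp_e_single
           else cfg$connectivity$p_inp_e_ensemble
  make_cfg <- function(n_inp, seed) {
    liquid_config(
      n_inp = n_inp, n_e = n_e, n_i = n_i,
      p_inp_e = p_inp, p_ee = cfg$connectivity$p_ee,
      p_ei = cfg$connectivity$p_ei, p_ie = cfg$connectivity$p_ie,
      p_ii = cfg$connectivity$p_ii,
      w_init_min = cfg$weights$w_init_min, w_init_max = cfg$weights$w_init_max,
      w_ee = cfg$weights$w_ee, w_ei = cfg$weights$w_ei,
      w_ie = cfg$weights$w_ie, w_ii = cfg$weights$w_ii,
      seed = seed
    )
  }
  if (n_liquids == 1) {
    return(make_cfg(prod(part_shape), if (is.null(cfg$seed)) NULL else cfg$seed + 101L))
  }
  scheme <- if (cfg$task == "image") cfg$liquid$scheme else "channel-blocks"
  parts <- partition_input(part_shape, scheme, n_liquids, cfg$liquid$overlap)
  configs <- lapply(seq_len(n_liquids), function(i) {
    make_cfg(length(parts[[i]]),
             if (is.null(cfg$seed)) NULL else cfg$seed + 100L + i)
  })
  ensemble_config(parts, configs)
}

#' Apply dotted-key overrides to a run config
#'
#' Overrides are given as `"key.subkey=value"` strings (values parsed as
#' YAML, so numbers and booleans work). Unknown keys raise an error naming
#' the key.
#'
#' @param cfg A `run_config`.
#' @param overrides Character vector of `key=value` strings.
#' @return The updated, revalidated `run_config`.
#' @export
apply_overrides <- function(cfg, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad override (expect key=value): ", ov, call. = FALSE)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    value <- yaml::yaml.load(kv[2])
    node <- cfg
    for (k in keys[-length(keys)]) {
      if (is.null(node[[k]])) stop("unknown config key: ", kv[1], call. = FALSE)
      node <- node[[k]]
    }
    if (!utils::tail(keys, 1) %in% names(node)) {
      stop("unknown config key: ", kv[1], call. = FALSE)
    }
    cfg[[keys]] <- value
  }
  validate_run_config(cfg)
}
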