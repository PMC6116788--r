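#' Map a pixel intensity to an average Poisson firing rate
#'
#' Intensities in `[0, 255]` map linearly onto `[0, 63.75]` spikes/s, i.e.
#' `rate = intensity / 4`. Vectorized.
#'
#' @param pixel Intensity value(s) in `[0, 255]`.
#' @return Firing rate(s) in spikes per second.
#' @export
#' @examples
#' intensity_to_rate(255)  # 63.75
intensity_to_rate <- function(pixel) {
  if (any(pixel < 0 | pixel > 255)) {
    stop("pixel intensity outside [0, 255]", call. = FALSE)
  }
  pixel * (63.75 / 255)
}

#' Convert an average firing rate to a per-time-step firing probability
#'
#' `p = rate / 1000 * t_step` with `t_step` in ms; at most one spike can be
#' emitted per step, so the probability must not exceed 1.
#'
#' @param rate Firing rate(s) in spikes/s (>= 0).
#' @param t_step Simulation time step in ms (default 0.5).
#' @return Firing probability per time step.
#' @export
#' @examples
#' rate_to_probability(63.75)  # 0.031875
rate_to_probability <- function(rate, t_step = 0.5) {
  if (any(rate < 0)) stop("rate must be non-negative", call. = FALSE)
  p <- rate / 1000 * t_step
  if (any(p > 1)) {
    stop("rate too high for the time step (probability > 1)", call. = FALSE)
  }
  p
}

#' Normalize a channel-by-time intensity matrix to firing probabilities
#'
#' Divides every entry by the global maximum intensity of the sample, so
#' the result lies in `[0, 1]` and is used directly as the per-time-step
#' firing probability of the corresponding input neuron. An all-zero
#' matrix maps to all-zero (no division). Idempotent.
#'
#' @param intensity Non-negative channel x time matrix.
#' @return Probability matrix of the same shape.
#' @export
normalize_channels <- function(intensity) {
  if (length(intensity) == 0) stop("empty intensity matrix", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  m <- max(intensity)
  if (m == 0) return(intensity)
  intensity / m
}

#' Encode an image as a rate-coded input
#'
#' Pixel intensities map to constant per-step Poisson firing probabilities
#' for the whole presentation (static rate coding). The image is flattened
#' row-major, matching [partition_input()].
#'
#' @param image Numeric matrix (height x width) or vector of intensities in
#'   `[0, 255]`.
#' @param duration Presentation interval in ms (default 350).
#' @param t_step Simulation time step in ms (default 0.5).
#' @return An object of class `encoded_input` with fields `firing_prob`
#'   (length n_inputs vector), `n_steps`, `duration`, `t_step`,
#'   `time_varying = FALSE`.
#' @export
encode_image <- function(image, duration = 350, t_step = 0.5) {
  x <- if (is.matrix(image)) as.vector(t(image)) else as.vector(image)
  p <- rate_to_probability(intensity_to_rate(x), t_step)
  new_encoded_input(p, duration, t_step, time_varying = FALSE)
}

#' Encode a channel-by-time intensity envelope as a time-varying input
#'
#' Normalizes the envelope with [normalize_channels()] (unless
#' `normalize = FALSE`, for matrices that are already probabilities) and
#' resamples the frame axis to the simulation grid by zero-order hold:
#' frame `k` covers simulation time `[(k-1)*frame_dt, k*frame_dt)`. If
#' `duration` exceeds the envelope, the tail is padded with zeros;
#' if shorter, the envelope is truncated.
#'
#' @param intensity Non-negative channel x frame matrix.
#' @param frame_dt Frame duration in ms.
#' @param duration Presentation interval in ms (default: whole envelope).
#' @param t_step Simulation time step in ms (default 0.5).
#' @param normalize Apply [normalize_channels()] first (default TRUE).
#' @return An `encoded_input` with `firing_prob` a channel x step matrix
#'   and `time_varying = TRUE`.
#' @export
encode_channels <- function(intensity, frame_dt = 5,
                            duration = NULL, t_step = 0.5, normalize = TRUE) {
  stopifnot(is.matrix(intensity), frame_dt > 0)
  p <- if (normalize) normalize_channels(intensity) else intensity
  if (any(p < 0 | p > 1)) stop("probabilities outside [0, 1]", call. = FALSE)
  if (is.null(duration)) duration <- ncol(p) * frame_dt
  n_steps <- duration / t_step
  if (n_steps != round(n_steps) || n_steps < 1) {
    stop("`duration` must be a positive multiple of `t_step`", call. = FALSE)
  }
  n_steps <- as.integer(round(n_steps))
  frame_of <- pmin(floor((seq_len(n_steps) - 1L) * t_step / frame_dt) + 1L,
                   .Machine$integer.max)
  grid <- matrix(0, nrow(p), n_steps)
  live <- frame_of <= ncol(p)
  grid[, live] <- p[, frame_of[live], drop = FALSE]
  new_encoded_input(grid, duration, t_step, time_varying = TRUE)
}

new_encoded_input <- function(firing_prob, duration, t_step, time_varying) {
  n_steps <- duration / t_step
  if (n_steps != round(n_steps) || n_steps < 1) {
    stop("`duration` must be a positive multiple of `t_step`", call. = FALSE)
  }
  if (any(firing_prob < 0 | firing_prob > 1)) {
    stop("firing probabilities outside [0, 1]", call. = FALSE)
  }
  structure(
    list(firing_prob = firing_prob,
         n_inputs = if (is.matrix(firing_prob)) nrow(firing_prob)
                    else length(firing_prob),
         n_steps = as.integer(round(n_steps)),
         duration = duration, t_step = t_step,
         time_varying = time_varying),
    class = "encoded_input"
  )
}

#' Sample a Bernoulli spike raster from an encoded input
#'
#' Independent Bernoulli draw per input neuron per time step: a spike is
#' emitted when a uniform(0, 1) draw falls below the firing probability.
#' Uses the current RNG stream (seed with `set.seed()` for reproducible
#' rasters).
#'
#' @param enc An `encoded_input` from [encode_image()] or
#'   [encode_channels()].
#' @return Logical raster matrix, `n_inputs` x `n_steps`.
#' @export
sample_spikes <- function(enc) {
  stopifnot(inherits(enc, "encoded_input"))
  u <- matrix(stats::runif(enc$n_inputs * enc$n_steps), enc$n_inputs, enc$n_steps)
  u < enc$firing_prob  # vector prob recycles down columns; matrix matches exactly
}

#' Write / read a spike raster as a (neuron, step) event list
#'
#' @param raster Logical matrix (neurons x steps).
#' @param path CSV path.
#' @return `write_raster_csv` returns `path` invisibly; `read_raster_csv`
#'   returns the logical raster (requires `n_inputs`/`n_steps`).
#' @export
write_raster_csv <- function(raster, path) {
  ev <- which(raster, arr.ind = TRUE)
  df <- data.frame(neuron = ev[, 1], step = ev[, 2])
  df <- df[order(df$step, df$neuron), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @param n_inputs,n_steps Raster dimensions.
#' @export
read_raster_csv <- function(path, n_inputs, n_steps) {
  df <- utils::read.csv(path)
  r <- matrix(FALSE, n_inputs, n_steps)
  if (nrow(df)) r[cbind(df$neuron, df$step)] <- TRUE
  r
}

#' Read images or labels from an IDX-format file
#'
#' Minimal reader for the big-endian IDX container used to distribute
#' handwritten-digit corpora: magic bytes `0 0 <type> <ndim>` (only
#' unsigned-byte data, type 0x08, is supported), `ndim` big-endian
#' 32-bit dimension sizes, then the raw bytes in row-major order.
#'
#' @param path IDX file (optionally gzip-compressed; `gzfile()` handles
#'   both).
#' @param n_max Read at most this many items (default all).
#' @return For 3-d files, a list of `rows x cols` integer matrices in
#'   `[0, 255]`; for 1-d files, an integer vector of labels.
#' @export
read_idx <- function(path, n_max = Inf) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 4, size = 1, signed = FALSE)
  if (magic[1] != 0 || magic[2] != 0 || magic[3] != 8) {
    stop("not an unsigned-byte IDX file: ", path, call. = FALSE)
  }
  ndim <- magic[4]
  dims <- readBin(con, "integer", ndim, size = 4, endian = "big")
  n <- min(dims[1], n_max)
  if (ndim == 1) {
    return(readBin(con, "integer", n, size = 1, signed = FALSE))
  }
  per <- prod(dims[-1])
  lapply(seq_len(n), function(i) {
    matrix(readBin(con, "integer", per, size = 1, signed = FALSE),
           dims[2], dims[3], byrow = TRUE)
  })
}
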