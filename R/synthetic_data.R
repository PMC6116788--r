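#' Specification of a synthetic labeled dataset
#'
#' Desk-scale stand-ins for the two input modalities the simulator
#' consumes: grayscale glyph images (intensities in `[0, 255]`) and
#' non-negative channel-by-time intensity envelopes. Templates are
#' deterministic functions of the class index and input shape so that
#' tests can reference them; only the noise is random.
#'
#' @param n_classes Number of classes (2–8).
#' @param input_shape `c(height, width)` for images, or
#'   `c(n_channels, n_frames)` for temporal envelopes.
#' @param noise_level For images: per-pixel flip probability in `[0, 1]`.
#'   For envelopes: multiplicative intensity noise fraction and temporal
#'   jitter scale.
#' @param samples_per_class Samples generated per class.
#' @param seed RNG seed (NULL: current stream).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 4, input_shape = c(12, 12),
                           noise_level = 0.1, samples_per_class = 25,
                           seed = NULL) {
  stopifnot(n_classes >= 2, noise_level >= 0, noise_level <= 1,
            samples_per_class >= 1, length(input_shape) == 2,
            all(input_shape >= 4))
  structure(
    list(n_classes = as.integer(n_classes),
         input_shape = as.integer(input_shape),
         noise_level = noise_level,
         samples_per_class = as.integer(samples_per_class),
         seed = seed),
    class = "synthetic_spec"
  )
}

#' Deterministic binary class templates for glyph images
#'
#' Up to 8 oriented-bar templates on an `h x w` grid: center horizontal
#' bar, center vertical bar, main diagonal, anti-diagonal, top bar,
#' bottom bar, left bar, right bar. Pairwise active-pixel overlap is
#' below 50% of the smaller template, so a nearest-template classifier
#' separates them easily.
#'
#' @param n_classes Number of templates (<= 8).
#' @param shape `c(height, width)`.
#' @return List of logical `h x w` matrices.
#' @export
image_templates <- function(n_classes, shape) {
  h <- shape[1]; w <- shape[2]
  if (n_classes > 8) {
    stop("at most 8 distinct image templates are available", call. = FALSE)
  }
  center_band <- function(extent) {
    half <- max(1L, floor(extent / 6))
    mid <- ceiling(extent / 2)
    seq.int(max(1L, mid - half + 1L), min(extent, mid + half))
  }
  edge <- function(extent) max(1L, ceiling(extent / 4))
  r <- row(matrix(0, h, w)); c_ <- col(matrix(0, h, w))
  makers <- list(
    function() r %in% center_band(h),                              # horizontal bar
    function() c_ %in% center_band(w),                             # vertical bar
    function() abs((r - 1) / (h - 1) - (c_ - 1) / (w - 1)) <= 0.12,      # diagonal
    function() abs((r - 1) / (h - 1) + (c_ - 1) / (w - 1) - 1) <= 0.12,  # anti-diag
    function() r <= edge(h),                                       # top bar
    function() r > h - edge(h),                                    # bottom bar
    function() c_ <= edge(w),                                      # left bar
    function() c_ > w - edge(w)                                    # right bar
  )
  lapply(makers[seq_len(n_classes)], function(f) {
    m <- f()
    dim(m) <- c(h, w)
    m
  })
}

#' Generate a labeled synthetic image dataset
#'
#' Each sample is its class template at intensity 255 on background 0 with
#' a `noise_level` fraction of pixels flipped independently (salt-and-
#' pepper corruption of the binary glyph).
#'
#' @param spec A [synthetic_spec()] with `input_shape = c(height, width)`.
#' @return A list of class `spilinc_dataset`: `x` (list of `h x w`
#'   intensity matrices), `labels` (integer), `kind = "image"`, `shape`.
#' @export
make_image_classes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  templates <- image_templates(spec$n_classes, spec$input_shape)
  with_seed(spec$seed, {
    x <- list(); labels <- integer(0)
    for (cls in seq_len(spec$n_classes)) {
      for (s in seq_len(spec$samples_per_class)) {
        flip <- matrix(stats::runif(prod(spec$input_shape)) < spec$noise_level,
                       spec$input_shape[1], spec$input_shape[2])
        img <- xor(templates[[cls]], flip) * 255
        x[[length(x) + 1L]] <- img
        labels <- c(labels, cls)
      }
    }
    structure(list(x = x, labels = labels, kind = "image",
                   shape = spec$input_shape, spec = spec),
              class = "spilinc_dataset")
  })
}

#' Deterministic channel-trajectory templates for temporal envelopes
#'
#' Up to 6 channel x frame trajectories: rising sweep across all
#' channels, steady low band, steady high band, pulsed center band,
#' V sweep (high-low-high), and a band alternating between low and high.
#' The active channel at each frame carries a Gaussian intensity bump
#' (sd of one channel). Time-summed channel profiles are pairwise
#' distinct (the sweeps spread energy over all channels, the bands
#' concentrate it at different positions or duty cycles).
#'
#' @param n_classes Number of templates (<= 6).
#' @param shape `c(n_channels, n_frames)`.
#' @return List of non-negative `channels x frames` matrices.
#' @export
temporal_templates <- function(n_classes, shape) {
  n_ch <- shape[1]; n_fr <- shape[2]
  if (n_classes > 6) {
    stop("at most 6 distinct temporal templates are available", call. = FALSE)
  }
  ch <- seq_len(n_ch)
  frames <- seq_len(n_fr)
  bump <- function(center) exp(-(ch - center)^2 / 2)  # sd = 1 channel
  traj <- list(
    function(f) 1 + (n_ch - 1) * (f - 1) / (n_fr - 1),               # rising
    function(f) n_ch / 4,                                            # low band
    function(f) 3 * n_ch / 4,                                        # high band
    function(f) if (f %% 10 < 5) n_ch / 2 else NA,                   # pulsed center
    function(f) n_ch - (n_ch - 1) * abs(2 * (f - 1) / (n_fr - 1) - 1),  # V sweep
    function(f) if (f %% 20 < 10) n_ch / 5 else 4 * n_ch / 5         # alternating
  )
  lapply(traj[seq_len(n_classes)], function(g) {
    m <- matrix(0, n_ch, n_fr)
    for (f in frames) {
      center <- g(f)
      if (!is.na(center)) m[, f] <- bump(center)
    }
    m
  })
}

#' Generate a labeled synthetic temporal (channel x time) dataset
#'
#' Samples perturb their class trajectory with multiplicative intensity
#' noise (`1 + noise_level * N(0,1)`, clipped at 0) and a small temporal
#' jitter: a circular frame shift drawn uniformly from
#' `+/- round(3 * noise_level / 0.1)` frames.
#'
#' @param spec A [synthetic_spec()] with
#'   `input_shape = c(n_channels, n_frames)`.
#' @return A `spilinc_dataset` with `kind = "channels"`.
#' @export
make_temporal_classes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  templates <- temporal_templates(spec$n_classes, spec$input_shape)
  jitter_max <- round(3 * spec$noise_level / 0.1)
  n_fr <- spec$input_shape[2]
  with_seed(spec$seed, {
    x <- list(); labels <- integer(0)
    for (cls in seq_len(spec$n_classes)) {
      for (s in seq_len(spec$samples_per_class)) {
        m <- templates[[cls]]
        if (jitter_max > 0) {
          shift <- sample.int(2 * jitter_max + 1, 1) - jitter_max - 1
          if (shift != 0) {
            ord <- ((seq_len(n_fr) - 1 - shift) %% n_fr) + 1
            m <- m[, ord, drop = FALSE]
          }
        }
        noise <- 1 + spec$noise_level * stats::rnorm(length(m))
        m <- pmax(m * noise, 0)
        dim(m) <- spec$input_shape
        x[[length(x) + 1L]] <- m
        labels <- c(labels, cls)
      }
    }
    structure(list(x = x, labels = labels, kind = "channels",
                   shape = spec$input_shape, spec = spec),
              class = "spilinc_dataset")
  })
}

#' Nearest-template classification of a synthetic dataset
#'
#' Sanity bound on learnability: assigns each sample to the class whose
#' template minimizes the Euclidean distance (images: binary template
#' scaled to 255; envelopes: raw trajectory). Noiseless samples classify
#' perfectly by construction.
#'
#' @param dataset A `spilinc_dataset`.
#' @return Accuracy in percent.
#' @export
nearest_template_accuracy <- function(dataset) {
  stopifnot(inherits(dataset, "spilinc_dataset"))
  n_classes <- max(dataset$labels)
  templates <- if (dataset$kind == "image") {
    lapply(image_templates(n_classes, dataset$shape), function(t) t * 255)
  } else {
    temporal_templates(n_classes, dataset$shape)
  }
  pred <- vapply(dataset$x, function(m) {
    which.min(vapply(templates, function(t) sum((m - t)^2), 0))
  }, 0L)
  mean(pred == dataset$labels) * 100
}

#' Write / read a dataset as CSV (one row per sample, wide layout)
#'
#' Samples are flattened row-major into columns `v1..vK` with a `label`
#' column; the shape and kind are echoed in a `<path>.meta.yaml` sidecar.
#'
#' @param dataset A `spilinc_dataset`.
#' @param path CSV path.
#' @return `write_dataset_csv` returns `path` invisibly;
#'   `read_dataset_csv` returns the `spilinc_dataset`.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "spilinc_dataset"))
  flat <- t(vapply(dataset$x, function(m) as.vector(t(m)),
                   numeric(prod(dataset$shape))))
  df <- data.frame(label = dataset$labels, flat)
  names(df) <- c("label", paste0("v", seq_len(ncol(flat))))
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(kind = dataset$kind, shape = as.integer(dataset$shape)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  df <- utils::read.csv(path)
  shape <- as.integer(meta$shape)
  x <- lapply(seq_len(nrow(df)), function(i) {
    matrix(as.numeric(df[i, -1]), shape[1], shape[2], byrow = TRUE)
  })
  structure(list(x = x, labels = as.integer(df$label), kind = meta$kind,
                 shape = shape, spec = NULL),
            class = "spilinc_dataset")
}
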