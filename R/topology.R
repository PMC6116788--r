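#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration of one liquid
#'
#' Holds the sizes, percentage connectivities and weight-initialization
#' bounds needed to generate one sparse random liquid. Connectivity is
#' expressed in percent (0–100); generation is Bernoulli with probability
#' `percent/100` per potential synapse. Plastic input weights are drawn
#' uniformly from `[w_init_min, w_init_max]`; recurrent weights are fixed
#' scalar constants applied through the generated masks.
#'
#' Task presets (see [run_preset()]): speech-like liquids use a 3:1
#' excitatory:inhibitory ratio, percentages (25, 0.5, 5, 20, 0.5), input
#' weights in `[0.005, 0.505]` and `w_ei = 3`; image-like liquids use 4:1,
#' (30 or 50, 1, 5, 30, 1), `[0.003, 0.303]` and `w_ei = 10`.
#'
#' @param n_inp,n_e,n_i Input, excitatory and inhibitory neuron counts.
#' @param p_inp_e,p_ee,p_ei,p_ie,p_ii Connection percentages in `[0, 100]`
#'   for input->excitatory and the four recurrent blocks (rows of the
#'   block name are presynaptic).
#' @param w_init_min,w_init_max Uniform bounds for plastic input weights.
#' @param w_ee,w_ei,w_ie,w_ii Fixed recurrent weight constants.
#' @param seed RNG seed used by [build_liquid()] (NULL: use current RNG).
#' @return An object of class `liquid_config`.
#' @export
liquid_config <- function(n_inp, n_e, n_i,
                          p_inp_e = 30, p_ee = 1, p_ei = 5, p_ie = 30, p_ii = 1,
                          w_init_min = 0.003, w_init_max = 0.303,
                          w_ee = 1, w_ei = 10, w_ie = 1, w_ii = 1,
                          seed = NULL) {
  pcts <- c(p_inp_e, p_ee, p_ei, p_ie, p_ii)
  stopifnot(
    n_inp >= 1, n_e >= 1, n_i >= 1,
    all(pcts >= 0), all(pcts <= 100),
    w_init_min < w_init_max
  )
  structure(
    list(n_inp = as.integer(n_inp), n_e = as.integer(n_e), n_i = as.integer(n_i),
         p_inp_e = p_inp_e, p_ee = p_ee, p_ei = p_ei, p_ie = p_ie, p_ii = p_ii,
         w_init_min = w_init_min, w_init_max = w_init_max,
         w_ee = w_ee, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii,
         seed = seed),
    class = "liquid_config"
  )
}

#' Bernoulli connectivity mask between two neuron groups
#'
#' Fills an `n_pre` x `n_post` matrix with uniform(0, 1) draws and keeps a
#' connection wherever the draw is below `percent/100`. Rows index
#' presynaptic neurons, columns postsynaptic. Uses the current RNG stream.
#'
#' @param n_pre,n_post Group sizes.
#' @param percent Connection percentage in `[0, 100]`.
#' @return A logical `n_pre` x `n_post` matrix.
#' @export
build_mask <- function(n_pre, n_post, percent) {
  if (percent < 0 || percent > 100) {
    stop("`percent` must lie in [0, 100]", call. = FALSE)
  }
  matrix(stats::runif(n_pre * n_post) < percent / 100, n_pre, n_post)
}

#' Initialize plastic input weights on a connectivity mask
#'
#' Uniform draws on `[w_init_min, w_init_max]` where the mask is true, zero
#' elsewhere. Uses the current RNG stream.
#'
#' @param mask Logical connectivity matrix (rows = pre, cols = post).
#' @param w_init_min,w_init_max Uniform bounds, `w_init_min < w_init_max`.
#' @return A numeric weight matrix of the same shape.
#' @export
init_input_weights <- function(mask, w_init_min, w_init_max) {
  stopifnot(is.logical(mask), w_init_min < w_init_max)
  w <- matrix(0, nrow(mask), ncol(mask))
  k <- sum(mask)
  if (k > 0) w[mask] <- stats::runif(k, w_init_min, w_init_max)
  w
}

#' Generate a liquid topology from its configuration
#'
#' Draws the five Bernoulli connectivity masks (input->e plastic; e->e,
#' e->i, i->e, i->i fixed) and initializes the plastic input weight matrix.
#' With a non-NULL `cfg$seed` the construction is reproducible and leaves
#' the caller's RNG stream untouched.
#'
#' @param cfg A [liquid_config()].
#' @return An object of class `liquid_topology`: logical masks `mask_inp_e`,
#'   `mask_ee`, `mask_ei`, `mask_ie`, `mask_ii`; plastic weight matrix
#'   `w_inp_e`; the fixed recurrent scalars; and the config echo `cfg`.
#' @export
build_liquid <- function(cfg) {
  stopifnot(inherits(cfg, "liquid_config"))
  with_seed(cfg$seed, {
    mask_inp_e <- build_mask(cfg$n_inp, cfg$n_e, cfg$p_inp_e)
    mask_ee <- build_mask(cfg$n_e, cfg$n_e, cfg$p_ee)
    mask_ei <- build_mask(cfg$n_e, cfg$n_i, cfg$p_ei)
    mask_ie <- build_mask(cfg$n_i, cfg$n_e, cfg$p_ie)
    mask_ii <- build_mask(cfg$n_i, cfg$n_i, cfg$p_ii)
    w_inp_e <- init_input_weights(mask_inp_e, cfg$w_init_min, cfg$w_init_max)
    structure(
      list(mask_inp_e = mask_inp_e, mask_ee = mask_ee, mask_ei = mask_ei,
           mask_ie = mask_ie, mask_ii = mask_ii,
           w_inp_e = w_inp_e,
           w_ee = cfg$w_ee, w_ei = cfg$w_ei, w_ie = cfg$w_ie, w_ii = cfg$w_ii,
           cfg = cfg),
      class = "liquid_topology"
    )
  })
}

#' Expected synapse count of a liquid network
#'
#' Closed-form expectation of the Bernoulli generation scheme:
#' \deqn{\#syn = \frac{p_{inp-e}}{100} n_{inp} n_e + \frac{p_{ee}}{100} n_e^2
#'  + \frac{p_{ei}}{100} n_e n_i + \frac{p_{ie}}{100} n_i n_e
#'  + \frac{p_{ii}}{100} n_i^2}
#' For an ensemble the per-liquid count is multiplied by `n_liquids`
#' (liquids share no synapses). The value may be fractional; realized
#' networks report their actual mask counts via [realized_synapse_count()].
#'
#' @param cfg A [liquid_config()].
#' @param n_liquids Number of identical liquids (default 1).
#' @return Expected synapse count (numeric).
#' @export
#' @examples
#' img <- liquid_config(784, 10240, 2560, p_inp_e = 30)
#' count_synapses(img)  # 12,697,600
count_synapses <- function(cfg, n_liquids = 1) {
  stopifnot(inherits(cfg, "liquid_config"), n_liquids >= 1)
  per <- cfg$p_inp_e / 100 * cfg$n_inp * cfg$n_e +
    cfg$p_ee / 100 * cfg$n_e^2 +
    cfg$p_ei / 100 * cfg$n_e * cfg$n_i +
    cfg$p_ie / 100 * cfg$n_i * cfg$n_e +
    cfg$p_ii / 100 * cfg$n_i^2
  per * n_liquids
}

#' Realized synapse count of a generated topology
#'
#' Sum of true entries over the five generated masks (one liquid).
#'
#' @param topology A [build_liquid()] result.
#' @return Integer synapse count.
#' @export
realized_synapse_count <- function(topology) {
  stopifnot(inherits(topology, "liquid_topology"))
  sum(topology$mask_inp_e) + sum(topology$mask_ee) + sum(topology$mask_ei) +
    sum(topology$mask_ie) + sum(topology$mask_ii)
}

#' Expected number of connected inputs per liquid in an ensemble
#'
#' \deqn{\frac{p_{inp-e}}{100}\left(\frac{dim}{n_{liquids}} + n_{overlap}\right)}
#' With one liquid and no overlap this reduces to the single-liquid case.
#'
#' @param p_inp_e Input->excitatory connection percentage.
#' @param input_dimension Total input dimension.
#' @param n_liquids Ensemble size (>= 1).
#' @param n_overlap Number of inputs shared across neighbouring partitions.
#' @return Expected connected inputs per liquid (may be fractional).
#' @export
inputs_per_liquid <- function(p_inp_e, input_dimension, n_liquids, n_overlap = 0) {
  stopifnot(n_liquids >= 1)
  p_inp_e / 100 * (input_dimension / n_liquids + n_overlap)
}

#' Partition an input across the liquids of an ensemble
#'
#' Images (`shape = c(height, width)`, flattened row-major so pixel
#' `(r, c)` maps to index `(r-1)*width + c`):
#' * `vertical-halves`, 2 liquids: left and right halves of width
#'   `width/2 + overlap/2` (default column overlap 4, mirroring 28x28 ->
#'   two 28x16 segments);
#' * `horizontal-halves`, 2 liquids: top and bottom halves, same overlap
#'   rule on rows;
#' * `vertical-halves`, 4 liquids: both vertical halves plus both
#'   horizontal halves.
#'
#' Channel inputs (`shape = n_channels`, scheme `channel-blocks`): blocks
#' of `dim/n + overlap*(n-1)/n` consecutive channels with `overlap` shared
#' channels between neighbours (39 channels, 2 blocks, overlap 21 -> blocks
#' 1–30 and 10–39). With `n_liquids = 1` the single partition is the whole
#' input under any scheme.
#'
#' @param shape `c(height, width)` for images or a channel count.
#' @param scheme One of `"vertical-halves"`, `"horizontal-halves"`,
#'   `"channel-blocks"`.
#' @param n_liquids Ensemble size.
#' @param overlap Shared columns/rows (images) or channels (blocks).
#' @return A list of integer index vectors, one per liquid, indexing the
#'   flattened input; attribute `shape` echoes the input shape.
#' @export
partition_input <- function(shape,
                            scheme = c("vertical-halves", "horizontal-halves",
                                       "channel-blocks"),
                            n_liquids = 2, overlap = NULL) {
  scheme <- match.arg(scheme)
  dim_total <- prod(shape)
  if (n_liquids == 1) {
    parts <- list(seq_len(dim_total))
    attr(parts, "shape") <- shape
    return(parts)
  }
  if (scheme == "channel-blocks") {
    stopifnot(length(shape) == 1)
    if (is.null(overlap)) overlap <- 0
    s <- (dim_total + overlap * (n_liquids - 1)) / n_liquids
    if (s != round(s)) {
      stop("block size (dim + overlap*(n-1))/n is not an integer", call. = FALSE)
    }
    if (s > dim_total) stop("segment larger than input", call. = FALSE)
    step <- s - overlap
    parts <- lapply(seq_len(n_liquids) - 1L, function(i) {
      seq.int(i * step + 1L, i * step + s)
    })
  } else {
    stopifnot(length(shape) == 2)
    if (is.null(overlap)) overlap <- 4
    h <- shape[1]; w <- shape[2]
    half <- function(extent) {
      s <- extent / 2 + overlap / 2
      if (s != round(s)) {
        stop("half extent/2 + overlap/2 is not an integer", call. = FALSE)
      }
      if (s > extent) stop("segment larger than input", call. = FALSE)
      s
    }
    idx <- function(rows, cols) {
      sort(as.integer(outer((rows - 1L) * w, cols, `+`)))  # row-major flatten
    }
    vert <- function() {
      s <- half(w)
      list(idx(seq_len(h), seq_len(s)), idx(seq_len(h), seq.int(w - s + 1L, w)))
    }
    horiz <- function() {
      s <- half(h)
      list(idx(seq_len(s), seq_len(w)), idx(seq.int(h - s + 1L, h), seq_len(w)))
    }
    parts <- switch(scheme,
      "vertical-halves" = if (n_liquids == 2) vert()
                          else if (n_liquids == 4) c(vert(), horiz())
                          else stop("vertical-halves supports 2 or 4 liquids",
                                    call. = FALSE),
      "horizontal-halves" = {
        if (n_liquids != 2) stop("horizontal-halves supports 2 liquids",
                                 call. = FALSE)
        horiz()
      })
  }
  attr(parts, "shape") <- shape
  parts
}

#' Count effective (unpruned) input synapses
#'
#' STDP drives the weights of uninformative input synapses (e.g. those from
#' background pixels) toward zero. A synapse counts as effective when it is
#' mask-supported and its weight exceeds `epsilon` (default `0.01 * w_max`
#' taken from the weight matrix maximum bound of 1 when unspecified).
#'
#' @param w_inp_e Plastic weight matrix (zeros off-mask).
#' @param epsilon Pruning threshold (>= 0).
#' @param mask Optional logical mask restricting the count to supported
#'   synapses; defaults to `w_inp_e != 0`'s support being implicit, i.e.
#'   every entry is examined.
#' @return Number of weights strictly greater than `epsilon`.
#' @export
effective_synapse_count <- function(w_inp_e, epsilon = 0.01, mask = NULL) {
  stopifnot(epsilon >= 0)
  if (inherits(w_inp_e, "liquid_topology")) {
    mask <- w_inp_e$mask_inp_e
    w_inp_e <- w_inp_e$w_inp_e
  }
  if (is.null(mask)) mask <- TRUE
  sum(w_inp_e > epsilon & mask)
}

#' Configure an ensemble of liquids (SpiLinC)
#'
#' Couples an input partition with one [liquid_config()] per liquid. Each
#' liquid sees only its own input segment; no synapses cross liquids.
#'
#' @param partitions Result of [partition_input()] (or any list of index
#'   vectors whose union covers the input).
#' @param configs List of [liquid_config()], one per partition, with
#'   `n_inp` equal to the partition length.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(partitions, configs) {
  stopifnot(length(partitions) == length(configs), length(partitions) >= 1)
  for (i in seq_along(partitions)) {
    stopifnot(inherits(configs[[i]], "liquid_config"),
              length(partitions[[i]]) >= 1,
              configs[[i]]$n_inp == length(partitions[[i]]))
  }
  structure(
    list(n_liquids = length(partitions), partitions = partitions,
         configs = configs),
    class = "ensemble_config"
  )
}

#' Generate all liquids of an ensemble
#'
#' @param ecfg An [ensemble_config()].
#' @return An object of class `liquid_ensemble`: `topologies` (list of
#'   [build_liquid()] results) and the partition/config echo.
#' @export
build_ensemble <- function(ecfg) {
  stopifnot(inherits(ecfg, "ensemble_config"))
  structure(
    list(topologies = lapply(ecfg$configs, build_liquid),
         partitions = ecfg$partitions, ecfg = ecfg),
    class = "liquid_ensemble"
  )
}
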