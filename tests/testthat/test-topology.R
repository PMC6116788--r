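test_that("mask generation hits the Bernoulli expectation", {
  set.seed(1)
  expect_equal(build_mask(10, 10, 0), matrix(FALSE, 10, 10))
  expect_equal(build_mask(10, 10, 100), matrix(TRUE, 10, 10))
  expect_error(build_mask(10, 10, 101), "\\[0, 100\\]")

  # 100 x 100 at 1%: mean count over seeds near 100, within 4 binomial SD
  counts <- vapply(1:20, function(s) {
    set.seed(s)
    sum(build_mask(100, 100, 1))
  }, 0)
  n <- 100 * 100
  p <- 0.01
  se <- sqrt(n * p * (1 - p) / 20)
  expect_lt(abs(mean(counts) - n * p), 4 * se)
})

test_that("plastic weights are uniform on the mask support, zero elsewhere", {
  set.seed(2)
  mask <- build_mask(30, 40, 50)
  w <- init_input_weights(mask, 0.005, 0.505)  # speech-row bounds
  expect_true(all(w[mask] >= 0.005 & w[mask] <= 0.505))
  expect_true(all(w[!mask] == 0))
  expect_equal(init_input_weights(matrix(FALSE, 5, 5), 0, 1), matrix(0, 5, 5))
  wd <- init_input_weights(matrix(TRUE, 3, 3), 0.1, 0.1 + 1e-12)
  expect_equal(as.vector(wd), rep(0.1, 9), tolerance = 1e-10)
})

test_that("expected synapse counts reproduce the published architectures", {
  img <- liquid_config(784, 10240, 2560, p_inp_e = 30, p_ee = 1, p_ei = 5,
                       p_ie = 30, p_ii = 1)
  expect_equal(count_synapses(img), 12697600)

  ens <- liquid_config(448, 2560, 640, p_inp_e = 50, p_ee = 1, p_ei = 5,
                       p_ie = 30, p_ii = 1)
  expect_equal(count_synapses(ens), 1216512)
  expect_equal(count_synapses(ens, n_liquids = 4), 4866048)

  zero <- liquid_config(10, 10, 10, p_inp_e = 0, p_ee = 0, p_ei = 0,
                        p_ie = 0, p_ii = 0)
  expect_equal(count_synapses(zero), 0)
})

test_that("expected count is the mean of realized mask counts", {
  cfg <- liquid_config(20, 30, 10, p_inp_e = 40, p_ee = 5, p_ei = 10,
                       p_ie = 30, p_ii = 5)
  realized <- vapply(1:30, function(s) {
    cfg$seed <- s
    realized_synapse_count(build_liquid(cfg))
  }, 0)
  mu <- count_synapses(cfg)
  # conservative binomial bound: total draws at the largest percentage
  se <- sqrt(mu) / sqrt(30) * 2
  expect_lt(abs(mean(realized) - mu), 4 * se)
})

test_that("same seed gives bit-identical topology", {
  cfg <- liquid_config(15, 20, 5, seed = 77)
  a <- build_liquid(cfg)
  b <- build_liquid(cfg)
  expect_identical(a$w_inp_e, b$w_inp_e)
  expect_identical(a$mask_ee, b$mask_ee)
  expect_identical(a$mask_ii, b$mask_ii)
  # and does not disturb the caller's RNG stream
  set.seed(5); x1 <- runif(1)
  set.seed(5); invisible(build_liquid(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("ensemble sizing follows the inputs-per-liquid rule", {
  expect_equal(inputs_per_liquid(30, 784, 1, 0), 0.3 * 784)
  expect_equal(inputs_per_liquid(50, 784, 4, 252), 224)  # 28x16 segments
  expect_equal(inputs_per_liquid(25, 39, 2, 10.5), 7.5)  # 30-channel blocks
})

test_that("input partitions match the published segment geometry", {
  # 28x28, 2 vertical halves -> columns 1..16 and 13..28, 448 pixels each
  parts <- partition_input(c(28, 28), "vertical-halves", 2)
  expect_length(parts, 2)
  expect_length(parts[[1]], 448)
  expect_length(parts[[2]], 448)
  cols <- function(idx, w) sort(unique((idx - 1) %% w + 1))
  expect_equal(cols(parts[[1]], 28), 1:16)
  expect_equal(cols(parts[[2]], 28), 13:28)
  expect_length(intersect(parts[[1]], parts[[2]]), 28 * 4)  # 4-column overlap

  # 4 liquids: the vertical pair plus the horizontal pair
  parts4 <- partition_input(c(28, 28), "vertical-halves", 4)
  expect_length(parts4, 4)
  expect_true(all(vapply(parts4, length, 0L) == 448))
  expect_equal(sort(unique(unlist(parts4))), 1:784)  # union covers the input

  # 39 channels in two blocks of 30 -> overlap of 21 channels
  blocks <- partition_input(39, "channel-blocks", 2, overlap = 21)
  expect_equal(blocks[[1]], 1:30)
  expect_equal(blocks[[2]], 10:39)
  expect_length(intersect(blocks[[1]], blocks[[2]]), 21)

  # single liquid: whole input
  whole <- partition_input(c(12, 12), "vertical-halves", 1)
  expect_equal(whole[[1]], 1:144)

  expect_error(partition_input(10, "channel-blocks", 2, overlap = 15),
               "not an integer|larger")
})

test_that("effective synapse accounting counts unpruned weights", {
  set.seed(4)
  mask <- build_mask(20, 20, 50)
  w <- init_input_weights(mask, 0.02, 0.3)
  expect_equal(effective_synapse_count(w, epsilon = 0.01, mask = mask),
               sum(mask))
  w[w > 0] <- 0
  expect_equal(effective_synapse_count(w, epsilon = 0.01, mask = mask), 0)
  # planted pattern vs brute-force count
  w2 <- matrix(runif(400), 20, 20) * mask
  keep <- sample(c(TRUE, FALSE), 400, replace = TRUE)
  w2[!keep] <- 0
  eps <- 0.5
  brute <- 0
  for (i in 1:20) for (j in 1:20) {
    if (mask[i, j] && w2[i, j] > eps) brute <- brute + 1
  }
  expect_equal(effective_synapse_count(w2, epsilon = eps, mask = mask), brute)
})

test_that("ensembles have no cross-liquid synapses and additive counts", {
  parts <- partition_input(c(8, 8), "vertical-halves", 2)
  cfgs <- lapply(1:2, function(i) {
    liquid_config(length(parts[[i]]), 12, 3, p_inp_e = 50, seed = i)
  })
  ens <- build_ensemble(ensemble_config(parts, cfgs))
  expect_length(ens$topologies, 2)
  total <- sum(vapply(ens$topologies, realized_synapse_count, 0))
  per <- vapply(ens$topologies, realized_synapse_count, 0)
  expect_equal(total, sum(per))
  # each liquid's masks only reference its own neurons/partition
  for (i in 1:2) {
    expect_equal(nrow(ens$topologies[[i]]$mask_inp_e), length(parts[[i]]))
  }
  expect_error(ensemble_config(parts, cfgs[1]), "length")
})
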