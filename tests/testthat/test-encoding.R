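test_that("intensity-to-rate mapping spans 0 to 63.75 spikes/s", {
  expect_equal(intensity_to_rate(255), 63.75)
  expect_equal(intensity_to_rate(0), 0)
  expect_equal(intensity_to_rate(128), 32)
  expect_error(intensity_to_rate(300), "\\[0, 255\\]")
})

test_that("rate-to-probability applies the time-step scaling with a cap", {
  expect_equal(rate_to_probability(63.75, 0.5), 0.031875)
  expect_equal(rate_to_probability(0), 0)
  expect_equal(rate_to_probability(2000, 0.5), 1)   # boundary accepted
  expect_error(rate_to_probability(2001, 0.5), "probability")
  expect_error(rate_to_probability(-1), "non-negative")
})

test_that("channel normalization divides by the global maximum", {
  expect_equal(normalize_channels(matrix(3, 2, 2)), matrix(1, 2, 2))
  z <- matrix(0, 3, 4)
  expect_equal(normalize_channels(z), z)
  m <- matrix(c(1, 4, 2, 0), 2, 2)
  expect_equal(normalize_channels(m), matrix(c(0.25, 1, 0.5, 0), 2, 2))
  expect_equal(normalize_channels(normalize_channels(m)),
               normalize_channels(m))  # idempotent
  expect_error(normalize_channels(matrix(-1, 2, 2)), "non-negative")
})

test_that("spike sampling is Bernoulli with the encoded probability", {
  enc0 <- encode_image(matrix(0, 4, 4), duration = 10)
  set.seed(1)
  expect_equal(sum(sample_spikes(enc0)), 0)

  enc1 <- encode_image(matrix(255, 1, 1), duration = 5)
  enc1$firing_prob[] <- 1
  set.seed(1)
  expect_true(all(sample_spikes(enc1)))

  # p = 0.031875 over 700 steps: empirical mean within 4 sigma of n*p
  enc <- encode_image(matrix(255, 1, 1), duration = 350)
  set.seed(99)
  counts <- vapply(1:1000, function(i) sum(sample_spikes(enc)), 0)
  np <- 700 * 0.031875
  se <- sqrt(700 * 0.031875 * (1 - 0.031875) / 1000)
  expect_lt(abs(mean(counts) - np), 4 * se)

  # long-run rate: 10 s at 63.75 Hz
  enc10 <- encode_image(255, duration = 10000)
  set.seed(7)
  n <- enc10$n_steps
  p <- 0.031875
  total <- sum(sample_spikes(enc10))
  expect_lt(abs(total - n * p), 4 * sqrt(n * p * (1 - p)))

  # seed determinism
  set.seed(42); a <- sample_spikes(enc)
  set.seed(42); b <- sample_spikes(enc)
  expect_identical(a, b)
})

test_that("image encoding is constant-rate and row-major", {
  img <- matrix(0, 2, 3)
  img[1, 2] <- 255
  enc <- encode_image(img, duration = 10)
  expect_false(enc$time_varying)
  expect_equal(enc$n_inputs, 6)
  expect_equal(which(enc$firing_prob > 0), 2L)  # row-major: (1,2) -> index 2
  expect_equal(max(enc$firing_prob), 0.031875)
  expect_error(encode_image(img, duration = 0.3, t_step = 0.5), "multiple")
})

test_that("channel encoding holds each frame constant on the 0.5 ms grid", {
  m <- matrix(c(1, 0, 0, 2), 2, 2)  # 2 channels x 2 frames, max = 2
  enc <- encode_channels(m, frame_dt = 5, t_step = 0.5)
  expect_true(enc$time_varying)
  expect_equal(enc$n_steps, 20)
  expect_equal(enc$firing_prob[1, 1:10], rep(0.5, 10))   # frame 1 held
  expect_equal(enc$firing_prob[2, 11:20], rep(1, 10))    # frame 2 held
  expect_equal(enc$firing_prob[1, 11:20], rep(0, 10))
  # duration beyond the envelope: zero-padded tail
  enc2 <- encode_channels(m, frame_dt = 5, duration = 15)
  expect_equal(enc2$firing_prob[, 21:30], matrix(0, 2, 10))
})

test_that("spike rasters round-trip through the CSV event list", {
  enc <- encode_image(matrix(c(255, 128, 0, 64), 2, 2), duration = 20)
  set.seed(3)
  r <- sample_spikes(enc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster_csv(r, path)
  expect_identical(read_raster_csv(path, nrow(r), ncol(r)), r)
})

test_that("IDX image and label files read back correctly", {
  # synthesize a 2-image unsigned-byte IDX pair in code
  img_path <- withr::local_tempfile(fileext = ".idx3-ubyte")
  lbl_path <- withr::local_tempfile(fileext = ".idx1-ubyte")
  imgs <- list(matrix(0:24, 5, 5, byrow = TRUE),
               matrix(rev(0:24), 5, 5, byrow = TRUE))
  con <- file(img_path, "wb")
  writeBin(as.raw(c(0, 0, 8, 3)), con)
  writeBin(c(2L, 5L, 5L), con, size = 4, endian = "big")
  for (m in imgs) writeBin(as.raw(as.vector(t(m))), con)
  close(con)
  con <- file(lbl_path, "wb")
  writeBin(as.raw(c(0, 0, 8, 1)), con)
  writeBin(2L, con, size = 4, endian = "big")
  writeBin(as.raw(c(3, 9)), con)
  close(con)

  back <- read_idx(img_path)
  expect_length(back, 2)
  expect_equal(back[[1]], imgs[[1]])
  expect_equal(back[[2]], imgs[[2]])
  expect_equal(read_idx(lbl_path), c(3L, 9L))
  expect_length(read_idx(img_path, n_max = 1), 1)
  bad <- withr::local_tempfile(fileext = ".idx")
  writeBin(as.raw(c(1, 2, 3, 4)), bad)
  expect_error(read_idx(bad), "IDX")
})
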