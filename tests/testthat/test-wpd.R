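test_that("quadrature-mirror pair matches the sign-alternated reversal", {
  haar <- qmf_pair(c(1, 1) / sqrt(2), name = "haar")
  expect_equal(haar$g, c(1, -1) / sqrt(2))

  for (nm in c("haar", "db2", "db4", "db8")) {
    f <- wavelet_filter(nm)
    expect_length(f$g, length(f$h))
    # brute-force inner product over taps: low- and high-pass orthogonal
    expect_lt(abs(sum(f$h * f$g)), 1e-10)
    # orthonormal family: taps sum to sqrt(2)
    expect_equal(sum(f$h), sqrt(2), tolerance = 1e-10)
    # explicit enumeration of g(k) = (-1)^k h reversed
    L <- length(f$h)
    expect_equal(f$g, (-1)^(0:(L - 1)) * f$h[L:1])
  }

  expect_error(qmf_pair(numeric(0)), "invalid filter")
  expect_error(qmf_pair(c(1, NA)), "invalid filter")
})

test_that("level-1 Haar decomposition matches hand-computed coefficients", {
  haar <- wavelet_filter("haar")

  # constant signal: high-pass node is identically zero
  tr <- wpd_decompose(rep(3, 16), 1, haar)
  expect_equal(tr$nodes[[1]][[2]], rep(0, 8))
  expect_equal(tr$nodes[[1]][[1]], rep(3 * sqrt(2), 8))

  # unit impulse at position 0: stride-2 windows place the taps directly
  x <- c(1, rep(0, 7))
  tr <- wpd_decompose(x, 1, haar)
  expect_equal(tr$nodes[[1]][[1]], c(haar$h[1], rep(0, 3)))
  expect_equal(tr$nodes[[1]][[2]], c(haar$g[1], rep(0, 3)))

  # energy splits exactly across the two children
  set.seed(42)
  y <- rnorm(64)
  tr <- wpd_decompose(y, 1, haar)
  expect_equal(sum(unlist(tr$nodes[[1]])^2), sum(y^2), tolerance = 1e-8)

  expect_error(wpd_decompose(rnorm(12), 3, haar), "depth error")
  expect_error(wpd_decompose(rnorm(8), 0, haar), "level")
})

test_that("perfect reconstruction and Parseval hold for orthonormal filters", {
  for (nm in c("haar", "db4")) {
    f <- wavelet_filter(nm)
    for (seed in 1:5) {
      set.seed(seed)
      x <- rnorm(512)
      tr <- wpd_decompose(x, 4, f)
      expect_lt(max(abs(wpd_reconstruct(tr, 0:15) - x)), 1e-8)
      for (l in 1:4) {
        expect_equal(sum(unlist(tr$nodes[[l]])^2), sum(x^2),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("reconstruction from selected nodes acts as a band selector", {
  f <- wavelet_filter("db4")
  set.seed(7)
  x <- rnorm(512)
  tr <- wpd_decompose(x, 4, f)

  # empty selection gives the zero signal
  expect_equal(wpd_reconstruct(tr, integer(0)), rep(0, 512))

  # a tone at the band centre of frequency-ordered node (4, 0) survives
  fs <- 250
  tone <- sin(2 * pi * (fs / 64) * seq_len(512) / fs)  # centre of 0..fs/32
  trt <- wpd_decompose(tone, 4, f)
  kept <- wpd_reconstruct(trt, 0, ordering = "freq")
  expect_gt(sum(kept^2) / sum(tone^2), 0.95)

  # frequency ordering is the Gray-code permutation of natural order
  expect_equal(wpd_natural_index(0:7), c(0L, 1L, 3L, 2L, 6L, 7L, 5L, 4L))
  # a tone in frequency band b is captured by frequency-ordered node b,
  # not by natural node b (for a band where the two orders differ)
  tone2 <- sin(2 * pi * 42.2 * seq_len(512) / fs)  # band 5 of 16
  tr2 <- wpd_decompose(tone2, 4, f)
  e_freq <- sum(wpd_reconstruct(tr2, 5, ordering = "freq")^2)
  e_nat <- sum(wpd_reconstruct(tr2, 5, ordering = "natural")^2)
  expect_gt(e_freq / sum(tone2^2), 0.5)
  expect_lt(e_nat / sum(tone2^2), 0.2)

  expect_error(wpd_reconstruct(tr, 16), "out of range")
  expect_error(wpd_reconstruct(tr, list(c(9, 0))), "level out of range")
})

test_that("epoch preprocessing band-limits, preserves shape, is idempotent", {
  set.seed(11)
  ep <- eeg_epoch(matrix(rnorm(3 * 512), 3), fs = 250, label = "x")

  out <- preprocess_epoch(ep)
  expect_equal(dim(out$data), dim(ep$data))
  expect_equal(out$label, ep$label)
  expect_equal(out$fs, ep$fs)

  # all-zero epoch stays zero
  z <- preprocess_epoch(eeg_epoch(matrix(0, 3, 512), fs = 250))
  expect_equal(z$data, matrix(0, 3, 512))

  # white noise: spectral energy above fs/8 drops by >= 90%
  for (ch in 1:3) {
    before <- band_power(ep$data[ch, ], 250, c(250 / 8, 125))
    after <- band_power(out$data[ch, ], 250, c(250 / 8, 125))
    expect_lt(after / before, 0.1)
  }

  # selected nodes form a projection: applying twice equals applying once
  twice <- preprocess_epoch(out)
  expect_lt(max(abs(twice$data - out$data)), 1e-6)

  # non-power-of-two lengths go through the padding path
  ep2 <- eeg_epoch(matrix(rnorm(2 * 500), 2), fs = 250)
  out2 <- preprocess_epoch(ep2)
  expect_equal(dim(out2$data), c(2L, 500L))

  expect_error(preprocess_epoch(eeg_epoch(matrix(1, 1, 8), fs = 250),
                                level = 4), "depth error")
})
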