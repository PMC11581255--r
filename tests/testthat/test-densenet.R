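tiny_cfg <- densenet_config("custom", growth_rate = 2L, stem_channels = 4L,
                            block_layers = c(2L, 2L, 2L, 2L), seed = 2L)

test_that("dense connectivity is load-bearing and counts L(L+1)/2 feeds", {
  model <- build_densenet(densenet_config(
    "custom", growth_rate = 2L, stem_channels = 4L,
    block_layers = c(3L, 2L, 2L, 2L), seed = 5L))
  block <- model$blocks[[1]]
  L <- length(block)
  set.seed(1)
  x0 <- array(rnorm(4 * 2 * 16), c(4, 2, 16))
  ref <- dense_block_forward(block, x0)

  # every (source, target) concatenation path changes the output when cut;
  # enumerating them gives exactly L(L+1)/2 direct feeds
  paths <- list()
  for (s in 0:(L - 1)) for (t in (s + 1):L) paths <- c(paths, list(c(s, t)))
  expect_length(paths, L * (L + 1) / 2)
  for (p in paths) {
    ablated <- dense_block_forward(block, x0, drop_paths = list(p))
    expect_gt(max(abs(ablated - ref)), 0,
              label = sprintf("path %d->%d", p[1], p[2]))
  }
})

test_that("channel accounting: block output = input + L * growth", {
  model <- build_densenet(tiny_cfg)
  set.seed(2)
  x <- array(rnorm(4 * 2 * 16), c(4, 2, 16))
  y <- dense_block_forward(model$blocks[[1]], x)
  expect_equal(dim(y)[1], 4L + 2L * tiny_cfg$growth_rate)
  # one layer contributes exactly growth_rate channels
  one <- dense_block_forward(model$blocks[[1]][1], x)
  expect_equal(dim(one)[1], 4L + tiny_cfg$growth_rate)
})

test_that("SE recalibration squeezes, gates in (0,1), and scales", {
  model <- build_densenet(tiny_cfg)
  se <- model$se[[1]]
  C <- ncol(se$w1)

  # constant channels squeeze to their constants
  U <- array(rep(seq_len(C), times = 12), c(C, 3, 4))
  expect_equal(apply(U, 1, mean), as.numeric(seq_len(C)))

  # scale step is a pure channelwise product: undoing the gate recovers U,
  # and a gate forced to one is the identity
  res <- se_recalibrate(U, se)
  expect_equal(res$X / rep(res$weights, times = 12), U, tolerance = 1e-12)
  se1 <- se
  se1$w2[] <- 0
  se1$b2[] <- 36                       # sigmoid(36) == 1 at double precision
  expect_equal(se_recalibrate(U, se1)$X, U)

  # gates stay strictly inside (0,1) across random inputs
  set.seed(3)
  for (i in 1:100) {
    Ui <- array(rnorm(C * 2 * 5), c(C, 2, 5))
    w <- se_recalibrate(Ui, se)$weights
    expect_true(all(w > 0 & w < 1))
  }
})

test_that("feature extraction is deterministic, shaped, and order-stable", {
  model <- build_densenet(tiny_cfg)
  cfg <- synth_config(seed = 4, epoch_seconds = 0.512)
  ds <- generate_dataset(cfg, 3)

  fe <- extract_features(model, ds)
  expect_equal(dim(fe), c(6L, model$feature_dim))
  expect_true(all(is.finite(fe)))

  # same epochs twice: identical rows; permuted epochs: permuted rows
  fe2 <- extract_features(model, ds)
  expect_identical(fe, fe2)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(extract_features(model, ds[perm, ]), fe[perm, ])

  # zero input produces a finite vector
  fz <- extract_features(model, list(eeg_epoch(matrix(0, 3, 128), fs = 250)))
  expect_true(all(is.finite(fz)))

  # rebuilt model with the same seed gives identical weights and features
  expect_identical(extract_features(build_densenet(tiny_cfg), ds[1, ]),
                   fe[1, , drop = FALSE])

  # optional standalone softmax head normalizes
  p <- densenet_softmax(model, fe)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
})

test_that("depth presets follow the 2*sum(layers)+5 depth convention", {
  for (nm in c("d72", "d96", "d121")) {
    cfg <- densenet_config(nm)
    depth <- 2 * sum(cfg$block_layers) + 5
    target <- c(d72 = 72, d96 = 96, d121 = 121)[[nm]]
    expect_lte(abs(depth - target), 1)
  }
})
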