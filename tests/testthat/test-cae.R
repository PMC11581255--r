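test_that("relu matches its piecewise definition", {
  expect_equal(relu(-1), 0)
  expect_equal(relu(2), 2)
  expect_equal(relu(0), 0)
  expect_equal(relu(c(-3, 0.5, 0)), c(0, 0.5, 0))
  expect_error(relu(NA_real_), "finite")
})

test_that("encoder and decoder follow their affine forms", {
  p <- cae_init(4, m = 2, patch_len = 2, seed = 1)

  # zero weights, zero bias: all-zero code
  p0 <- p; p0$W[] <- 0; p0$b[] <- 0
  expect_equal(as.numeric(cae_encode(c(1, 2), p0)), c(0, 0))

  # single 1x1 kernel, w = 1, b = 0 passes the input through
  p1 <- cae_init(1, m = 1, patch_len = 1, seed = 1)
  p1$W[] <- 1; p1$b[] <- 0
  expect_equal(as.numeric(cae_encode(0.5, p1)), 0.5)

  # codes are non-negative for random parameters and inputs
  set.seed(2)
  for (i in 1:100) {
    pr <- cae_init(6, m = 3, patch_len = 6, seed = i)
    expect_true(all(cae_encode(matrix(rnorm(12), 6), pr) >= 0))
  }

  # zero code, zero decoder bias: zero reconstruction, patch-shaped output
  pd <- p; pd$b_hat[] <- 0
  expect_equal(as.numeric(cae_decode(c(0, 0), pd)), c(0, 0))
  expect_equal(dim(cae_decode(matrix(0, 2, 3), p)), c(2L, 3L))

  # orthogonal toy: decoder = transpose of a rotation encoder reproduces
  # inputs whose codes stay in the ReLU-linear (non-negative) regime
  theta <- 0.3
  Q <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2)
  po <- cae_init(2, m = 2, patch_len = 2, seed = 1)
  po$W <- Q; po$b[] <- 0
  po$W_hat <- t(Q); po$b_hat[] <- 0
  x <- c(2, 1)                       # Q %*% x is componentwise positive
  expect_equal(as.numeric(cae_decode(cae_encode(x, po), po)), x,
               tolerance = 1e-12)

  expect_error(cae_encode(c(1, 2, 3), p), "shape mismatch")
  expect_error(cae_decode(c(1, 2, 3), p), "shape mismatch")
  expect_error(cae_init(4, patch_len = 8), "patch_len")
})

test_that("reconstruction cost is a patch-order-invariant MSE", {
  p <- cae_init(2, m = 2, patch_len = 2, seed = 3)

  # perfect reconstruction: zero cost (identity encoder/decoder pair)
  pid <- p
  pid$W <- diag(2); pid$b[] <- 0
  pid$W_hat <- diag(2); pid$b_hat[] <- 0
  X <- matrix(abs(rnorm(10)), 2)
  expect_equal(reconstruction_cost(X, pid), 0)

  # hand example: x = (1, 0) reconstructed as (0, 0) costs 1
  pz <- p; pz$W[] <- 0; pz$b[] <- 0; pz$W_hat[] <- 0; pz$b_hat[] <- 0
  expect_equal(reconstruction_cost(matrix(c(1, 0), 2), pz), 1)

  set.seed(4)
  Y <- matrix(rnorm(20), 2)
  expect_equal(reconstruction_cost(Y, p),
               reconstruction_cost(Y[, sample(10)], p))
  expect_gte(reconstruction_cost(Y, p), 0)
  expect_error(reconstruction_cost(matrix(numeric(0), 2, 0), p), "empty")
})

test_that("analytic gradients match central finite differences", {
  set.seed(5)
  x <- matrix(rnorm(4 * 6), 4, 6)
  y <- c(1L, 2L, 1L, 2L)
  params <- cae_init(6, m = 1, patch_len = 3, classes = c("a", "b"),
                     seed = 2)
  lg <- mihawk:::cae_loss_and_grad(params, x, y, lambda = 0.7)
  eps <- 1e-6
  for (nm in c("W", "b", "W_hat", "b_hat", "V", "cc")) {
    for (i in seq_along(params[[nm]])) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      fd <- (mihawk:::cae_loss_and_grad(up, x, y, 0.7)$loss -
               mihawk:::cae_loss_and_grad(dn, x, y, 0.7)$loss) / (2 * eps)
      an <- lg$grads[[nm]][i]
      expect_lt(abs(an - fd) / max(1e-8, abs(an) + abs(fd)), 1e-4,
                label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("SGD training contract: lr = 0 freezes, seeds reproduce, loss falls", {
  set.seed(6)
  X <- matrix(rnorm(40 * 12), 40, 12)
  lab <- rep(c("l", "r"), 20)

  f0 <- train_cae(X, lab, m = 4, patch_len = 4, lr = 0, epochs = 3, seed = 9)
  ref <- cae_init(12, m = 4, patch_len = 4, classes = c("l", "r"), seed = 9)
  expect_identical(f0$params$W, ref$W)
  expect_identical(f0$params$V, ref$V)

  f1 <- train_cae(X, lab, m = 4, patch_len = 4, lr = 0.01, epochs = 5,
                  seed = 9)
  f2 <- train_cae(X, lab, m = 4, patch_len = 4, lr = 0.01, epochs = 5,
                  seed = 9)
  expect_identical(f1$trace, f2$trace)
  expect_lt(f1$trace$loss[5], f1$trace$loss[1])
  expect_equal(nrow(f1$trace), 5)
})

test_that("classification head normalizes and solves a separable toy", {
  # symmetric logits give uniform scores
  fit <- train_cae(matrix(rnorm(8 * 4), 8), rep(c("a", "b"), 4),
                   m = 2, patch_len = 2, lr = 0, epochs = 1, seed = 1)
  fit$params$V[] <- 0; fit$params$cc[] <- 0
  sc <- cae_classify(fit, matrix(rnorm(3 * 4), 3))
  expect_equal(unname(as.matrix(sc[, c("a", "b")])),
               matrix(0.5, 3, 2), tolerance = 1e-12)

  # score rows always sum to one
  set.seed(7)
  fit2 <- train_cae(matrix(rnorm(30 * 6), 30), rep(c("a", "b"), 15),
                    m = 4, patch_len = 3, lr = 0.02, epochs = 5, seed = 7)
  sc2 <- cae_classify(fit2, matrix(rnorm(20 * 6), 20))
  expect_equal(rowSums(as.matrix(sc2[, c("a", "b")])), rep(1, 20),
               tolerance = 1e-6)

  # linearly separable 2-D latent toy is solved exactly after training
  set.seed(8)
  Z <- rbind(matrix(rnorm(60 * 2, mean = 3), 60, 2),
             matrix(rnorm(60 * 2, mean = -3), 60, 2))
  zl <- rep(c("p", "q"), each = 60)
  fz <- train_cae(Z, zl, m = 4, patch_len = 2, lr = 0.05, epochs = 50,
                  seed = 8)
  expect_equal(mean(cae_classify(fz, Z)$.pred_class == zl), 1.0)

  # an unsupervised fit has no head to classify with
  fu <- train_cae(Z, labels = NULL, m = 2, patch_len = 2, lr = 0.01,
                  epochs = 2, seed = 1)
  expect_error(cae_classify(fu, Z), "untrained head")
  expect_true(all(is.na(fu$trace$accuracy)))
})
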