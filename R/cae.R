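# Convolutional autoencoder (CAE) classifier. The encoder applies m shared
# kernels to d-length patches of the input vector (a convolution with
# stride = patch length), giving non-negative codes o = ReLU(W x + b); the
# decoder reconstructs each patch linearly, x_hat = W_hat o + b_hat. The
# reconstruction cost is the mean squared error over patches. For
# classification, the codes are mean-pooled over patches into a latent
# vector and passed through a softmax head; training minimizes
# J = J_cae + lambda * cross-entropy by seeded minibatch SGD with
# analytic gradients.

#' Rectified linear unit
#'
#' `relu(x) = x` for `x >= 0`, else 0, elementwise.
#'
#' @param x Numeric vector, matrix or array.
#' @return Same shape as `x`.
#' @export
relu <- function(x) {
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  pmax(x, 0)
}

#' Initialize CAE parameters
#'
#' @param input_dim Length of the input vectors.
#' @param m Number of encoder kernels (latent channels).
#' @param patch_len Patch length `d`; inputs are split into consecutive
#'   non-overlapping patches (zero-padded to a multiple of `d`). Must not
#'   exceed `input_dim`.
#' @param classes Character vector of class labels, or `NULL` for a purely
#'   unsupervised autoencoder (no classification head).
#' @param seed Seed for the random initialization.
#' @return A list of class `cae_params` with encoder `W` (m x d), `b`,
#'   decoder `W_hat` (d x m), `b_hat`, and optionally head `V`, `cc`.
#' @export
cae_init <- function(input_dim, m = 16L, patch_len = 8L, classes = NULL,
                     seed = 1L) {
  patch_len <- as.integer(patch_len); m <- as.integer(m)
  if (patch_len > input_dim) {
    stop("`patch_len` must not exceed `input_dim` (kernel fits in patch)",
         call. = FALSE)
  }
  stopifnot(m >= 1, patch_len >= 1)
  withr::local_seed(seed)
  params <- list(
    W = matrix(stats::rnorm(m * patch_len, sd = sqrt(2 / patch_len)),
               m, patch_len),
    b = numeric(m),
    W_hat = matrix(stats::rnorm(patch_len * m, sd = sqrt(1 / m)),
                   patch_len, m),
    b_hat = numeric(patch_len),
    input_dim = as.integer(input_dim), m = m, patch_len = patch_len,
    classes = classes)
  if (!is.null(classes)) {
    K <- length(classes)
    params$V <- matrix(stats::rnorm(K * m, sd = sqrt(1 / m)), K, m)
    params$cc <- numeric(K)
  }
  structure(params, class = "cae_params")
}

# split rows of x (n x input_dim) into patches: returns d x (n * P) matrix,
# columns grouped sample-major (all patches of sample 1, then sample 2, ...)
.to_patches <- function(x, patch_len) {
  n <- nrow(x); Fdim <- ncol(x)
  P <- ceiling(Fdim / patch_len)
  padded <- matrix(0, n, P * patch_len)
  padded[, seq_len(Fdim)] <- x
  # row i of `padded` becomes P columns of length d
  matrix(t(padded), nrow = patch_len)
}

.from_patches <- function(patches, n, input_dim) {
  padded <- matrix(as.numeric(patches), nrow = n, byrow = TRUE)
  padded[, seq_len(input_dim), drop = FALSE]
}

#' Encode patches
#'
#' `o_j = relu(w_j . x + b_j)` for each of the `m` kernels; codes are
#' non-negative by construction.
#'
#' @param x Patch matrix (`patch_len` x p) or a single patch vector.
#' @param params A [cae_init()] parameter set.
#' @return Code matrix (`m` x p).
#' @export
cae_encode <- function(x, params) {
  x <- as.matrix(x)
  if (nrow(x) != params$patch_len) {
    stop("patch shape mismatch: expected length ", params$patch_len,
         call. = FALSE)
  }
  relu(params$W %*% x + params$b)
}

#' Decode codes
#'
#' Linear reconstruction `x_hat = W_hat o + b_hat` (the decoder activation is
#' the identity; the nonlinearity lives in the encoder).
#'
#' @param o Code matrix (`m` x p) or vector.
#' @param params A [cae_init()] parameter set.
#' @return Reconstructed patch matrix (`patch_len` x p).
#' @export
cae_decode <- function(o, params) {
  o <- as.matrix(o)
  if (nrow(o) != params$m) {
    stop("code shape mismatch: expected length ", params$m, call. = FALSE)
  }
  params$W_hat %*% o + params$b_hat
}

#' Mean squared reconstruction cost
#'
#' `J = (1/p) * sum_i || x_i - x_hat_i ||^2` over the `p` patches.
#'
#' @param patches Patch matrix (`patch_len` x p).
#' @param params A [cae_init()] parameter set.
#' @return Non-negative scalar; 0 iff every patch is reconstructed exactly.
#' @export
reconstruction_cost <- function(patches, params) {
  patches <- as.matrix(patches)
  if (ncol(patches) == 0) stop("empty patch set", call. = FALSE)
  rec <- cae_decode(cae_encode(patches, params), params)
  mean(colSums((patches - rec)^2))
}

# Joint loss and analytic gradients on a batch.
# x: n x input_dim; y: integer class indices (or NULL for recon-only).
cae_loss_and_grad <- function(params, x, y = NULL, lambda = 1) {
  n <- nrow(x)
  d <- params$patch_len; m <- params$m
  Xp <- .to_patches(x, d)                    # d x (n * P)
  P <- ncol(Xp) / n
  Z <- params$W %*% Xp + params$b
  O <- pmax(Z, 0)
  Xhat <- params$W_hat %*% O + params$b_hat
  R <- Xhat - Xp
  p_total <- ncol(Xp)
  J_cae <- sum(R^2) / p_total

  dXhat <- 2 * R / p_total
  gW_hat <- dXhat %*% t(O)
  gb_hat <- rowSums(dXhat)
  dO <- t(params$W_hat) %*% dXhat

  ce <- NA_real_; acc <- NA_real_
  gV <- NULL; gcc <- NULL
  if (!is.null(y)) {
    if (is.null(params$V)) stop("untrained head: no classes configured",
                                call. = FALSE)
    # mean-pool codes per sample: columns are sample-major blocks of P
    grp <- rep(seq_len(n), each = P)
    U <- t(rowsum(t(O), grp)) / P            # m x n
    logits <- params$V %*% U + params$cc     # K x n
    S <- exp(sweep(logits, 2, apply(logits, 2, max)))
    S <- sweep(S, 2, colSums(S), "/")
    idx <- cbind(y, seq_len(n))
    ce <- -mean(log(pmax(t(S)[cbind(seq_len(n), y)], 1e-300)))
    acc <- mean(apply(S, 2, which.max) == y)
    dlogits <- S
    dlogits[cbind(y, seq_len(n))] <- dlogits[cbind(y, seq_len(n))] - 1
    dlogits <- dlogits / n
    gV <- lambda * (dlogits %*% t(U))
    gcc <- lambda * rowSums(dlogits)
    dU <- t(params$V) %*% dlogits            # m x n
    dO <- dO + lambda * dU[, grp, drop = FALSE] / P
  }

  dZ <- dO * (Z > 0)
  gW <- dZ %*% t(Xp)
  gb <- rowSums(dZ)

  loss <- J_cae + if (is.null(y)) 0 else lambda * ce
  list(loss = loss, J_cae = J_cae, ce = ce, accuracy = acc,
       grads = list(W = gW, b = gb, W_hat = gW_hat, b_hat = gb_hat,
                    V = gV, cc = gcc))
}

#' Train the CAE by minibatch stochastic gradient descent
#'
#' Minimizes the composite objective
#' `J = J_cae + lambda * cross-entropy` (reconstruction only when `labels`
#' is `NULL`) with seeded shuffling, so a fixed seed gives an identical loss
#' trace. Training aborts with diagnostics if the loss becomes non-finite.
#'
#' @param x Numeric matrix, samples x features (e.g. DenseNet feature
#'   vectors, or flattened preprocessed epochs).
#' @param labels Class labels (factor/character), or `NULL` for unsupervised
#'   reconstruction.
#' @param m Number of encoder kernels.
#' @param patch_len Patch length `d`.
#' @param lr Learning rate (> 0; `lr = 0` leaves parameters untouched).
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param lambda Weight of the cross-entropy term (default 1).
#' @param clip Global gradient-norm ceiling per minibatch (`Inf` disables);
#'   keeps large learning rates stable on poorly scaled batches.
#' @param seed Seed for initialization and shuffling.
#' @return An object of class `cae_fit`: `params`, `trace` tibble
#'   (`epoch`, `loss`, `J_cae`, `ce`, `accuracy`), and the settings.
#' @export
train_cae <- function(x, labels = NULL, m = 16L, patch_len = 8L,
                      lr = 0.01, batch_size = 16L, epochs = 20L,
                      lambda = 1, clip = 5, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 1, lr >= 0, epochs >= 1)
  classes <- if (!is.null(labels)) sort(unique(as.character(labels)))
  y <- if (!is.null(labels)) match(as.character(labels), classes)
  params <- cae_init(ncol(x), m = m, patch_len = patch_len,
                     classes = classes, seed = seed)
  withr::local_seed(seed + 1L)
  n <- nrow(x)
  trace <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    batch_stats <- c(loss = 0, J_cae = 0, ce = 0, accuracy = 0)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      take <- ord[s:min(s + batch_size - 1L, n)]
      lg <- cae_loss_and_grad(params, x[take, , drop = FALSE], y[take],
                              lambda)
      if (!is.finite(lg$loss)) {
        stop(sprintf(
          "CAE training diverged at epoch %d (loss = %g); lower `lr`",
          ep, lg$loss), call. = FALSE)
      }
      gnorm <- sqrt(sum(vapply(lg$grads, function(g)
        if (is.null(g)) 0 else sum(g^2), numeric(1))))
      scale <- if (is.finite(clip) && gnorm > clip) clip / gnorm else 1
      for (nm in c("W", "b", "W_hat", "b_hat", "V", "cc")) {
        if (!is.null(lg$grads[[nm]])) {
          params[[nm]] <- params[[nm]] - lr * scale * lg$grads[[nm]]
        }
      }
      w <- length(take) / n
      batch_stats <- batch_stats +
        w * c(lg$loss, lg$J_cae,
              ifelse(is.na(lg$ce), 0, lg$ce),
              ifelse(is.na(lg$accuracy), 0, lg$accuracy))
    }
    trace[[ep]] <- tibble::tibble(
      epoch = ep, loss = batch_stats[1], J_cae = batch_stats[2],
      ce = if (is.null(y)) NA_real_ else batch_stats[3],
      accuracy = if (is.null(y)) NA_real_ else batch_stats[4])
  }
  structure(list(params = params, trace = dplyr::bind_rows(trace),
                 m = m, patch_len = patch_len, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lambda = lambda,
                 seed = as.integer(seed)),
            class = "cae_fit")
}

#' @export
print.cae_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf(
    "<cae_fit: m = %d, d = %d, %d epochs; final loss %.4g%s>\n",
    x$m, x$patch_len, x$epochs, last$loss,
    if (!is.na(last$accuracy))
      sprintf(", train accuracy %.3f", last$accuracy) else ""))
  invisible(x)
}

#' Classify with a trained CAE
#'
#' Encodes the inputs, mean-pools the codes over patches and applies the
#' softmax head. Score rows sum to 1.
#'
#' @param fit A [train_cae()] fit trained with labels.
#' @param x Numeric matrix, samples x features (same width as training).
#' @return A tibble with `.pred_class` and one score column per class.
#' @export
cae_classify <- function(fit, x) {
  stopifnot(inherits(fit, "cae_fit"))
  params <- fit$params
  if (is.null(params$V)) {
    stop("untrained head: fit the CAE with labels to classify",
         call. = FALSE)
  }
  x <- as.matrix(x)
  n <- nrow(x)
  Xp <- .to_patches(x, params$patch_len)
  P <- ncol(Xp) / n
  O <- cae_encode(Xp, params)
  U <- t(rowsum(t(O), rep(seq_len(n), each = P))) / P
  logits <- t(params$V %*% U + params$cc)
  scores <- .softmax_rows(logits)
  colnames(scores) <- params$classes
  out <- tibble::as_tibble(scores)
  out$.pred_class <- params$classes[max.col(scores, ties.method = "first")]
  dplyr::relocate(out, ".pred_class")
}
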