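# Densely connected convolutional feature extractor with squeeze-and-
# excitation (SE) channel recalibration. Epochs are mapped to
# 1 x channels x samples "images" (2-D convolutions over channel x time);
# stem = 7x7 conv stride 2 + 3x3 max pool stride 2; four dense blocks
# (each layer a 1x1 then 3x3 convolution, concatenative connectivity),
# an SE block after each dense block, 1x1-conv + 2x2 average-pool
# transitions between blocks, and a global-average-pool feature head.
# Weights are He-initialized from a seed and fixed: the network is a
# structured random-projection feature extractor; classification is
# learned downstream by the convolutional autoencoder.

# ---- tensor helpers (tensors stored as C x H x W arrays) ----------------

.conv2d <- function(x, w, stride = 1L, pad = 0L) {
  # x: C_in x H x W array; w: C_out x C_in x kh x kw
  dims <- dim(x); C_in <- dims[1]; H <- dims[2]; W <- dims[3]
  kd <- dim(w); C_out <- kd[1]; kh <- kd[3]; kw <- kd[4]
  if (kd[2] != C_in) stop("contract error: channel mismatch", call. = FALSE)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  H_out <- (Hp - kh) %/% stride + 1L
  W_out <- (Wp - kw) %/% stride + 1L
  if (H_out < 1L || W_out < 1L) {
    stop("configuration error: spatial size too small for kernel",
         call. = FALSE)
  }
  xp <- array(0, c(C_in, Hp, Wp))
  xp[, pad + seq_len(H), pad + seq_len(W)] <- x
  # im2col: rows index (C_in, kh, kw), columns index output positions
  hi <- (seq_len(H_out) - 1L) * stride
  wi <- (seq_len(W_out) - 1L) * stride
  cols <- matrix(0, nrow = C_in * kh * kw, ncol = H_out * W_out)
  r <- 0L
  for (dw in seq_len(kw)) {
    for (dh in seq_len(kh)) {
      patch <- xp[, hi + dh, wi + dw, drop = FALSE]
      cols[r + seq_len(C_in), ] <- matrix(patch, nrow = C_in)
      r <- r + C_in
    }
  }
  # kernel collapsed column-major (C_in fastest, then kh, then kw) matches
  # the im2col row order built above
  wm <- matrix(w, nrow = C_out)
  out <- wm %*% cols
  array(out, c(C_out, H_out, W_out))
}

.maxpool2d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  dims <- dim(x); C <- dims[1]; H <- dims[2]; W <- dims[3]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  xp <- array(-Inf, c(C, Hp, Wp))
  xp[, pad + seq_len(H), pad + seq_len(W)] <- x
  H_out <- (Hp - k) %/% stride + 1L
  W_out <- (Wp - k) %/% stride + 1L
  out <- array(-Inf, c(C, H_out, W_out))
  hi <- (seq_len(H_out) - 1L) * stride
  wi <- (seq_len(W_out) - 1L) * stride
  for (dh in seq_len(k)) {
    for (dw in seq_len(k)) {
      out <- pmax(out, xp[, hi + dh, wi + dw, drop = FALSE])
    }
  }
  out
}

.avgpool2d <- function(x, k = 2L, stride = 2L) {
  dims <- dim(x); C <- dims[1]; H <- dims[2]; W <- dims[3]
  H_out <- max((H - k) %/% stride + 1L, 1L)
  W_out <- max((W - k) %/% stride + 1L, 1L)
  kh <- min(k, H); kw <- min(k, W)
  out <- array(0, c(C, H_out, W_out))
  hi <- (seq_len(H_out) - 1L) * stride
  wi <- (seq_len(W_out) - 1L) * stride
  for (dh in seq_len(kh)) {
    for (dw in seq_len(kw)) {
      out <- out + x[, pmin(hi + dh, H), pmin(wi + dw, W), drop = FALSE]
    }
  }
  out / (kh * kw)
}

.relu <- function(x) pmax(x, 0)

.he_kernel <- function(C_out, C_in, kh, kw) {
  fan_in <- C_in * kh * kw
  array(stats::rnorm(C_out * C_in * kh * kw, sd = sqrt(2 / fan_in)),
        c(C_out, C_in, kh, kw))
}

# ---- configuration -------------------------------------------------------

#' DenseNet-SE configuration
#'
#' Depth presets follow the convention depth = 2 * sum(block_layers) + 5
#' (stem conv + two convs per dense layer + three transitions + head):
#' `d121` is the classic `[6, 12, 24, 16]`; `d96` and `d72` are
#' reduced-depth analogues; `reduced` is a desk-scale preset
#' (`[2, 2, 2, 2]`, growth 8, stem 16) used throughout the tests.
#'
#' @param preset One of `"reduced"`, `"d72"`, `"d96"`, `"d121"`, or
#'   `"custom"` (then supply the other arguments).
#' @param growth_rate Channels added by each dense layer.
#' @param block_layers Integer vector of 4: layers per dense block.
#' @param stem_channels Channels produced by the 7x7 stem.
#' @param se_reduction Bottleneck ratio of the SE gate (>= 1); the hidden
#'   width is `max(1, C %/% se_reduction)`.
#' @param num_classes Classes for the optional standalone softmax head.
#' @param seed Seed for He weight initialization.
#' @return A list of class `densenet_config`.
#' @export
densenet_config <- function(preset = c("reduced", "d72", "d96", "d121",
                                       "custom"),
                            growth_rate = NULL, block_layers = NULL,
                            stem_channels = NULL, se_reduction = 4L,
                            num_classes = 2L, seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    reduced = list(growth_rate = 8L, block_layers = c(2L, 2L, 2L, 2L),
                   stem_channels = 16L),
    d72 = list(growth_rate = 4L, block_layers = c(4L, 8L, 14L, 8L),
               stem_channels = 8L),
    d96 = list(growth_rate = 4L, block_layers = c(6L, 12L, 20L, 8L),
               stem_channels = 8L),
    d121 = list(growth_rate = 4L, block_layers = c(6L, 12L, 24L, 16L),
                stem_channels = 8L),
    custom = list(growth_rate = 4L, block_layers = c(2L, 2L, 2L, 2L),
                  stem_channels = 8L))
  growth_rate <- as.integer(growth_rate %||% defaults$growth_rate)
  block_layers <- as.integer(block_layers %||% defaults$block_layers)
  stem_channels <- as.integer(stem_channels %||% defaults$stem_channels)
  stopifnot(growth_rate >= 1, length(block_layers) == 4,
            all(block_layers >= 1), stem_channels >= 1, se_reduction >= 1,
            num_classes >= 2)
  structure(list(preset = preset, growth_rate = growth_rate,
                 block_layers = block_layers,
                 stem_channels = stem_channels,
                 se_reduction = as.integer(se_reduction),
                 num_classes = as.integer(num_classes),
                 seed = as.integer(seed)),
            class = "densenet_config")
}

#' Build a DenseNet-SE feature extractor
#'
#' Instantiates all weights (seeded He initialization) for the configured
#' architecture. The returned model is a plain list of named numeric arrays
#' plus the config, so it can be serialized as JSON + delimited arrays.
#'
#' @param config A [densenet_config()].
#' @return An object of class `densenet_model`.
#' @export
build_densenet <- function(config) {
  stopifnot(inherits(config, "densenet_config"))
  withr::local_seed(config$seed)
  k <- config$growth_rate
  layers <- list(stem = .he_kernel(config$stem_channels, 1L, 7L, 7L))
  C <- config$stem_channels
  blocks <- vector("list", 4L)
  se <- vector("list", 4L)
  transitions <- vector("list", 3L)
  for (b in 1:4) {
    L <- config$block_layers[b]
    blk <- vector("list", L)
    Cin <- C
    for (l in seq_len(L)) {
      bottleneck <- 4L * k
      blk[[l]] <- list(
        w1 = .he_kernel(bottleneck, Cin, 1L, 1L),   # 1x1 bottleneck
        w3 = .he_kernel(k, bottleneck, 3L, 3L))     # 3x3 growth conv
      Cin <- Cin + k
    }
    blocks[[b]] <- blk
    C <- Cin
    hidden <- max(1L, C %/% config$se_reduction)
    se[[b]] <- list(
      w1 = matrix(stats::rnorm(hidden * C, sd = sqrt(2 / C)), hidden, C),
      b1 = numeric(hidden),
      w2 = matrix(stats::rnorm(C * hidden, sd = sqrt(2 / hidden)), C, hidden),
      b2 = numeric(C))
    if (b < 4) {
      C_out <- max(1L, C %/% 2L)                    # 0.5 compression
      transitions[[b]] <- .he_kernel(C_out, C, 1L, 1L)
      C <- C_out
    }
  }
  head <- list(
    w = matrix(stats::rnorm(config$num_classes * C, sd = sqrt(2 / C)),
               config$num_classes, C),
    b = numeric(config$num_classes))
  structure(list(config = config, stem = layers$stem, blocks = blocks,
                 se = se, transitions = transitions, head = head,
                 feature_dim = C),
            class = "densenet_model")
}

#' @export
print.densenet_model <- function(x, ...) {
  cat(sprintf(
    "<densenet_model: preset %s, blocks [%s], growth %d, %d features>\n",
    x$config$preset, paste(x$config$block_layers, collapse = ","),
    x$config$growth_rate, x$feature_dim))
  invisible(x)
}

#' Dense block forward pass
#'
#' Layer `i` of an L-layer dense block receives the channel concatenation of
#' the block input and all previous layer outputs, applies a 1x1 bottleneck
#' convolution and a 3x3 convolution (both ReLU), and contributes
#' `growth_rate` new channels. An L-layer block therefore realises
#' `L * (L + 1) / 2` direct layer-to-layer feeds, and its output has
#' `input_channels + L * growth_rate` channels.
#'
#' @param block One element of `model$blocks`.
#' @param x0 Input activation array (C x H x W).
#' @param drop_paths Optional list of `c(source, target)` 0-based layer index
#'   pairs whose concatenation path is zeroed (ablation diagnostics; source
#'   0 is the block input).
#' @return Output activation array.
#' @export
dense_block_forward <- function(block, x0, drop_paths = NULL) {
  feats <- list(x0)  # feats[[j + 1]] is the output of layer j (0 = input)
  for (l in seq_along(block)) {
    parts <- feats
    if (!is.null(drop_paths)) {
      for (dp in drop_paths) {
        if (dp[2] == l && dp[1] + 1 <= length(parts)) {
          z <- parts[[dp[1] + 1]]
          parts[[dp[1] + 1]] <- array(0, dim(z))
        }
      }
    }
    x_cat <- .cat_channels(parts)
    h <- .relu(.conv2d(x_cat, block[[l]]$w1, stride = 1L, pad = 0L))
    h <- .relu(.conv2d(h, block[[l]]$w3, stride = 1L, pad = 1L))
    feats[[l + 1L]] <- h
  }
  .cat_channels(feats)
}

.cat_channels <- function(parts) {
  if (length(parts) == 1L) return(parts[[1L]])
  dims <- dim(parts[[1L]])
  total <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(0, c(total, dims[2], dims[3]))
  at <- 0L
  for (p in parts) {
    C <- dim(p)[1]
    out[at + seq_len(C), , ] <- p
    at <- at + C
  }
  out
}

#' Squeeze-and-excitation channel recalibration
#'
#' Squeeze: global average pool each channel to a scalar. Excitation: a
#' two-layer gate (ReLU bottleneck of width `C / reduction`, then sigmoid)
#' produces one weight in (0, 1) per channel. Scale: the input is multiplied
#' channelwise by the gate.
#'
#' @param U Activation array (C x H x W).
#' @param se SE parameters (`w1`, `b1`, `w2`, `b2`), e.g. one element of
#'   `model$se`.
#' @return List with `X` (recalibrated array) and `weights` (the per-channel
#'   gate values, all strictly inside (0, 1)).
#' @export
se_recalibrate <- function(U, se) {
  C <- dim(U)[1]
  if (C < 1L) stop("SE input must have at least one channel", call. = FALSE)
  z <- apply(U, 1, mean)                       # squeeze: 1 x 1 x C
  h <- .relu(as.numeric(se$w1 %*% z + se$b1))  # excitation bottleneck
  s <- 1 / (1 + exp(-(as.numeric(se$w2 %*% h + se$b2))))
  list(X = U * array(rep(s, times = prod(dim(U)[2:3])), dim(U)),
       weights = s)
}

.densenet_forward <- function(model, x) {
  h <- .relu(.conv2d(x, model$stem, stride = 2L, pad = 3L))
  h <- .maxpool2d(h, k = 3L, stride = 2L, pad = 1L)
  for (b in 1:4) {
    h <- dense_block_forward(model$blocks[[b]], h)
    h <- se_recalibrate(h, model$se[[b]])$X
    if (b < 4) {
      h <- .relu(.conv2d(h, model$transitions[[b]], stride = 1L, pad = 0L))
      h <- .avgpool2d(h, k = 2L, stride = 2L)
    }
  }
  apply(h, 1, mean)                            # global average pool
}

#' Extract feature vectors from epochs
#'
#' Maps each epoch to a `1 x channels x samples` image, runs the DenseNet-SE
#' forward pass and returns the global-average-pooled features, one row per
#' epoch. Deterministic given the model's (seeded) weights.
#'
#' @param model A [build_densenet()] model.
#' @param epochs A list of [eeg_epoch()] objects, or a dataset tibble with an
#'   `epoch` list-column.
#' @return Numeric matrix, `length(epochs)` x `model$feature_dim`.
#' @export
extract_features <- function(model, epochs) {
  stopifnot(inherits(model, "densenet_model"))
  if (is.data.frame(epochs)) epochs <- epochs$epoch
  out <- matrix(NA_real_, nrow = length(epochs), ncol = model$feature_dim)
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    x <- array(ep$data, c(1L, nrow(ep$data), ncol(ep$data)))
    out[i, ] <- .densenet_forward(model, x)
  }
  out
}

#' Standalone softmax head over DenseNet features
#'
#' Retained for optional standalone use of the extractor as a classifier;
#' the pipeline default delegates classification to the CAE.
#'
#' @param model A [build_densenet()] model.
#' @param features Feature matrix from [extract_features()].
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
densenet_softmax <- function(model, features) {
  logits <- features %*% t(model$head$w) +
    matrix(model$head$b, nrow(features), length(model$head$b), byrow = TRUE)
  .softmax_rows(logits)
}

.softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
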