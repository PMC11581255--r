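# Wavelet packet decomposition with periodic (circular) extension.
#
# Analysis step (stride-2 circular correlation): for a parent node with
# coefficients x of even length n,
#   a[i] = sum_j h[j] * x[(2i + j) mod n]   (low-pass child,  node 2m)
#   b[i] = sum_j g[j] * x[(2i + j) mod n]   (high-pass child, node 2m+1)
# which is the coefficient recursion d^{l+1,2m}_i = sum_k h(k - 2i) d^{l,m}_k
# after the substitution j = k - 2i. Worked Haar example (h = g-flip of
# [1,1]/sqrt(2)), x = c(1, 2, 3, 4):
#   a = (x[1]+x[2], x[3]+x[4])/sqrt(2) = (2.121..., 4.949...)
#   b = (x[1]-x[2], x[3]-x[4])/sqrt(2) * (-1) sign per tap order.
# The synthesis step is the adjoint; for orthonormal taps the transform is
# orthogonal, so Parseval holds exactly and reconstruction is perfect.

.wpd_analysis_step <- function(x, taps) {
  n <- length(x)
  half <- n %/% 2L
  i0 <- seq.int(0L, n - 2L, by = 2L)
  out <- numeric(half)
  for (j in seq_along(taps)) {
    out <- out + taps[j] * x[((i0 + (j - 1L)) %% n) + 1L]
  }
  out
}

.wpd_synthesis_step <- function(coef, taps) {
  # adjoint of .wpd_analysis_step: x[k] = sum_i taps[(k - 2i) mod n] coef[i]
  half <- length(coef)
  n <- 2L * half
  x <- numeric(n)
  i0 <- seq.int(0L, n - 2L, by = 2L)
  for (j in seq_along(taps)) {
    idx <- ((i0 + (j - 1L)) %% n) + 1L
    x[idx] <- x[idx] + taps[j] * coef
  }
  x
}

#' Wavelet packet decomposition of a signal
#'
#' Expands a 1-D signal into the full wavelet-packet binary tree down to
#' `level`, using periodic (circular) boundary extension. Both the low-pass
#' and high-pass branches are split at every level, so level `l` holds
#' `2^l` sub-band nodes, each with `length(signal) / 2^l` coefficients.
#' Nodes are stored in natural (Paley) recursion order: child `2m` is the
#' low-pass filtering of node `m`, child `2m + 1` the high-pass filtering.
#'
#' @param signal Numeric vector; its length must be divisible by `2^level`.
#' @param level Integer decomposition depth (>= 1).
#' @param filter A `wavelet_filter` (see [wavelet_filter()], [qmf_pair()]).
#'
#' @return An object of class `wpd_tree`: a list with `level`,
#'   `signal_length`, `filter` and `nodes`, where `nodes[[l]][[m + 1]]` holds
#'   the coefficients of node `(l, m)`.
#'
#' @seealso [wpd_reconstruct()], [preprocess_epoch()]
#' @export
wpd_decompose <- function(signal, level, filter = wavelet_filter("db4")) {
  stopifnot(inherits(filter, "wavelet_filter"))
  level <- as.integer(level)
  if (level < 1L) stop("`level` must be >= 1", call. = FALSE)
  n <- length(signal)
  if (!is.numeric(signal) || !all(is.finite(signal))) {
    stop("`signal` must be finite numeric", call. = FALSE)
  }
  if (n %% (2L^level) != 0L || n < 2L^level) {
    stop(sprintf(
      "decomposition depth error: signal length %d is not divisible by 2^%d",
      n, level), call. = FALSE)
  }
  nodes <- vector("list", level)
  parents <- list(as.numeric(signal))
  for (l in seq_len(level)) {
    children <- vector("list", 2L^l)
    for (m in seq_along(parents)) {
      x <- parents[[m]]
      children[[2L * m - 1L]] <- .wpd_analysis_step(x, filter$h)
      children[[2L * m]] <- .wpd_analysis_step(x, filter$g)
    }
    nodes[[l]] <- children
    parents <- children
  }
  structure(list(level = level, signal_length = n, filter = filter,
                 nodes = nodes),
            class = "wpd_tree")
}

#' @export
print.wpd_tree <- function(x, ...) {
  cat(sprintf("<wpd_tree: level %d, signal length %d, wavelet %s>\n",
              x$level, x$signal_length, x$filter$name))
  invisible(x)
}

#' Map frequency-ordered node indices to natural (Paley) order
#'
#' High-pass decimation reverses a band's frequency content, so the natural
#' recursion order of wavelet-packet nodes is not monotone in frequency. The
#' frequency-ordered band `f` at a given level corresponds to the natural
#' node `f XOR (f %/% 2)` (binary-reflected Gray code).
#'
#' @param f Integer vector of frequency-ordered node indices (0-based).
#' @return Integer vector of natural-order indices (0-based).
#' @export
wpd_natural_index <- function(f) {
  f <- as.integer(f)
  bitwXor(f, f %/% 2L)
}

.resolve_nodes <- function(nodes, level, ordering) {
  nodes <- as.integer(nodes)
  if (any(nodes < 0L)) stop("invalid node: negative index", call. = FALSE)
  if (identical(ordering, "freq")) wpd_natural_index(nodes) else nodes
}

#' Reconstruct a signal from selected wavelet-packet nodes
#'
#' Inverts the wavelet-packet transform keeping only the selected nodes
#' (every other node zeroed). Selecting all nodes of the deepest level gives
#' perfect reconstruction; selecting a frequency-contiguous subset acts as an
#' (orthogonal-projection) band-pass filter.
#'
#' @param tree A `wpd_tree` from [wpd_decompose()].
#' @param nodes Integer vector of node indices at level `level` (0-based), or
#'   a list of `c(level, index)` pairs for a mixed-level cover.
#' @param level Level at which `nodes` are indexed; defaults to the tree depth.
#' @param ordering `"freq"` (indices ordered by band frequency, the default)
#'   or `"natural"` (Paley recursion order).
#'
#' @return Numeric vector of length `tree$signal_length`.
#' @export
wpd_reconstruct <- function(tree, nodes, level = tree$level,
                            ordering = c("freq", "natural")) {
  stopifnot(inherits(tree, "wpd_tree"))
  ordering <- match.arg(ordering)
  if (is.list(nodes)) {
    pairs <- lapply(nodes, function(p) c(as.integer(p[1]), as.integer(p[2])))
  } else {
    pairs <- lapply(as.integer(nodes), function(m) c(as.integer(level), m))
  }
  out <- numeric(tree$signal_length)
  for (p in pairs) {
    l <- p[1]; m_req <- p[2]
    if (l < 1L || l > tree$level) {
      stop("invalid node: level out of range", call. = FALSE)
    }
    m <- .resolve_nodes(m_req, l, ordering)
    if (m_req < 0L || m_req >= 2L^l) {
      stop("invalid node: index out of range", call. = FALSE)
    }
    coef <- tree$nodes[[l]][[m + 1L]]
    # climb to the root: a single node's contribution is the adjoint chain
    for (lev in seq.int(l, 1L)) {
      taps <- if (m %% 2L == 0L) tree$filter$h else tree$filter$g
      coef <- .wpd_synthesis_step(coef, taps)
      m <- m %/% 2L
    }
    out <- out + coef
  }
  out
}

#' Band-limit an EEG epoch through wavelet-packet selection
#'
#' Decomposes each channel to `level`, keeps the selected sub-band nodes and
#' reconstructs, returning an epoch of identical shape. With the defaults
#' (level 4, frequency-ordered nodes 0-3) the retained band is
#' `[0, fs/8)` Hz - at 250 Hz sampling this is 0-31.25 Hz, covering the mu
#' (8-13 Hz) and beta (13-30 Hz) sensorimotor rhythms that motor imagery
#' modulates. Channels whose length is not a multiple of `2^level` are
#' padded by symmetric reflection before the transform and cropped after.
#'
#' @param epoch An [eeg_epoch()].
#' @param level Decomposition depth (default 4).
#' @param nodes 0-based node indices kept at `level` (default `0:3`).
#' @param wavelet Wavelet family name or a `wavelet_filter` (default `"db4"`).
#' @param ordering Node index ordering, `"freq"` (default) or `"natural"`.
#'
#' @return An [eeg_epoch()] with the same shape, label, sampling rate and
#'   channel names as the input.
#' @export
preprocess_epoch <- function(epoch, level = 4L, nodes = 0:3,
                             wavelet = "db4",
                             ordering = c("freq", "natural")) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  ordering <- match.arg(ordering)
  filt <- if (inherits(wavelet, "wavelet_filter")) wavelet
          else wavelet_filter(wavelet)
  n <- ncol(epoch$data)
  block <- 2L^as.integer(level)
  if (n < block) {
    stop(sprintf("decomposition depth error: %d samples < 2^%d", n, level),
         call. = FALSE)
  }
  pad <- (block - n %% block) %% block
  out <- epoch$data
  for (ch in seq_len(nrow(out))) {
    x <- out[ch, ]
    if (pad > 0L) x <- c(x, x[seq.int(n, by = -1L, length.out = pad)])
    tree <- wpd_decompose(x, level, filt)
    y <- wpd_reconstruct(tree, nodes, level = level, ordering = ordering)
    out[ch, ] <- y[seq_len(n)]
  }
  eeg_epoch(out, fs = epoch$fs, label = epoch$label,
            channel_names = epoch$channel_names)
}
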