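# Orthonormal Daubechies low-pass taps (standard published values; sum = sqrt(2)).
.db_lowpass <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.4829629131445341, 0.8365163037378079,
          0.2241438680420134, -0.1294095225512604),
  db4 = c(0.2303778133088964, 0.7148465705529154, 0.6308807679298587,
          -0.0279837694168599, -0.1870348117190931, 0.0308413818355607,
          0.0328830116668852, -0.0105974017850690),
  db8 = c(0.0544158422431072, 0.3128715909143166, 0.6756307362973195,
          0.5853546836542159, -0.0158291052563823, -0.2840155429615824,
          0.0004724845739124, 0.1287474266204893, -0.0173693010018090,
          -0.0440882539307971, 0.0139810279174001, 0.0087460940474065,
          -0.0048703529934520, -0.0003917403733770, 0.0006754494064506,
          -0.0001174767841248)
)

#' Quadrature-mirror filter pair
#'
#' Builds the high-pass filter `g` paired with a low-pass filter `h` through
#' the quadrature-mirror relation `g(k) = (-1)^k h(1 - k)`. With the filter's
#' support indexed so that the relation amounts to the sign-alternated
#' reversal `g(k) = (-1)^k h(L - 1 - k)`, the resulting pair is orthogonal
#' for orthonormal wavelet families (Haar, Daubechies): `sum(h * g) == 0`,
#' and all even shifts of `h` and `g` rows stay mutually orthonormal, which
#' is what makes the packet transform energy-preserving.
#'
#' @param h Numeric vector of low-pass filter taps (finite, non-empty).
#' @param name Optional wavelet family identifier stored with the pair.
#'
#' @return An object of class `wavelet_filter`: a list with elements `h`, `g`
#'   and `name`.
#'
#' @examples
#' qmf_pair(c(1, 1) / sqrt(2), name = "haar")
#'
#' @export
qmf_pair <- function(h, name = "custom") {
  if (length(h) == 0 || !is.numeric(h) || !all(is.finite(h))) {
    stop("invalid filter: `h` must be a non-empty finite numeric vector",
         call. = FALSE)
  }
  L <- length(h)
  k <- seq_len(L) - 1L
  g <- (-1)^k * rev(h)
  structure(list(h = as.numeric(h), g = as.numeric(g), name = name),
            class = "wavelet_filter")
}

#' Built-in wavelet filters
#'
#' Returns the quadrature-mirror filter pair for a named orthonormal wavelet
#' family. Haar is exact and convenient for hand-checkable examples; `db4`
#' (8 taps) is the package default for EEG band-limiting.
#'
#' @param name One of `"haar"`, `"db2"`, `"db4"`, `"db8"`.
#' @return A `wavelet_filter` (see [qmf_pair()]).
#' @export
wavelet_filter <- function(name = c("db4", "haar", "db2", "db8")) {
  name <- match.arg(name)
  qmf_pair(.db_lowpass[[name]], name = name)
}

#' @export
print.wavelet_filter <- function(x, ...) {
  cat(sprintf("<wavelet_filter: %s, %d taps>\n", x$name, length(x$h)))
  invisible(x)
}
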