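# Synthetic motor-imagery EEG: class-conditional mu/beta event-related
# desynchronization (ERD) over lateralized channel groups, on 1/f noise.

#' Synthetic MI-EEG generator configuration
#'
#' Describes the emulated recording: sampling rate, channel count, epoch
#' duration, the mu and beta bands carrying the sensorimotor rhythm, the ERD
#' attenuation depth applied to the channel group contralateral to the
#' imagined hand, the 1/f spectral slope of the background noise, and the
#' oscillation-to-noise ratio.
#'
#' The default epoch length of 2.048 s at 250 Hz gives 512 samples - an
#' exact multiple of `2^4`, so level-4 wavelet-packet preprocessing needs no
#' boundary padding.
#'
#' @param fs Sampling rate, Hz.
#' @param n_channels Number of channels; laid out as a left-lateral group, a
#'   midline group and a right-lateral group (proxying C3/Cz/C4).
#' @param epoch_seconds Epoch duration, seconds.
#' @param classes Character vector of class labels. Odd-numbered classes
#'   (first, third, ...) attenuate the right-lateral group, even-numbered
#'   ones the left - i.e. contralateral ERD for left/right hand imagery.
#' @param mu_band,beta_band Frequency intervals (Hz) of the two rhythms.
#' @param erd_depth Fractional oscillation attenuation in `[0, 1]` on the
#'   contralateral group; 0 means no class signal at all.
#' @param noise_exponent Spectral slope of the background noise
#'   (power ~ 1/f^exponent).
#' @param snr_db Oscillation-to-noise power ratio, dB, on non-attenuated
#'   channels.
#' @param onset_ramp If `TRUE`, ERD ramps in over the first quarter of the
#'   epoch instead of applying throughout.
#' @param seed Integer seed used by [generate_dataset()].
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 250, n_channels = 3, epoch_seconds = 2.048,
                         classes = c("left_hand", "right_hand"),
                         mu_band = c(8, 13), beta_band = c(13, 30),
                         erd_depth = 0.6, noise_exponent = 1,
                         snr_db = 10, onset_ramp = FALSE, seed = 1L) {
  stopifnot(fs > 2 * max(beta_band), erd_depth >= 0, erd_depth <= 1,
            n_channels >= 1, epoch_seconds > 0, length(classes) >= 1)
  structure(list(fs = fs, n_channels = as.integer(n_channels),
                 epoch_seconds = epoch_seconds, classes = classes,
                 mu_band = mu_band, beta_band = beta_band,
                 erd_depth = erd_depth, noise_exponent = noise_exponent,
                 snr_db = snr_db, onset_ramp = isTRUE(onset_ramp),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# contiguous left / midline / right channel groups, as equal as possible
.channel_groups <- function(n_channels) {
  sizes <- diff(round(seq(0, n_channels, length.out = 4)))
  rep(c("left", "mid", "right"), times = sizes)
}

# 1/f^a noise with unit variance, via FFT spectral shaping
.pink_noise <- function(n, exponent) {
  white <- stats::rnorm(n)
  if (exponent == 0) return(white)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                 # DC gets the f=1 weight
  f <- pmin(f, n - f + 1)                   # fold to two-sided frequencies
  spec <- spec * f^(-exponent / 2)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Generate one synthetic MI epoch
#'
#' Each channel receives unit-variance 1/f background noise plus mu- and
#' beta-band sinusoids with random frequency (uniform within the band) and
#' phase. On the channel group contralateral to `class_label` the
#' oscillations are attenuated by `1 - erd_depth` (ERD). The oscillation
#' amplitude on unattenuated channels is set so the oscillation-to-noise
#' power ratio equals `snr_db`.
#'
#' Uses the current RNG state; seed upstream (or use [generate_dataset()],
#' which seeds from its config) for reproducibility.
#'
#' @param class_label One of `config$classes`.
#' @param config A [synth_config()].
#' @return An [eeg_epoch()].
#' @export
generate_epoch <- function(class_label, config) {
  stopifnot(inherits(config, "synth_config"))
  idx <- match(class_label, config$classes)
  if (is.na(idx)) stop("invalid class: ", class_label, call. = FALSE)
  n <- round(config$fs * config$epoch_seconds)
  t <- seq_len(n) / config$fs
  groups <- .channel_groups(config$n_channels)
  contra <- if (idx %% 2L == 1L) "right" else "left"
  # equal-power mu and beta components; total oscillation power from snr_db
  osc_sd <- sqrt(10^(config$snr_db / 10))
  amp <- osc_sd            # per component: 2 components, each amp/sqrt(2) RMS
  ramp <- if (config$onset_ramp) pmin(t / (max(t) / 4), 1) else rep(1, n)
  data <- matrix(0, nrow = config$n_channels, ncol = n)
  for (ch in seq_len(config$n_channels)) {
    f_mu <- stats::runif(1, config$mu_band[1], config$mu_band[2])
    f_beta <- stats::runif(1, config$beta_band[1], config$beta_band[2])
    ph <- stats::runif(2, 0, 2 * pi)
    osc <- amp * (sin(2 * pi * f_mu * t + ph[1]) +
                    sin(2 * pi * f_beta * t + ph[2]))
    gain <- if (groups[ch] == contra) {
      1 - config$erd_depth * ramp
    } else rep(1, n)
    data[ch, ] <- .pink_noise(n, config$noise_exponent) + gain * osc
  }
  eeg_epoch(data, fs = config$fs, label = class_label,
            channel_names = paste0(groups, "_", seq_len(config$n_channels)))
}

#' Generate a balanced labeled synthetic dataset
#'
#' Draws `n_per_class` epochs for every class in `config$classes`, seeded
#' from `config$seed` so identical configs yield bit-identical data. The
#' generator configuration and seed travel with the tibble as attributes and
#' are recorded in the manifest by [write_epoch_dataset()].
#'
#' @param config A [synth_config()].
#' @param n_per_class Epochs per class (>= 1).
#' @param shuffle If `TRUE`, rows are returned in seeded random order
#'   (class-major order otherwise).
#'
#' @return A tibble with columns `epoch_id`, `label` and list-column `epoch`.
#' @export
generate_dataset <- function(config, n_per_class, shuffle = FALSE) {
  stopifnot(inherits(config, "synth_config"), n_per_class >= 1)
  withr::local_seed(config$seed)
  labels <- rep(config$classes, each = n_per_class)
  epochs <- purrr::map(labels, generate_epoch, config = config)
  ord <- if (shuffle) sample.int(length(epochs)) else seq_along(epochs)
  out <- tibble::tibble(epoch_id = seq_along(epochs)[ord],
                        label = labels[ord], epoch = epochs[ord])
  attr(out, "synth_config") <- unclass(config)
  attr(out, "seed") <- config$seed
  out
}

#' Band power of an epoch channel
#'
#' Mean periodogram power of one channel inside a frequency band; used for
#' spectral checks and the ERD effect-size diagnostics.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate, Hz.
#' @param band Length-2 numeric interval, Hz.
#' @return Mean power (signal units squared) over periodogram bins in `band`.
#' @export
band_power <- function(x, fs, band) {
  n <- length(x)
  spec <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- freqs >= band[1] & freqs <= band[2]
  mean(spec[keep])
}
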