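#' Labeled multichannel EEG epoch
#'
#' The pipeline's atomic input: one trial of multichannel EEG with its
#' sampling rate, class label and channel names.
#'
#' @param data Numeric matrix, channels x samples (microvolts). All entries
#'   must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Class identifier (character), or `NA` for unlabeled data.
#' @param channel_names Optional character vector, one name per channel.
#'
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, fs, label = NA_character_, channel_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("`data` must be a finite numeric matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` length must match the number of channels",
         call. = FALSE)
  }
  structure(list(data = data, fs = as.numeric(fs),
                 label = as.character(label),
                 channel_names = as.character(channel_names)),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch: %d ch x %d samples @ %g Hz, label = %s>\n",
              nrow(x$data), ncol(x$data), x$fs, x$label))
  invisible(x)
}

#' Write / read a single epoch as delimited matrix + JSON sidecar
#'
#' The on-disk format is a plain tab-separated numeric matrix (rows =
#' channels, no header) plus a `<path>.json` sidecar holding `fs`, `label`
#' and `channel_names`.
#'
#' @param epoch An [eeg_epoch()].
#' @param path File path for the matrix; the sidecar is `<path>.json`.
#' @return `write_epoch()` returns `path` invisibly; `read_epoch()` returns
#'   an [eeg_epoch()].
#' @export
write_epoch <- function(epoch, path) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  utils::write.table(epoch$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(fs = epoch$fs, label = epoch$label,
               channel_names = epoch$channel_names)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epoch
#' @param path File path written by [write_epoch()].
#' @export
read_epoch <- function(path) {
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  eeg_epoch(mat, fs = meta$fs, label = meta$label,
            channel_names = meta$channel_names)
}

#' Write / read an epoch dataset directory
#'
#' A dataset is a tibble with columns `epoch_id`, `label` and an `epoch`
#' list-column of [eeg_epoch()] objects (as returned by
#' [generate_dataset()]). On disk it becomes one delimited file + JSON
#' sidecar per epoch and a `manifest.json` recording the epoch files, labels
#' and any generator configuration attached to the tibble.
#'
#' @param dataset Epoch dataset tibble.
#' @param dir Directory to write into (created if missing).
#' @return `write_epoch_dataset()` returns `dir` invisibly;
#'   `read_epoch_dataset()` returns the dataset tibble.
#' @export
write_epoch_dataset <- function(dataset, dir) {
  stopifnot(is.data.frame(dataset), "epoch" %in% names(dataset))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("epoch_%04d.tsv", seq_len(nrow(dataset)))
  purrr::walk2(dataset$epoch, files,
               function(ep, f) write_epoch(ep, file.path(dir, f)))
  manifest <- list(files = files, labels = dataset$label,
                   config = attr(dataset, "synth_config"),
                   seed = attr(dataset, "seed"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epoch_dataset
#' @export
read_epoch_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  epochs <- purrr::map(manifest$files,
                       function(f) read_epoch(file.path(dir, f)))
  out <- tibble::tibble(epoch_id = seq_along(epochs),
                        label = purrr::map_chr(epochs, "label"),
                        epoch = epochs)
  attr(out, "synth_config") <- manifest$config
  attr(out, "seed") <- manifest$seed
  out
}
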