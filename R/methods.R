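#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for fitted pipeline objects
#'
#' `tidy()` returns the per-unit detail (convergence history, per-class
#' metrics, loss trace); `glance()` returns a one-row summary.
#'
#' @param x A `bhhsho_result`, `eval_report`, `cae_fit`, `mihawk_tune` or
#'   `mihawk_run`.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name mihawk-tidiers
NULL

#' @rdname mihawk-tidiers
#' @export
tidy.bhhsho_result <- function(x, ...) x$history

#' @rdname mihawk-tidiers
#' @export
glance.bhhsho_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 iterations = x$config$iters, N = x$config$N,
                 sense = x$config$sense, n_rejected = x$n_rejected)
}

#' @rdname mihawk-tidiers
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @rdname mihawk-tidiers
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall,
                 accuracy = x$accuracy, f_score = x$f_score, n = x$n)
}

#' @rdname mihawk-tidiers
#' @export
tidy.cae_fit <- function(x, ...) x$trace

#' @rdname mihawk-tidiers
#' @export
glance.cae_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(epochs = x$epochs, lr = x$lr, m = x$m,
                 patch_len = x$patch_len, final_loss = last$loss,
                 final_J_cae = last$J_cae, final_accuracy = last$accuracy)
}

#' @rdname mihawk-tidiers
#' @export
tidy.mihawk_tune <- function(x, ...) x$history

#' @rdname mihawk-tidiers
#' @export
glance.mihawk_tune <- function(x, ...) {
  tibble::tibble(best_precision = x$best_precision, lr = x$best_hp$lr,
                 batch = x$best_hp$batch, depth = x$best_hp$depth)
}

#' @rdname mihawk-tidiers
#' @export
tidy.mihawk_run <- function(x, ...) tidy(x$report)

#' @rdname mihawk-tidiers
#' @export
glance.mihawk_run <- function(x, ...) glance(x$report)

#' Plot optimizer convergence
#'
#' Best-so-far and population-mean fitness per iteration.
#'
#' @param object A `bhhsho_result` or `mihawk_tune`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bhhsho_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"iteration",
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "fitness",
                  title = "BHHSHO convergence") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bhhsho_result
#' @export
autoplot.mihawk_tune <- function(object, ...) {
  autoplot(object$result) +
    ggplot2::labs(y = "validation precision",
                  title = "Hyperparameter tuning convergence")
}

#' Plot CAE training curves
#'
#' @param object A `cae_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cae_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"epoch",
                            names_to = "metric", values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "CAE training trace") +
    ggplot2::theme_minimal()
}

#' Plot per-class metrics of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_class[, c("class", "precision", "recall", "accuracy",
                         "f_score")],
    -"class", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "value", title = "Per-class metrics") +
    ggplot2::theme_minimal()
}

#' Plot a multichannel epoch
#'
#' Stacked channel traces against time.
#'
#' @param object An `eeg_epoch`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_epoch <- function(object, ...) {
  df <- tibble::tibble(
    time = rep(seq_len(ncol(object$data)) / object$fs,
               each = nrow(object$data)),
    channel = rep(object$channel_names, ncol(object$data)),
    value = as.numeric(object$data))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (uV)",
                  title = sprintf("EEG epoch (label: %s)", object$label)) +
    ggplot2::theme_minimal()
}
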