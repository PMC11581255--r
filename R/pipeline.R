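# End-to-end orchestration: WPD band-limiting -> DenseNet-SE features ->
# optional BHHSHO hyperparameter tuning -> CAE classification -> evaluation.

#' Hyperparameter search space
#'
#' Three dimensions, all encoded on `[0, 1]` for the optimizer: learning
#' rate (log-uniform on `[1e-4, 1e-1]`), batch size (equal-width bins over
#' an ordered set), and DenseNet depth preset.
#'
#' @param batch Ordered integer set of batch sizes.
#' @param depth Ordered character set of depth presets (see
#'   [densenet_config()]).
#' @return A list of class `search_space`.
#' @export
search_space <- function(batch = c(8L, 16L, 32L, 64L),
                         depth = c("d72", "d96", "d121")) {
  structure(list(lr_range = c(1e-4, 1e-1), batch = as.integer(batch),
                 depth = depth),
            class = "search_space")
}

#' Default (untuned) hyperparameters of a search space
#'
#' The centre of the space: learning rate 0.01 (the conventional SGD
#' default, mid-range on the log scale), the median batch size and the
#' median depth preset. This is the baseline a tuned configuration is
#' compared against.
#'
#' @param space A [search_space()].
#' @return List with `lr`, `batch`, `depth`.
#' @export
default_hyperparameters <- function(space = search_space()) {
  mid <- function(set) set[ceiling((length(set) + 1) / 2)]
  list(lr = 0.01, batch = mid(space$batch), depth = mid(space$depth))
}

#' Decode an optimizer position into hyperparameters
#'
#' `lr = 10^(-4 + 3 * x1)` (so 0 -> 1e-4, 2/3 -> 1e-2, 1 -> 1e-1); batch
#' size and depth preset by equal-width binning of `x2`, `x3` over their
#' ordered sets.
#'
#' @param position Numeric vector in `[0, 1]^3`.
#' @param space A [search_space()].
#' @return List with `lr`, `batch`, `depth`.
#' @export
decode_position <- function(position, space = search_space()) {
  x <- pmin(pmax(position, 0), 1)
  bin <- function(u, set) set[min(floor(u * length(set)) + 1L, length(set))]
  list(lr = 10^(-4 + 3 * x[1]),
       batch = bin(x[2], space$batch),
       depth = bin(x[3], space$depth))
}

#' Compute classification metrics
#'
#' Builds one-vs-rest confusion counts per class and macro-averages.
#' Per class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy
#' `(TP+TN)/n`, F the harmonic mean of precision and recall (conventions:
#' 0 when a denominator is 0). The report's macro F-score is the harmonic
#' mean of macro precision and macro recall.
#'
#' @param predictions Character/factor vector of predicted labels.
#' @param labels True labels, same length.
#' @return An object of class `eval_report`: list with `per_class` tibble
#'   (counts and per-class metrics), `precision`, `recall`, `accuracy`,
#'   `f_score` (macro), and `n`.
#' @export
evaluate <- function(predictions, labels) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (length(predictions) != length(labels)) {
    stop("`predictions` and `labels` must have equal length", call. = FALSE)
  }
  n <- length(labels)
  if (n < 1) stop("need at least one sample", call. = FALSE)
  classes <- sort(unique(c(labels, predictions)))
  per_class <- purrr::map_dfr(classes, function(cl) {
    TP <- sum(predictions == cl & labels == cl)
    FP <- sum(predictions == cl & labels != cl)
    FN <- sum(predictions != cl & labels == cl)
    TN <- n - TP - FP - FN
    P <- if (TP + FP > 0) TP / (TP + FP) else 0
    R <- if (TP + FN > 0) TP / (TP + FN) else 0
    tibble::tibble(class = cl, TP = TP, FP = FP, FN = FN, TN = TN,
                   precision = P, recall = R,
                   accuracy = (TP + TN) / n,
                   f_score = if (P + R > 0) 2 * P * R / (P + R) else 0)
  })
  mp <- mean(per_class$precision)
  mr <- mean(per_class$recall)
  structure(list(per_class = per_class,
                 precision = mp, recall = mr,
                 accuracy = mean(predictions == labels),
                 f_score = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0,
                 n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<eval_report: n = %d | precision %.4f | recall %.4f | ",
    "accuracy %.4f | F %.4f>\n"),
    x$n, x$precision, x$recall, x$accuracy, x$f_score))
  invisible(x)
}

#' Stratified train/validation/test split
#'
#' Adds a `split` column to an epoch dataset, assigning each class's rows to
#' train/validation/test in the given proportions (seeded shuffle within
#' class).
#'
#' @param dataset Epoch dataset tibble (needs a `label` column).
#' @param ratios Length-3 proportions for train/validation/test (sum 1).
#' @param seed Integer seed.
#' @return The dataset with an added `split` column.
#' @export
split_dataset <- function(dataset, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  withr::local_seed(seed)
  split <- character(nrow(dataset))
  for (cl in unique(dataset$label)) {
    idx <- sample(which(dataset$label == cl))
    k <- length(idx)
    n_tr <- round(ratios[1] * k)
    n_va <- round(ratios[2] * k)
    split[idx] <- rep(c("train", "validation", "test"),
                      c(n_tr, n_va, k - n_tr - n_va))
  }
  dataset$split <- split
  dataset
}

#' Pipeline configuration
#'
#' Namespaced settings for every stage. `synth = NULL` means the caller
#' supplies a dataset to [run_pipeline()] instead of generating one.
#'
#' @param synth A [synth_config()] or `NULL`.
#' @param n_per_class Epochs per class when generating.
#' @param wavelet List: `name`, `level`, `nodes`, `ordering`.
#' @param densenet List passed to [densenet_config()].
#' @param cae List: `m`, `patch_len` (`NULL` = one patch spanning the whole
#'   feature vector, i.e. a dense encoder), `lr`, `batch`, `epochs`,
#'   `lambda`.
#' @param split Train/validation/test proportions.
#' @param tune List: `enabled`, plus BHHSHO budget (`N`, `iters`) and the
#'   short per-candidate training budget `epochs`.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            n_per_class = 50L,
                            wavelet = list(name = "db4", level = 4L,
                                           nodes = 0:3, ordering = "freq"),
                            densenet = list(preset = "reduced"),
                            cae = list(m = 16L, patch_len = NULL,
                                       lr = 0.05, batch = 16L, epochs = 5L,
                                       lambda = 3),
                            split = c(0.6, 0.2, 0.2),
                            tune = list(enabled = FALSE, N = 6L, iters = 5L,
                                        epochs = 5L),
                            seed = 1L) {
  structure(list(synth = synth, n_per_class = as.integer(n_per_class),
                 wavelet = wavelet, densenet = densenet, cae = cae,
                 split = split, tune = tune, seed = as.integer(seed)),
            class = "pipeline_config")
}

.preprocess_dataset <- function(dataset, wavelet) {
  filt <- wavelet_filter(wavelet$name %||% "db4")
  dataset$epoch <- purrr::map(dataset$epoch, preprocess_epoch,
                              level = wavelet$level %||% 4L,
                              nodes = wavelet$nodes %||% 0:3,
                              wavelet = filt,
                              ordering = wavelet$ordering %||% "freq")
  dataset
}

# z-score columns by training-split statistics (stabilizes CAE training
# across the learning-rate range of the search space)
.standardize_features <- function(feats, train_idx) {
  mu <- colMeans(feats[train_idx, , drop = FALSE])
  sd <- apply(feats[train_idx, , drop = FALSE], 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  sweep(sweep(feats, 2, mu), 2, sd, "/")
}

# validation precision of one hyperparameter candidate; features per depth
# preset are computed once and cached in `cache` (an environment). A
# candidate whose training diverges or whose precision is undefined scores
# 0 (the explicit fallback for the undefined-precision case).
.candidate_precision <- function(hp, dataset, cache, cae_cfg, tune_epochs,
                                 seed, num_classes) {
  feats <- .preset_features(hp$depth, dataset, cache, seed, num_classes)
  tr <- dataset$split == "train"
  va <- dataset$split == "validation"
  feats <- .standardize_features(feats, tr)
  tryCatch({
    fit <- train_cae(feats[tr, , drop = FALSE], dataset$label[tr],
                     m = cae_cfg$m %||% 16L,
                     patch_len = min(cae_cfg$patch_len %||% ncol(feats),
                                     ncol(feats)),
                     lr = hp$lr, batch_size = hp$batch, epochs = tune_epochs,
                     lambda = cae_cfg$lambda %||% 3, seed = seed)
    pred <- cae_classify(fit, feats[va, , drop = FALSE])
    evaluate(pred$.pred_class, dataset$label[va])$precision
  }, error = function(e) {
    warning("candidate scored 0 (", conditionMessage(e), ")", call. = FALSE)
    0
  })
}

.preset_features <- function(preset, dataset, cache, seed, num_classes) {
  key <- as.character(preset)
  if (is.null(cache[[key]])) {
    model <- build_densenet(densenet_config(preset = preset,
                                            num_classes = num_classes,
                                            seed = seed))
    cache[[key]] <- extract_features(model, dataset)
  }
  cache[[key]]
}

#' Validation precision of a single hyperparameter configuration
#'
#' Trains the CAE on the training split with the given hyperparameters for
#' the short tuning budget and scores macro precision on the validation
#' split - the same quantity the tuner maximizes. Useful for comparing a
#' tuned configuration against [default_hyperparameters()].
#'
#' @param dataset Preprocessed epoch dataset with a `split` column.
#' @param hp List with `lr`, `batch`, `depth`.
#' @param config A [pipeline_config()].
#' @return Precision in `[0, 1]`.
#' @export
validation_precision <- function(dataset, hp, config = pipeline_config()) {
  stopifnot("split" %in% names(dataset))
  cache <- new.env(parent = emptyenv())
  .candidate_precision(hp, dataset, cache, config$cae,
                       config$tune$epochs %||% 5L, config$seed,
                       length(unique(dataset$label)))
}

#' Tune hyperparameters with BHHSHO
#'
#' Maximizes validation precision over the (learning rate, batch size,
#' depth preset) space. Each candidate trains the CAE for a fixed short
#' budget on the training split and is scored on the validation split;
#' features are cached per depth preset, so the DenseNet forward pass runs
#' once per preset.
#'
#' @param dataset Preprocessed epoch dataset with a `split` column (see
#'   [split_dataset()]); epochs should already be band-limited.
#' @param space A [search_space()].
#' @param config A [pipeline_config()] (supplies CAE settings, tuning
#'   budget and seed).
#' @return List of class `mihawk_tune`: `best_hp`, `best_precision`,
#'   `history` tibble, and the underlying `bhhsho_result`.
#' @export
tune_pipeline <- function(dataset, space = search_space(),
                          config = pipeline_config()) {
  stopifnot("split" %in% names(dataset))
  cache <- new.env(parent = emptyenv())
  num_classes <- length(unique(dataset$label))
  objective <- function(x) {
    hp <- decode_position(x, space)
    .candidate_precision(hp, dataset, cache, config$cae,
                         config$tune$epochs %||% 5L, config$seed,
                         num_classes)
  }
  bcfg <- bhhsho_config(N = config$tune$N %||% 5L,
                        iters = config$tune$iters %||% 4L,
                        lb = rep(0, 3), ub = rep(1, 3),
                        seed = config$seed, sense = "maximize")
  res <- bhhsho_optimize(objective, bcfg)
  structure(list(best_hp = decode_position(res$best_position, space),
                 best_precision = res$best_fitness,
                 history = res$history, result = res),
            class = "mihawk_tune")
}

#' @export
print.mihawk_tune <- function(x, ...) {
  cat(sprintf(
    "<mihawk_tune: best validation precision %.4f | lr %.2g, batch %d, %s>\n",
    x$best_precision, x$best_hp$lr, x$best_hp$batch, x$best_hp$depth))
  invisible(x)
}

#' Run the full classification pipeline
#'
#' Generates (or takes) a labeled epoch dataset, band-limits every epoch by
#' wavelet-packet selection, extracts DenseNet-SE features, optionally tunes
#' (learning rate, batch size, depth) with BHHSHO on the validation split,
#' trains the CAE classifier on the training split with the selected
#' hyperparameters, and evaluates on the held-out test split. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param dataset Optional epoch dataset tibble; generated from
#'   `config$synth` when omitted.
#' @return An object of class `mihawk_run`: list with `report` (test-set
#'   [evaluate()] result), `predictions` tibble, `cae_fit`, `hp` (the
#'   hyperparameters used), `tuning` (a `mihawk_tune` or `NULL`), `splits`
#'   and the config.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset)) {
    if (is.null(config$synth)) {
      stop("no dataset: supply `dataset` or a `synth` config", call. = FALSE)
    }
    synth <- config$synth
    synth$seed <- config$seed
    dataset <- generate_dataset(synth, config$n_per_class)
  }
  dataset <- .preprocess_dataset(dataset, config$wavelet)
  dataset <- split_dataset(dataset, config$split, seed = config$seed)
  num_classes <- length(unique(dataset$label))

  cache <- new.env(parent = emptyenv())
  tuning <- NULL
  if (isTRUE(config$tune$enabled)) {
    tuning <- tune_pipeline(dataset, search_space(), config)
    hp <- tuning$best_hp
  } else {
    hp <- list(lr = config$cae$lr %||% 0.05,
               batch = config$cae$batch %||% 16L,
               depth = config$densenet$preset %||% "reduced")
  }

  feats <- .preset_features(hp$depth, dataset, cache, config$seed,
                            num_classes)
  tr <- dataset$split == "train"
  te <- dataset$split == "test"
  feats <- .standardize_features(feats, tr)
  fit <- train_cae(feats[tr, , drop = FALSE], dataset$label[tr],
                   m = config$cae$m %||% 16L,
                   patch_len = min(config$cae$patch_len %||% ncol(feats),
                                   ncol(feats)),
                   lr = hp$lr, batch_size = hp$batch,
                   epochs = config$cae$epochs %||% 5L,
                   lambda = config$cae$lambda %||% 3, seed = config$seed)
  pred <- cae_classify(fit, feats[te, , drop = FALSE])
  report <- evaluate(pred$.pred_class, dataset$label[te])
  predictions <- dplyr::bind_cols(
    tibble::tibble(epoch_id = dataset$epoch_id[te],
                   label = dataset$label[te]),
    pred)
  structure(list(report = report, predictions = predictions,
                 cae_fit = fit, hp = hp, tuning = tuning,
                 splits = table(dataset$split), config = config),
            class = "mihawk_run")
}

#' @export
print.mihawk_run <- function(x, ...) {
  cat("<mihawk_run>\n")
  cat(sprintf("  splits: %s\n",
              paste(names(x$splits), as.integer(x$splits), sep = "=",
                    collapse = ", ")))
  cat(sprintf("  hyperparameters: lr %.2g, batch %d, depth %s%s\n",
              x$hp$lr, x$hp$batch, x$hp$depth,
              if (is.null(x$tuning)) "" else " (BHHSHO-tuned)"))
  cat(sprintf("  test: precision %.4f | recall %.4f | accuracy %.4f | F %.4f\n",
              x$report$precision, x$report$recall, x$report$accuracy,
              x$report$f_score))
  invisible(x)
}
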