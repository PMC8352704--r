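# Seeded mini-batch SGD for the single-modal backbones and the fusion head,
# plus the iteration-count and batch-size sweep experiments.  "Iterations"
# counts parameter updates.  The batch sweep holds the epoch budget fixed, so
# larger batches mean fewer updates; that is the reading under which training
# time declines as batch size grows.

#' Training configuration
#'
#' @param iterations number of parameter updates.
#' @param batch_size mini-batch size (must not exceed the training-set size).
#' @param learning_rate SGD step size on the mean batch loss (default 0.5;
#'   sigmoid activations keep gradients small, so larger-than-textbook steps
#'   are appropriate — see the vignette).
#' @param seed integer seed; a run is bit-reproducible from (config, data).
#' @param freeze_backbones fusion only: keep transferred backbones fixed
#'   (default `TRUE`).
#' @param record_every record a history checkpoint every this many updates.
#' @return An object of class `train_config`.
#' @export
train_config <- function(iterations = 300L, batch_size = 16L,
                         learning_rate = 0.5, seed = 1L,
                         freeze_backbones = TRUE, record_every = 10L) {
  iterations <- as.integer(iterations); batch_size <- as.integer(batch_size)
  if (iterations < 1L) stop("iterations must be positive")
  if (batch_size < 1L) stop("batch_size must be positive")
  if (learning_rate < 0) stop("learning_rate must be nonnegative")
  structure(list(iterations = iterations, batch_size = batch_size,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 freeze_backbones = isTRUE(freeze_backbones),
                 record_every = as.integer(record_every)),
            class = "train_config")
}

#' Sample a mini-batch without replacement
#'
#' Draws `batch_size` distinct indices from the current RNG stream (callers
#' seed the stream; [train_model()] does so from `config$seed`).
#'
#' @param dataset list of training pairs (or any list).
#' @param batch_size number of elements to draw; at most `length(dataset)`.
#' @return Integer vector of indices into `dataset`.
#' @export
sample_batch <- function(dataset, batch_size) {
  n <- length(dataset)
  if (batch_size > n)
    stop(sprintf("batch_size %d exceeds training-set size %d", batch_size, n))
  sample.int(n, batch_size)
}

sgd_step <- function(par, grad, lr) {
  for (nm in names(grad)) par[[nm]] <- par[[nm]] - lr * grad[[nm]]
  par
}

new_history <- function() data.frame(update = integer(), mean_batch_loss = numeric(),
                                     seconds = numeric())

#' Train a model with mini-batch SGD
#'
#' Runs `config$iterations` updates, each on a batch sampled without
#' replacement from the training set; the trajectory is bit-reproducible
#' from `(config, train_set)`.  Dispatches on the model class:
#' single-modal backbones update every layer; fusion models update the head
#' (plus projections / backbones when those are not frozen).  A non-finite
#' batch loss aborts with the offending update index.
#'
#' @param model a `network_params` or `fusion_model` object.
#' @param train_set list of [labeled_image_pair()] objects.
#' @param config a [train_config()].
#' @param validation_set optional list of pairs; when given, the model with
#'   the highest validation recognition over the recorded checkpoints (the
#'   "optimal number of adoptions") is returned instead of the final one.
#' @return list with `model` (trained) and `history` (data.frame: update,
#'   mean_batch_loss, seconds of elapsed wall time).
#' @export
train_model <- function(model, train_set, config, validation_set = NULL)
  UseMethod("train_model")

# validation-checkpoint bookkeeping shared by both methods
checkpoint_keeper <- function(validation_set) {
  best <- list(score = -Inf, model = NULL)
  list(consider = function(model) {
    if (is.null(validation_set)) return(invisible(NULL))
    sc <- metrics(confusion(predict(model, validation_set),
                            cohort_labels(validation_set)))$recognition
    if (sc > best$score) best <<- list(score = sc, model = model)
    invisible(NULL)
  },
  final = function(model) if (is.null(best$model)) model else best$model)
}

#' @export
train_model.network_params <- function(model, train_set, config,
                                       validation_set = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (config$batch_size > length(train_set))
    stop(sprintf("batch_size %d exceeds training-set size %d",
                 config$batch_size, length(train_set)))
  x_all <- images_to_batch(model, train_set)
  y_all <- cohort_labels(train_set)
  lr <- config$learning_rate
  keeper <- checkpoint_keeper(validation_set)
  history <- new_history()
  t0 <- proc.time()[["elapsed"]]
  withr::with_seed(config$seed, {
    for (it in seq_len(config$iterations)) {
      idx <- sample_batch(train_set, config$batch_size)
      fw <- net_forward(model, x_all[, , , idx, drop = FALSE], labels = y_all[idx])
      if (!is.finite(fw$loss))
        stop(sprintf("non-finite loss at update %d", it))
      g <- net_backward(model, fw)
      model$conv1$kernels <- model$conv1$kernels - lr * g$conv1$kernels
      model$conv1$biases <- model$conv1$biases - lr * g$conv1$biases
      model$conv2$kernels <- model$conv2$kernels - lr * g$conv2$kernels
      model$conv2$biases <- model$conv2$biases - lr * g$conv2$biases
      model$fc1 <- sgd_step(model$fc1, list(weights = g$fc1$weights,
                                            biases = g$fc1$biases), lr)
      model$fc2 <- sgd_step(model$fc2, list(weights = g$fc2$weights,
                                            biases = g$fc2$biases), lr)
      if (it %% config$record_every == 0L || it == config$iterations) {
        history[nrow(history) + 1L, ] <-
          list(it, fw$loss, proc.time()[["elapsed"]] - t0)
        keeper$consider(model)
      }
    }
  })
  list(model = keeper$final(model), history = history)
}

#' @export
train_model.fusion_model <- function(model, train_set, config,
                                     validation_set = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (config$batch_size > length(train_set))
    stop(sprintf("batch_size %d exceeds training-set size %d",
                 config$batch_size, length(train_set)))
  model$freeze_backbones <- config$freeze_backbones
  y_all <- cohort_labels(train_set)
  lr <- config$learning_rate
  frozen <- model$freeze_backbones
  if (frozen) {
    # backbones fixed: extract every subject's features once, train the
    # head on cached 192-vectors (orders of magnitude faster)
    f_ct <- net_forward(model$ct_backbone,
                        images_to_batch(model$ct_backbone, train_set))$features
    f_xr <- net_forward(model$xray_backbone,
                        images_to_batch(model$xray_backbone, train_set))$features
  } else {
    ct_all <- images_to_batch(model$ct_backbone, train_set)
    xr_all <- images_to_batch(model$xray_backbone, train_set)
  }
  keeper <- checkpoint_keeper(validation_set)
  history <- new_history()
  t0 <- proc.time()[["elapsed"]]
  withr::with_seed(config$seed, {
    for (it in seq_len(config$iterations)) {
      idx <- sample_batch(train_set, config$batch_size)
      fw <- if (frozen) {
        fusion_forward_batch(model, NULL, labels = y_all[idx],
                             features = list(ct = f_ct[, idx, drop = FALSE],
                                             xray = f_xr[, idx, drop = FALSE]))
      } else {
        fusion_forward_batch(model, NULL, labels = y_all[idx],
                             ct_batch = ct_all[, , , idx, drop = FALSE],
                             xray_batch = xr_all[, , , idx, drop = FALSE])
      }
      if (!is.finite(fw$loss))
        stop(sprintf("non-finite loss at update %d", it))
      g <- fusion_backward(model, fw)
      model$head_out <- sgd_step(model$head_out,
                                 list(weights = g$head_out$weights,
                                      biases = g$head_out$biases), lr)
      model$head_fc <- sgd_step(model$head_fc,
                                list(weights = g$head_fc$weights,
                                     biases = g$head_fc$biases), lr)
      if (model$trainable_projections)
        for (nm in names(model$proj))
          model$proj[[nm]] <- model$proj[[nm]] - lr * g$proj[[nm]]
      if (!frozen) {
        for (side in c("ct_backbone", "xray_backbone")) {
          gb <- g[[side]]
          model[[side]]$conv1$kernels <- model[[side]]$conv1$kernels - lr * gb$conv1$kernels
          model[[side]]$conv1$biases <- model[[side]]$conv1$biases - lr * gb$conv1$biases
          model[[side]]$conv2$kernels <- model[[side]]$conv2$kernels - lr * gb$conv2$kernels
          model[[side]]$conv2$biases <- model[[side]]$conv2$biases - lr * gb$conv2$biases
          model[[side]]$fc1 <- sgd_step(model[[side]]$fc1,
                                        list(weights = gb$fc1$weights,
                                             biases = gb$fc1$biases), lr)
        }
      }
      if (it %% config$record_every == 0L || it == config$iterations) {
        history[nrow(history) + 1L, ] <-
          list(it, fw$loss, proc.time()[["elapsed"]] - t0)
        keeper$consider(model)
      }
    }
  })
  list(model = keeper$final(model), history = history)
}

# Train the full three-model pipeline on one split: CT and X-ray backbones,
# then the fusion model by parameter transfer.  Returns models + the wall
# time spent on each.
train_pipeline <- function(split, config, fusion_cfg = NULL,
                           models = c("CT-CNN", "XRAY-CNN", "FUSION"),
                           n_classes = 2L) {
  out <- list()
  tm <- c(`CT-CNN` = NA_real_, `XRAY-CNN` = NA_real_, FUSION = NA_real_)
  need_ct <- any(c("CT-CNN", "FUSION") %in% models)
  need_xr <- any(c("XRAY-CNN", "FUSION") %in% models)
  if (need_ct) {
    t <- system.time(res <- train_model(
      build_network(n_classes, seed = config$seed, modality_tag = "CT"),
      split$train, config))[["elapsed"]]
    out$`CT-CNN` <- res$model; tm["CT-CNN"] <- t
  }
  if (need_xr) {
    t <- system.time(res <- train_model(
      build_network(n_classes, seed = config$seed + 1L, modality_tag = "XRAY"),
      split$train, config))[["elapsed"]]
    out$`XRAY-CNN` <- res$model; tm["XRAY-CNN"] <- t
  }
  if ("FUSION" %in% models) {
    spec <- fusion_cfg %||% fusion_spec(seed = config$seed + 2L)
    t <- system.time({
      fm <- build_fusion_model(out$`CT-CNN`, out$`XRAY-CNN`, spec, n_classes,
                               freeze_backbones = config$freeze_backbones)
      res <- train_model(fm, split$train, config)
    })[["elapsed"]]
    # fusion training time includes the transferred backbones' training
    out$FUSION <- res$model
    tm["FUSION"] <- t + sum(tm[c("CT-CNN", "XRAY-CNN")], na.rm = TRUE)
  }
  list(models = out[models[models %in% names(out)]], seconds = tm[models])
}

sweep_row <- function(model_tag, grid_name, grid_value, m, secs, seed) {
  data.frame(model = model_tag, grid_name = grid_name, grid_value = grid_value,
             recognition = m$recognition, sensitivity = m$sensitivity,
             specificity = m$specificity, train_seconds = secs, seed = seed,
             stringsAsFactors = FALSE)
}

#' Iteration-count sweep
#'
#' For each grid value, trains every requested model fresh for that many
#' updates (the fusion model transfers backbones trained at the same grid
#' value; its recorded time includes theirs) and evaluates on the held-out
#' set.
#'
#' @param split a [split_cohort()] result (`train` / `test`).
#' @param iteration_grid ascending positive integers.
#' @param config a [train_config()]; its `iterations` field is overridden by
#'   the grid.
#' @param models subset of `c("CT-CNN", "XRAY-CNN", "FUSION")`.
#' @return data.frame with one row per (grid value, model): model,
#'   grid_name, grid_value, recognition, sensitivity, specificity,
#'   train_seconds, seed.
#' @export
sweep_iterations <- function(split, iteration_grid, config,
                             models = c("CT-CNN", "XRAY-CNN", "FUSION")) {
  if (length(iteration_grid) == 0L) stop("iteration grid is empty")
  if (is.unsorted(iteration_grid, strictly = TRUE))
    stop("iteration grid must be ascending")
  out <- list()
  for (iters in iteration_grid) {
    cfg <- config; cfg$iterations <- as.integer(iters)
    pl <- train_pipeline(split, cfg, models = models)
    for (tag in names(pl$models)) {
      ev <- evaluate(pl$models[[tag]], split$test)
      out[[length(out) + 1L]] <- sweep_row(tag, "iterations", iters,
                                           ev$metrics, pl$seconds[[tag]],
                                           config$seed)
    }
  }
  do.call(rbind, out)
}

#' Batch-size sweep under a fixed epoch budget
#'
#' For each batch size the number of updates is
#' `max(1, round(epochs * n_train / batch))`, so the total number of
#' training examples seen is constant (to batch rounding) and training time
#' falls as batch size rises.
#'
#' @param split a [split_cohort()] result.
#' @param batch_grid ascending batch sizes, each `<=` the training-set size.
#' @param config a [train_config()].
#' @param epochs epoch budget (default 20).
#' @param models subset of `c("CT-CNN", "XRAY-CNN", "FUSION")`.
#' @return data.frame as in [sweep_iterations()] with `grid_name = "batch_size"`.
#' @export
sweep_batches <- function(split, batch_grid, config, epochs = 20,
                          models = c("CT-CNN", "XRAY-CNN", "FUSION")) {
  if (length(batch_grid) == 0L) stop("batch grid is empty")
  n_train <- length(split$train)
  if (any(batch_grid > n_train)) stop("batch size exceeds training-set size")
  out <- list()
  for (b in batch_grid) {
    cfg <- config
    cfg$batch_size <- as.integer(b)
    cfg$iterations <- max(1L, as.integer(round(epochs * n_train / b)))
    pl <- train_pipeline(split, cfg, models = models)
    for (tag in names(pl$models)) {
      ev <- evaluate(pl$models[[tag]], split$test)
      out[[length(out) + 1L]] <- sweep_row(tag, "batch_size", b, ev$metrics,
                                           pl$seconds[[tag]], config$seed)
    }
  }
  do.call(rbind, out)
}
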