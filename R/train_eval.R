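#' Training configuration
#'
#' The training recipe: cross-entropy loss optimized with Adam at learning
#' rate 0.0001 over ten epochs, minibatches of 32 shuffled each epoch with
#' the run seed.
#'
#' @param lr Learning rate (> 0, default 0.0001).
#' @param epochs Number of epochs (>= 1, default 10).
#' @param batch_size Minibatch size (default 32).
#' @param seed Run seed (init, shuffling, dropout).
#' @param eval_test If `TRUE`, also record test accuracy each epoch (used
#'   for accuracy curves over the held-out set).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 10, batch_size = 32, seed = 1,
                         eval_test = FALSE) {
  if (lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed,
                 eval_test = isTRUE(eval_test)),
            class = "train_config")
}

# Integer class labels (1-based) for a task, with the fixed level order that
# defines confusion-matrix orientation: negative/control class first.
task_levels <- function(task) {
  switch(task,
         treatment = c("control", "CBD"),
         condition = c("LPS", "GP120", "Abeta42"),
         stop("task must be 'treatment' or 'condition'", call. = FALSE))
}

encode_labels <- function(labels, levels) {
  y <- as.integer(factor(labels, levels = levels))
  if (anyNA(y)) {
    stop("labels outside the model's classes: ",
         paste(setdiff(unique(labels), levels), collapse = ", "),
         call. = FALSE)
  }
  y
}

#' Train a classifier on a split slice set
#'
#' Minibatch training with softmax cross-entropy and Adam. Each epoch records
#' train loss/accuracy (accumulated over the training passes), validation
#' loss/accuracy, and optionally test accuracy; the parameter snapshot with
#' the best validation accuracy is retained alongside the final-epoch
#' parameters. Reproducible: all randomness comes from `config$seed`.
#'
#' @param spec An [arch_spec()] (e.g. [build_treatment_model()]).
#' @param slices A [slice_set()].
#' @param split A [split_dataset()] result aligned to `slices`.
#' @param config A [train_config()].
#' @param task `"treatment"` or `"condition"`; determines which label column
#'   is the class.
#' @return An object of class `ros_cnn`: the spec, final and best
#'   parameters, the task/levels, and `history` (a `training_history` data
#'   frame: epoch, train_loss, val_loss, train_acc, val_acc, and test_acc
#'   when requested; accuracies in percent).
#' @export
train_model <- function(spec, slices, split, config = train_config(),
                        task = "treatment") {
  stopifnot(inherits(spec, "arch_spec"), inherits(slices, "slice_set"))
  levels <- task_levels(task)
  if (length(levels) != spec$n_classes) {
    stop("spec has ", spec$n_classes, " classes but task '", task,
         "' has ", length(levels), call. = FALSE)
  }
  labcol <- if (task == "treatment") "treatment" else "condition"
  y_all <- encode_labels(slices$info[[labcol]], levels)
  part <- split$partition
  idx_tr <- which(part == "train"); idx_va <- which(part == "val")
  idx_te <- which(part == "test")
  if (length(idx_tr) == 0 || length(idx_va) == 0) {
    stop("train and validation partitions must be nonempty", call. = FALSE)
  }
  H <- dim(slices$images)[1]; W <- dim(slices$images)[2]

  with_seed(config$seed, {
    params <- init_params(spec)
    state <- adam_init(params)
    hist <- list()
    best <- list(acc = -Inf, params = params, epoch = 0L)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(idx_tr)
      tr_loss <- 0; tr_correct <- 0L
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + config$batch_size - 1L, length(ord))
        ib <- ord[i:j]
        xb <- scale_input(slices$images[, , ib, drop = FALSE])
        dim(xb) <- c(H, W, 1L, length(ib))
        yb <- y_all[ib]
        fw <- nn_forward(spec, params, xb, training = TRUE)
        tr_loss <- tr_loss + cross_entropy(fw$logits, yb) * length(ib)
        tr_correct <- tr_correct +
          sum(max.col(fw$logits, ties.method = "first") == yb)
        grads <- nn_backward(spec, params, xb, fw, yb)
        upd <- adam_step(params, grads, state, config$lr)
        params <- upd$params; state <- upd$state
        i <- j + 1L
      }
      va <- nn_predict_probs(spec, params,
                             slices$images[, , idx_va, drop = FALSE])
      va_loss <- -mean(log(pmax(va[cbind(seq_along(idx_va),
                                         y_all[idx_va])], 1e-12)))
      va_acc <- mean(max.col(va, ties.method = "first") == y_all[idx_va])
      row <- data.frame(epoch = ep,
                        train_loss = tr_loss / length(idx_tr),
                        val_loss = va_loss,
                        train_acc = 100 * tr_correct / length(idx_tr),
                        val_acc = 100 * va_acc)
      if (config$eval_test && length(idx_te) > 0) {
        te <- nn_predict_probs(spec, params,
                               slices$images[, , idx_te, drop = FALSE])
        row$test_acc <- 100 * mean(max.col(te, ties.method = "first") ==
                                     y_all[idx_te])
      }
      hist[[ep]] <- row
      if (va_acc > best$acc) {
        best <- list(acc = va_acc, params = params, epoch = ep)
      }
    }
    history <- do.call(rbind, hist)
    class(history) <- c("training_history", "data.frame")
    structure(list(spec = spec, params = params, best_params = best$params,
                   best_epoch = best$epoch, task = task, levels = levels,
                   config = config, history = history),
              class = "ros_cnn")
  })
}

#' @export
print.ros_cnn <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<ros_cnn %s, %d classes> %d epochs; final val acc %.1f%% (best %.1f%% @ epoch %d)\n",
    x$task, x$spec$n_classes, nrow(h), h$val_acc[nrow(h)],
    max(h$val_acc), x$best_epoch))
  invisible(x)
}

#' Class probabilities for a set of slices
#'
#' @param object A trained `ros_cnn`.
#' @param images An (H, W, N) 8-bit image array, a [slice_set()], or a
#'   single `processed_slice`.
#' @param use_best Use the best-validation checkpoint instead of the
#'   final-epoch parameters.
#' @param ... Unused.
#' @return N x n_classes matrix of softmax probabilities (columns named by
#'   class).
#' @export
predict.ros_cnn <- function(object, images, use_best = FALSE, ...) {
  if (inherits(images, "slice_set")) images <- images$images
  if (inherits(images, "processed_slice")) {
    images <- array(images$pixels, c(dim(images$pixels), 1L))
  }
  if (length(dim(images)) == 2L) images <- array(images, c(dim(images), 1L))
  params <- if (use_best) object$best_params else object$params
  pr <- nn_predict_probs(object$spec, params, images)
  colnames(pr) <- object$levels
  pr
}

#' Evaluate a trained model on a test partition
#'
#' Computes test accuracy, the confusion matrix and ROC/AUC. The confusion
#' matrix is oriented with true classes in rows and predicted classes in
#' columns, negative class first — for the binary treatment task that is
#' true negatives upper-left, false positives upper-right, false negatives
#' lower-left, true positives lower-right, with CBD as the positive class.
#' Binary tasks get one ROC curve on the positive-class probability; ternary
#' tasks get one-vs-rest curves per class and their macro-average AUC. A
#' class absent from the test set has an undefined (NA) AUC and is flagged.
#'
#' @param model A trained `ros_cnn`.
#' @param slices A [slice_set()] (evaluated in full), or together with
#'   `split` restricted to its test partition.
#' @param split Optional [split_dataset()]; when given, only slices in the
#'   `"test"` partition are evaluated.
#' @param use_best Evaluate the best-validation checkpoint.
#' @return An object of class `eval_report`: `accuracy` (%), `confusion`,
#'   `auc` (per curve), `macro_auc`, `roc` (data frame of ROC points),
#'   `missing_classes`, `n`.
#' @export
evaluate <- function(model, slices, split = NULL, use_best = FALSE) {
  stopifnot(inherits(model, "ros_cnn"), inherits(slices, "slice_set"))
  labcol <- if (model$task == "treatment") "treatment" else "condition"
  idx <- seq_len(nrow(slices$info))
  if (!is.null(split)) idx <- which(split$partition == "test")
  if (length(idx) == 0) stop("test partition is empty", call. = FALSE)
  truth <- factor(slices$info[[labcol]][idx], levels = model$levels)
  probs <- predict(model, slices$images[, , idx, drop = FALSE],
                   use_best = use_best)
  pred <- factor(model$levels[max.col(probs, ties.method = "first")],
                 levels = model$levels)
  confusion <- table(truth = truth, predicted = pred)
  accuracy <- 100 * mean(pred == truth)
  missing <- model$levels[tabulate(truth, nbins = length(model$levels)) == 0]

  roc_points <- list(); aucs <- c()
  binary <- length(model$levels) == 2L
  targets <- if (binary) model$levels[2] else model$levels
  for (cls in targets) {
    resp <- as.integer(truth == cls)
    if (length(unique(resp)) < 2) {
      aucs[cls] <- NA_real_
      next
    }
    r <- pROC::roc(response = resp, predictor = probs[, cls], quiet = TRUE,
                   direction = "<", levels = c(0, 1))
    aucs[cls] <- as.numeric(pROC::auc(r))
    roc_points[[cls]] <- data.frame(
      class = cls,
      fpr = rev(1 - r$specificities),
      tpr = rev(r$sensitivities))
  }
  if (length(missing)) {
    warning("class(es) absent from the test set, AUC undefined: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(
    accuracy = accuracy, confusion = confusion, auc = aucs,
    macro_auc = mean(aucs, na.rm = TRUE),
    roc = if (length(roc_points)) do.call(rbind, roc_points) else NULL,
    missing_classes = missing, n = length(idx),
    positive = if (length(model$levels) == 2L) model$levels[2] else NA
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy = %.2f%%, macro AUC = %.3f\n",
              x$n, x$accuracy, x$macro_auc))
  print(x$confusion)
  invisible(x)
}

#' Train/validation divergence statistic
#'
#' Summarizes overfitting from a training history: the final-epoch gap
#' `val_loss - train_loss`, the maximum running gap, and a `diverging` flag
#' set when validation loss rises over three or more consecutive epochs
#' while training loss falls.
#'
#' @param history A `training_history` data frame from [train_model()] (or
#'   any data frame with `train_loss` and `val_loss` columns).
#' @return A list: `final_gap`, `max_gap`, `diverging`.
#' @export
overfit_divergence <- function(history) {
  tl <- history$train_loss; vl <- history$val_loss
  stopifnot(length(tl) == length(vl), length(tl) >= 1)
  gap <- vl - tl
  diverging <- FALSE
  if (length(tl) >= 4) {
    run <- 0L
    for (i in 2:length(tl)) {
      if (vl[i] > vl[i - 1] && tl[i] < tl[i - 1]) run <- run + 1L else run <- 0L
      if (run >= 3L) diverging <- TRUE
    }
  }
  list(final_gap = gap[length(gap)], max_gap = max(gap),
       diverging = diverging)
}

#' Save / load a trained model
#'
#' Weights are written as a flat JSON of numeric vectors with a sidecar of
#' the architecture, so checkpoints are plain text and framework-free.
#'
#' @param model A `ros_cnn`.
#' @param path Output path (`.json`).
#' @return `save_model`: the path, invisibly. `load_model`: the `ros_cnn`.
#' @export
save_model <- function(model, path) {
  flat <- function(ps) lapply(ps, function(p) {
    list(dim = dim(p) %||% length(p), data = as.numeric(p))
  })
  obj <- list(spec = unclass(model$spec), task = model$task,
              levels = model$levels, best_epoch = model$best_epoch,
              params = flat(model$params),
              best_params = flat(model$best_params),
              history = as.data.frame(model$history))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unflat <- function(ps) lapply(ps, function(p) {
    d <- unlist(p$dim)
    if (length(d) > 1) array(unlist(p$data), d) else unlist(p$data)
  })
  # rebuild the spec through its constructor to restore the layer list
  spec <- arch_spec(n_classes = obj$spec$n_classes,
                    conv_filters = obj$spec$conv_filters,
                    kernel_sizes = obj$spec$kernel_sizes,
                    pool_size = obj$spec$pool_size,
                    dropout = obj$spec$dropout,
                    hidden = obj$spec$hidden,
                    input_size = obj$spec$input_size)
  history <- obj$history
  class(history) <- c("training_history", "data.frame")
  structure(list(spec = spec, params = unflat(obj$params),
                 best_params = unflat(obj$best_params),
                 best_epoch = obj$best_epoch, task = obj$task,
                 levels = obj$levels, config = NULL, history = history),
            class = "ros_cnn")
}
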