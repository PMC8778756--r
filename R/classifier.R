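# The 11-class progress classifier: a compact convolutional network
# (stacked 3x3 conv + ReLU + 2x2 max-pool blocks, dense head, softmax)
# trained with cross-entropy and Adam, with on-the-fly augmentation of the
# training images. The network kernels live in compiled code; all
# randomness (initialisation, shuffling, augmentation draws) is seeded on
# the R side so training is reproducible.

#' Classifier configuration
#'
#' @param input_side Input resolution the network sees (default 200, the
#'   preprocessing resolution; reducible -- not below 32 -- for desk-scale
#'   runs, with images downscaled at load time). Must halve cleanly through
#'   every block.
#' @param conv_blocks List of `(filters, kernel, pool)` triples. Kernels
#'   must be 3 and pools 2 (the only sizes the compiled kernels implement).
#'   Default: four blocks of 16/32/64/128 filters.
#' @param dense_units Width of the dense head (default 128).
#' @param n_classes Number of classes (default 11).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param lr_decay,decay_every Step decay of the learning rate: multiply by
#'   `lr_decay` every `decay_every` epochs (stabilises the late epochs; set
#'   `lr_decay = 1` to disable).
#' @param patience Early stopping: stop after this many epochs without a new
#'   best validation accuracy.
#' @param augment Apply random flip/rotation/brightness to training images.
#' @param seed Seed covering weight initialisation, shuffling and
#'   augmentation.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(input_side = 200L,
                              conv_blocks = list(c(16L, 3L, 2L),
                                                 c(32L, 3L, 2L),
                                                 c(64L, 3L, 2L),
                                                 c(128L, 3L, 2L)),
                              dense_units = 128L, n_classes = 11L,
                              epochs = 20L, batch_size = 32L,
                              learning_rate = 1e-3, lr_decay = 0.5,
                              decay_every = 10L, patience = 10L,
                              augment = TRUE, seed = 1L) {
  if (input_side < 32)
    stop("`input_side` must be >= 32", call. = FALSE)
  side <- input_side
  for (b in conv_blocks) {
    if (length(b) != 3L || b[2] != 3L || b[3] != 2L)
      stop("conv blocks must be (filters, 3, 2) triples", call. = FALSE)
    if (side %% 2 != 0)
      stop("`input_side` must halve cleanly through every block",
           call. = FALSE)
    side <- side %/% 2L
  }
  structure(list(input_side = as.integer(input_side),
                 conv_blocks = conv_blocks,
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 patience = as.integer(patience),
                 augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# He-normal initial weights for the given geometry.
init_weights <- function(cfg) {
  filters <- vapply(cfg$conv_blocks, `[`, integer(1), 1L)
  side <- cfg$input_side
  cin <- 3L
  Wc <- list(); bc <- list()
  for (f in filters) {
    fan_in <- 9L * cin
    Wc[[length(Wc) + 1L]] <-
      matrix(stats::rnorm(f * fan_in, 0, sqrt(2 / fan_in)), f, fan_in)
    bc[[length(bc) + 1L]] <- numeric(f)
    cin <- f
    side <- side %/% 2L
  }
  flat <- cin * side * side
  list(Wc = Wc, bc = bc,
       Wd = matrix(stats::rnorm(cfg$dense_units * flat, 0, sqrt(2 / flat)),
                   cfg$dense_units, flat),
       bd = numeric(cfg$dense_units),
       Wo = matrix(stats::rnorm(cfg$n_classes * cfg$dense_units, 0,
                                sqrt(2 / cfg$dense_units)),
                   cfg$n_classes, cfg$dense_units),
       bo = numeric(cfg$n_classes))
}

# Flatten a dataset's image array to the (features x batch) matrix the
# compiled kernels expect, downscaling to the model side when needed.
dataset_matrix <- function(dataset, side) {
  d <- dim(dataset$x)
  n <- d[4]
  if (d[1] != side) {
    out <- matrix(0, side * side * 3L, n)
    for (i in seq_len(n))
      out[, i] <- as.numeric(resize_raster(dataset$x[, , , i], side))
    out
  } else {
    matrix(dataset$x, d[1] * d[2] * 3L, n)
  }
}

adam_step <- function(w, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(w = w - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Walk the nested weight list applying Adam to every leaf.
adam_update <- function(weights, grads, states, lr, t) {
  upd <- function(w, g, s) {
    if (is.list(w)) {
      out <- Map(upd, w, g, s)
      list(w = lapply(out, `[[`, "w"), state = lapply(out, `[[`, "state"))
    } else adam_step(w, g, s, lr, t)
  }
  out <- Map(upd, weights, grads, states)
  list(weights = lapply(out, `[[`, "w"),
       states = lapply(out, `[[`, "state"))
}

zero_states <- function(weights) {
  z <- function(w) {
    if (is.list(w)) lapply(w, z)
    else list(m = w * 0, v = w * 0)
  }
  lapply(weights, z)
}

batch_accuracy <- function(weights, X, y, side, batch = 256L) {
  n <- ncol(X)
  correct <- 0L
  loss <- 0
  for (at in seq(1L, n, by = batch)) {
    j <- at:min(n, at + batch - 1L)
    res <- cpp_cnn_batch(weights, X[, j, drop = FALSE], y[j], side, FALSE)
    pred <- max.col(t(res$probs), ties.method = "first") - 1L
    correct <- correct + sum(pred == y[j])
    loss <- loss + res$loss * length(j)
  }
  list(acc = correct / n, loss = loss / n)
}

#' Train the progress classifier
#'
#' Minimises categorical cross-entropy with Adam, augmenting training
#' images on the fly (never validation or test), and keeps the weights of
#' the epoch with the best validation accuracy. Stops early after
#' `patience` epochs without improvement.
#'
#' @param splits A [make_splits()] result.
#' @param cfg A [classifier_config()]; `cfg$n_classes` must cover every
#'   label present and every class must appear in the training split.
#' @return An object of class `decell_cnn`: best `weights`, `config`,
#'   per-epoch `history` (train/val loss and accuracy) and `best_epoch`.
#' @export
train_classifier <- function(splits, cfg = classifier_config()) {
  stopifnot(inherits(splits, "dataset_splits"),
            inherits(cfg, "classifier_config"))
  present <- sort(unique(splits$train$labels))
  if (length(setdiff(0:(cfg$n_classes - 1L), present)))
    stop("every class must appear in the training split", call. = FALSE)
  side <- cfg$input_side
  Xtr_raw <- dataset_matrix(splits$train, side)
  ytr <- splits$train$labels
  Xva <- dataset_matrix(splits$val, side)
  yva <- splits$val$labels
  n <- ncol(Xtr_raw)

  seeds <- derive_seeds(cfg$seed, 2L + cfg$epochs)
  weights <- with_seed(seeds[1], init_weights(cfg))
  states <- zero_states(weights)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  best <- list(acc = -Inf, weights = weights, epoch = 0L)
  t <- 0L
  dimv <- c(side, side, 3L)

  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$learning_rate * cfg$lr_decay^((epoch - 1L) %/% cfg$decay_every)
    ep_seed <- seeds[2L + epoch]
    order_aug <- with_seed(ep_seed, {
      ord <- sample(n)
      aug <- if (cfg$augment) data.frame(
        flip = stats::runif(n) < 0.5,
        angle = stats::runif(n, -15, 15),
        scale = stats::runif(n, 0.85, 1.15)) else NULL
      list(ord = ord, aug = aug)
    })
    ord <- order_aug$ord
    ep_loss <- 0; ep_correct <- 0L
    for (at in seq(1L, n, by = cfg$batch_size)) {
      j <- ord[at:min(n, at + cfg$batch_size - 1L)]
      Xb <- Xtr_raw[, j, drop = FALSE]
      if (cfg$augment) {
        for (k in seq_along(j)) {
          a <- order_aug$aug[j[k], ]
          img <- array(Xb[, k], dimv)
          Xb[, k] <- as.numeric(apply_augment(img, a$flip, a$angle, a$scale))
        }
      }
      res <- cpp_cnn_batch(weights, Xb, ytr[j], side, TRUE)
      if (!is.finite(res$loss))
        stop(sprintf("non-finite loss at epoch %d (batch at %d)",
                     epoch, at), call. = FALSE)
      t <- t + 1L
      upd <- adam_update(weights, res$grads, states, lr, t)
      weights <- upd$weights
      states <- upd$states
      pred <- max.col(t(res$probs), ties.method = "first") - 1L
      ep_correct <- ep_correct + sum(pred == ytr[j])
      ep_loss <- ep_loss + res$loss * length(j)
    }
    val <- batch_accuracy(weights, Xva, yva, side)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = val$loss, val_acc = val$acc))
    if (val$acc > best$acc)
      best <- list(acc = val$acc, weights = weights, epoch = epoch)
    if (epoch - best$epoch >= cfg$patience) break
  }

  structure(list(weights = best$weights, config = cfg, history = history,
                 best_epoch = best$epoch),
            class = "decell_cnn")
}

#' @export
print.decell_cnn <- function(x, ...) {
  np <- sum(rapply(x$weights, length, how = "unlist"))
  cat(sprintf(
    "<decell_cnn: %d classes, input %dx%d, %d parameters>\n",
    x$config$n_classes, x$config$input_side, x$config$input_side, np))
  cat(sprintf("  trained %d epochs, best epoch %d (val acc %.3f)\n",
              nrow(x$history), x$best_epoch,
              x$history$val_acc[x$best_epoch]))
  invisible(x)
}

#' Predict class probabilities
#'
#' @param object A trained `decell_cnn`.
#' @param newdata One H x W x 3 raster, a `decell_dataset`, or a features x
#'   batch matrix already at the model side.
#' @param type `"prob"` for the probability matrix (n x n_classes) or
#'   `"class"` for 0-based hard labels.
#' @param ... Unused.
#' @return Matrix of probabilities (rows sum to 1) or an integer vector.
#' @export
predict.decell_cnn <- function(object, newdata, type = c("prob", "class"),
                               ...) {
  type <- match.arg(type)
  side <- object$config$input_side
  X <- if (inherits(newdata, "decell_dataset")) {
    dataset_matrix(newdata, side)
  } else if (is.matrix(newdata)) {
    if (nrow(newdata) != side * side * 3L)
      stop("matrix input does not match the model input size", call. = FALSE)
    newdata
  } else if (is.array(newdata) && length(dim(newdata)) == 3L) {
    x <- newdata
    if (is.integer(x) || max(x) > 1) x <- x / 255
    if (dim(x)[1] != side) x <- resize_raster(x, side)
    matrix(as.numeric(x), ncol = 1L)
  } else stop("unsupported `newdata`", call. = FALSE)
  n <- ncol(X)
  probs <- matrix(0, n, object$config$n_classes)
  for (at in seq(1L, n, by = 256L)) {
    j <- at:min(n, at + 255L)
    res <- cpp_cnn_batch(object$weights, X[, j, drop = FALSE], integer(0),
                         side, FALSE)
    probs[j, ] <- t(res$probs)
  }
  if (type == "class") max.col(probs, ties.method = "first") - 1L else probs
}

#' Evaluate the classifier on a held-out set
#'
#' Computes the confusion matrix, overall accuracy, and macro-averaged
#' precision, recall and F1 (classes with an empty predicted column
#' contribute 0, never NaN).
#'
#' @param model A trained `decell_cnn`.
#' @param test A `decell_dataset` (disjoint from training by construction
#'   of [make_splits()]).
#' @return An object of class `decell_eval`: `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1` and the `confusion`
#'   matrix (rows = truth, columns = prediction).
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(model, "decell_cnn"),
            inherits(test, "decell_dataset"))
  if (!length(test$labels)) stop("empty test set", call. = FALSE)
  pred <- predict(model, test, type = "class")
  eval_from_predictions(test$labels, pred, model$config$n_classes)
}

# Shared metric computation from hard labels.
eval_from_predictions <- function(truth, pred, n_classes) {
  lev <- 0:(n_classes - 1L)
  confusion <- table(factor(truth, levels = lev),
                     factor(pred, levels = lev))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(truth = lev, predicted = lev)
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(accuracy = sum(tp) / sum(confusion),
                 macro_precision = mean(prec),
                 macro_recall = mean(rec),
                 macro_f1 = mean(f1),
                 confusion = confusion),
            class = "decell_eval")
}

#' @export
print.decell_eval <- function(x, ...) {
  cat(sprintf(
    "<decell_eval: accuracy %.3f, macro P %.3f / R %.3f / F1 %.3f>\n",
    x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}
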