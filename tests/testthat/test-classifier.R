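# Builds tiny in-memory datasets; the network itself is checked against
# finite differences before any training property is asserted.

toy_dataset <- function(n_per_class = 20L, side = 32L, seed = 1L) {
  # solid-black vs solid-white images with slight noise
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(0, c(side, side, 3L, n))
  labels <- integer(n)
  for (i in seq_len(n)) {
    lab <- (i - 1L) %% 2L
    base <- if (lab == 0L) 0.05 else 0.95
    x[, , , i] <- pmin(pmax(base + stats::rnorm(side * side * 3, 0, 0.02),
                            0), 1)
    labels[i] <- lab
  }
  decellwatch:::new_dataset(x, labels,
                            data.frame(session_id = "toy",
                                       cycle = seq_len(n), step = 0L))
}

test_that("analytic gradients match finite differences", {
  set.seed(11)
  side <- 8L
  cfg <- list(filters = c(2L, 3L))
  # hand-built tiny weight set
  w <- list(Wc = list(matrix(stats::rnorm(2 * 27, 0, 0.3), 2, 27),
                      matrix(stats::rnorm(3 * 18, 0, 0.3), 3, 18)),
            bc = list(stats::rnorm(2, 0, 0.1), stats::rnorm(3, 0, 0.1)),
            Wd = matrix(stats::rnorm(4 * 12, 0, 0.3), 4, 12),
            bd = stats::rnorm(4, 0, 0.1),
            Wo = matrix(stats::rnorm(3 * 4, 0, 0.3), 3, 4),
            bo = stats::rnorm(3, 0, 0.1))
  X <- matrix(stats::runif(side * side * 3 * 2), ncol = 2)
  y <- c(0L, 2L)
  res <- decellwatch:::cpp_cnn_batch(w, X, y, side, TRUE)

  loss_at <- function(wmod) decellwatch:::cpp_cnn_batch(wmod, X, y, side,
                                                        FALSE)$loss
  eps <- 1e-6
  check_leaf <- function(path, k) {
    wp <- w
    wref <- if (length(path) == 2L) w[[path[[1]]]][[path[[2]]]]
         else w[[path[[1]]]]
    g <- if (length(path) == 2L) res$grads[[path[[1]]]][[path[[2]]]]
         else res$grads[[path[[1]]]]
    for (idx in k) {
      wplus <- wref; wplus[idx] <- wplus[idx] + eps
      wminus <- wref; wminus[idx] <- wminus[idx] - eps
      if (length(path) == 2L) {
        wp[[path[[1]]]][[path[[2]]]] <- wplus
        lp <- loss_at(wp)
        wp[[path[[1]]]][[path[[2]]]] <- wminus
        lm <- loss_at(wp)
        wp[[path[[1]]]][[path[[2]]]] <- wref
      } else {
        wp[[path[[1]]]] <- wplus
        lp <- loss_at(wp)
        wp[[path[[1]]]] <- wminus
        lm <- loss_at(wp)
        wp[[path[[1]]]] <- wref
      }
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(g[idx] - fd), 1e-6 + 1e-4 * abs(fd))
    }
  }
  check_leaf(list("Wc", 1L), c(1L, 10L, 54L))
  check_leaf(list("Wc", 2L), c(2L, 30L))
  check_leaf(list("bc", 1L), 1L)
  check_leaf("Wd", c(1L, 25L))
  check_leaf("bd", 2L)
  check_leaf("Wo", c(3L, 12L))
  check_leaf("bo", 1L)
})

test_that("configuration constraints are enforced", {
  expect_error(classifier_config(input_side = 16L), ">= 32")
  expect_error(classifier_config(conv_blocks = list(c(8L, 5L, 2L))),
               "triples")
  expect_error(classifier_config(input_side = 36L,
                                 conv_blocks = list(c(8L, 3L, 2L),
                                                    c(8L, 3L, 2L),
                                                    c(8L, 3L, 2L))),
               "halve")
})

test_that("a separable two-class problem is learned within 3 epochs", {
  ds <- toy_dataset(n_per_class = 60L)
  sp <- make_splits(ds, seed = 1L)
  cfg <- classifier_config(input_side = 32L,
                           conv_blocks = list(c(4L, 3L, 2L)),
                           dense_units = 8L, n_classes = 2L,
                           epochs = 3L, batch_size = 8L,
                           learning_rate = 0.01, augment = FALSE,
                           seed = 2L)
  mod <- train_classifier(sp, cfg)
  expect_equal(max(mod$history$val_acc), 1.0)
  expect_lte(nrow(mod$history), 3L)
  # training accuracy does not degrade over epochs
  expect_gte(mod$history$train_acc[nrow(mod$history)],
             mod$history$train_acc[1])

  # determinism of the whole training run under the seed
  mod2 <- train_classifier(sp, cfg)
  expect_equal(mod$history$train_loss[1], mod2$history$train_loss[1])
  expect_identical(mod$weights, mod2$weights)
})

test_that("predictions live on the probability simplex", {
  ds <- toy_dataset(n_per_class = 10L)
  sp <- make_splits(ds, seed = 1L)
  cfg <- classifier_config(input_side = 32L,
                           conv_blocks = list(c(4L, 3L, 2L)),
                           dense_units = 8L, n_classes = 2L,
                           epochs = 1L, augment = FALSE, seed = 3L)
  mod <- train_classifier(sp, cfg)
  p <- predict(mod, sp$test)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)

  # duplicate input -> identical output
  img <- ds$x[, , , 1]
  expect_identical(predict(mod, img), predict(mod, img))

  expect_error(predict(mod, matrix(0, 10, 2)), "input size")
})

test_that("training refuses a split with an absent class", {
  ds <- toy_dataset(n_per_class = 10L)
  sp <- make_splits(ds, seed = 1L)
  cfg <- classifier_config(input_side = 32L,
                           conv_blocks = list(c(4L, 3L, 2L)),
                           dense_units = 8L, n_classes = 3L,
                           epochs = 1L, seed = 1L)
  expect_error(train_classifier(sp, cfg), "every class")
})

test_that("evaluation metrics are exact on oracle and random predictors", {
  # oracle predictor: perfect diagonal
  truth <- rep(0:10, each = 30L)
  ev <- decellwatch:::eval_from_predictions(truth, truth, 11L)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$macro_f1, 1)
  expect_true(all(ev$confusion[upper.tri(ev$confusion)] == 0))
  expect_equal(as.integer(diag(ev$confusion)), rep(30L, 11L))

  # uniform-random predictor on a balanced 11-class set: accuracy near 1/11
  set.seed(123)
  accs <- replicate(100, {
    pred <- sample(0:10, length(truth), replace = TRUE)
    decellwatch:::eval_from_predictions(truth, pred, 11L)$accuracy
  })
  # binomial 99% band around 1/11 for the mean of 100 draws of n=330
  p <- 1 / 11
  se <- sqrt(p * (1 - p) / (330 * 100))
  expect_lt(abs(mean(accs) - p), 2.58 * se * 1.5)

  # confusion row sums are the per-class test counts
  pred <- sample(0:10, length(truth), replace = TRUE)
  ev2 <- decellwatch:::eval_from_predictions(truth, pred, 11L)
  expect_equal(as.integer(rowSums(ev2$confusion)), rep(30L, 11L))
  expect_equal(ev2$accuracy, sum(diag(ev2$confusion)) / sum(ev2$confusion))

  # empty predicted class contributes zero precision, not NaN
  ev3 <- decellwatch:::eval_from_predictions(c(0L, 0L, 1L), c(0L, 0L, 0L),
                                             2L)
  expect_equal(ev3$macro_precision, mean(c(2 / 3, 0)))
  expect_false(any(is.nan(c(ev3$macro_precision, ev3$macro_recall,
                            ev3$macro_f1))))
})

test_that("metrics agree with an independent recomputation", {
  set.seed(9)
  truth <- sample(0:10, 400, replace = TRUE)
  pred <- ifelse(stats::runif(400) < 0.7, truth,
                 sample(0:10, 400, replace = TRUE))
  ev <- decellwatch:::eval_from_predictions(truth, pred, 11L)
  cm <- ev$confusion
  # recompute every metric from the confusion matrix alone
  accuracy <- sum(diag(cm)) / sum(cm)
  precs <- recs <- f1s <- numeric(11)
  for (k in 1:11) {
    tp <- cm[k, k]
    precs[k] <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    recs[k] <- if (sum(cm[k, ]) > 0) tp / sum(cm[k, ]) else 0
    f1s[k] <- if (precs[k] + recs[k] > 0)
      2 * precs[k] * recs[k] / (precs[k] + recs[k]) else 0
  }
  expect_equal(ev$accuracy, accuracy)
  expect_equal(ev$macro_precision, mean(precs))
  expect_equal(ev$macro_recall, mean(recs))
  expect_equal(ev$macro_f1, mean(f1s))
})

test_that("label permutation drives accuracy to chance", {
  ds <- toy_dataset(n_per_class = 25L)
  set.seed(77)
  ds$labels <- sample(ds$labels)   # break the image-label association
  sp <- make_splits(ds, seed = 1L)
  cfg <- classifier_config(input_side = 32L,
                           conv_blocks = list(c(4L, 3L, 2L)),
                           dense_units = 8L, n_classes = 2L,
                           epochs = 3L, learning_rate = 0.01,
                           augment = FALSE, seed = 5L)
  mod <- train_classifier(sp, cfg)
  ev <- evaluate_classifier(mod, sp$test)
  expect_lt(abs(ev$accuracy - 0.5), 0.35)
})
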