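#' Train/test split specification
#'
#' @param test_fraction held-out fraction, in `(0, 0.5)`; the default 1/6
#'   gives the 5:1 train:test ratio.
#' @param seed integer RNG seed.
#' @param group_aware if `TRUE`, whole groups (synthetic patients) are
#'   assigned to one side, so no group spans the split.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 1 / 6, seed = 1, group_aware = FALSE) {
  if (test_fraction <= 0 || test_fraction >= 0.5) {
    abort("`test_fraction` must be in (0, 0.5).")
  }
  structure(list(test_fraction = test_fraction, seed = as.integer(seed),
                 group_aware = isTRUE(group_aware)),
            class = "split_spec")
}

#' Split a feature table into train and test sets
#'
#' Disjoint and exhaustive. The default mode samples tiles within each
#' class (stratified); group-aware mode assigns whole groups to the test
#' side until the target fraction is reached, so no group leaks across.
#'
#' @param features tibble with a `label` column (0/1), optional `group_id`,
#'   and feature columns `f1...fn`.
#' @param spec a [split_spec()].
#' @return A list with `train` and `test` tibbles.
#' @export
split_dataset <- function(features, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- nrow(features)
  if (n < 12) abort("at least 12 samples are required to split.")
  with_seed(spec$seed, {
    if (spec$group_aware) {
      if (!"group_id" %in% names(features)) {
        abort("group-aware split requires a `group_id` column.")
      }
      groups <- sample(unique(features$group_id))
      sizes <- table(features$group_id)[groups]
      take <- groups[cumsum(sizes) <= max(spec$test_fraction * n, min(sizes))]
      if (length(take) == 0) take <- groups[1]
      test_idx <- which(features$group_id %in% take)
    } else {
      test_idx <- unlist(lapply(split(seq_len(n), features$label), function(ix) {
        k <- max(1L, round(length(ix) * spec$test_fraction))
        sample(ix, k)
      }), use.names = FALSE)
    }
    train <- features[-test_idx, , drop = FALSE]
    test <- features[test_idx, , drop = FALSE]
    if (length(unique(train$label)) < 2 || length(unique(test$label)) < 2) {
      abort("a class is absent from one side of the split.")
    }
    list(train = train, test = test)
  })
}

#' Train a linear support vector machine on pooled features
#'
#' A hinge-loss linear SVM (libsvm via e1071) on the feature columns;
#' features are standardized with train-set statistics by default.
#'
#' @param train training tibble from [split_dataset()].
#' @param cost soft-margin regularization parameter.
#' @param standardize scale features to zero mean / unit variance.
#' @return A model of class `sc_svm`.
#' @export
train_linear_svm <- function(train, cost = 1, standardize = TRUE) {
  cols <- feature_columns(train)
  if (length(unique(train$label)) < 2) abort("both classes must be present.")
  x <- as.matrix(train[, cols])
  keep <- apply(x, 2, function(v) sd(v) > 0)
  if (!any(keep)) abort("all features are constant.")
  model <- e1071::svm(x[, keep, drop = FALSE],
                      factor(train$label, levels = c(0, 1)),
                      kernel = "linear", cost = cost, scale = standardize)
  structure(list(model = model, feature_cols = cols[keep],
                 n_train = nrow(train), classifier = "svm",
                 config = list(cost = cost, standardize = standardize)),
            class = "sc_svm")
}

#' @export
predict.sc_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$feature_cols])
  as.integer(as.character(predict(object$model, x)))
}

#' Train a one-hidden-layer MLP with dropout and softmax
#'
#' A fully connected hidden layer (ReLU), a dropout layer active during
#' training only, and a 2-way softmax output trained with cross-entropy
#' (Adam, mini-batches). A stratified validation carve-out drives early
#' stopping; the best-validation weights are restored. Fully deterministic
#' given `seed`.
#'
#' @param train training tibble from [split_dataset()].
#' @param hidden hidden-layer width.
#' @param dropout_rate probability of dropping a hidden unit per step.
#' @param epochs maximum training epochs.
#' @param seed integer RNG seed.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param standardize scale features with train-set statistics.
#' @param validation_fraction carve-out for early stopping (0 disables).
#' @param patience epochs without validation improvement before stopping.
#' @return A model of class `sc_mlp`.
#' @export
train_mlp <- function(train, hidden = 512, dropout_rate = 0.5, epochs = 100,
                      seed = 1, learning_rate = 1e-3, batch_size = 32,
                      standardize = TRUE, validation_fraction = 0.1,
                      patience = 15) {
  cols <- feature_columns(train)
  if (length(unique(train$label)) < 2) abort("both classes must be present.")
  x <- as.matrix(train[, cols])
  y <- as.integer(train$label)
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  if (!standardize) {
    mu <- rep(0, ncol(x)); sg <- rep(1, ncol(x))
  }
  x <- sweep(sweep(x, 2, mu), 2, sg, `/`)
  with_seed(seed, {
    n <- nrow(x); d <- ncol(x)
    val_idx <- integer(0)
    if (validation_fraction > 0 && n >= 20) {
      val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
        sample(ix, max(1L, round(length(ix) * validation_fraction)))
      }), use.names = FALSE)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    W1 <- matrix(rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(rnorm(hidden * 2, sd = sqrt(2 / hidden)), hidden, 2)
    b2 <- numeric(2)
    adam <- list(t = 0)
    moments <- lapply(list(W1, b1, W2, b2), function(p) {
      list(m = p * 0, v = p * 0)
    })
    forward <- function(X, drop) {
      H <- pmax(X %*% W1 + rep(b1, each = nrow(X)), 0)
      if (drop && dropout_rate > 0) {
        M <- matrix(runif(length(H)) >= dropout_rate, nrow(H)) / (1 - dropout_rate)
        H <- H * M
        attr(H, "mask") <- M
      }
      Z <- H %*% W2 + rep(b2, each = nrow(H))
      Z <- Z - apply(Z, 1, max)
      P <- exp(Z) / rowSums(exp(Z))
      list(H = H, P = P)
    }
    val_loss <- function() {
      fw <- forward(x[val_idx, , drop = FALSE], drop = FALSE)
      -mean(log(pmax(fw$P[cbind(seq_along(val_idx), y[val_idx] + 1)], 1e-12)))
    }
    best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2, wait = 0)
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      for (start in seq(1, length(ord), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, length(ord))]
        Xb <- x[bi, , drop = FALSE]
        yb <- y[bi]
        fw <- forward(Xb, drop = TRUE)
        G <- fw$P
        G[cbind(seq_along(bi), yb + 1)] <- G[cbind(seq_along(bi), yb + 1)] - 1
        G <- G / length(bi)
        gW2 <- crossprod(fw$H, G)
        gb2 <- colSums(G)
        dH <- G %*% t(W2)
        mask <- attr(fw$H, "mask")
        if (!is.null(mask)) dH <- dH * mask
        dH <- dH * (fw$H > 0)
        gW1 <- crossprod(Xb, dH)
        gb1 <- colSums(dH)
        adam$t <- adam$t + 1
        grads <- list(gW1, gb1, gW2, gb2)
        params <- list(W1, b1, W2, b2)
        for (j in 1:4) {
          moments[[j]]$m <- 0.9 * moments[[j]]$m + 0.1 * grads[[j]]
          moments[[j]]$v <- 0.999 * moments[[j]]$v + 0.001 * grads[[j]]^2
          mhat <- moments[[j]]$m / (1 - 0.9^adam$t)
          vhat <- moments[[j]]$v / (1 - 0.999^adam$t)
          params[[j]] <- params[[j]] - learning_rate * mhat / (sqrt(vhat) + 1e-8)
        }
        W1 <- params[[1]]; b1 <- params[[2]]; W2 <- params[[3]]; b2 <- params[[4]]
      }
      if (length(val_idx) > 0) {
        vl <- val_loss()
        if (vl < best$loss - 1e-6) {
          best <- list(loss = vl, W1 = W1, b1 = b1, W2 = W2, b2 = b2, wait = 0)
        } else {
          best$wait <- best$wait + 1
          if (best$wait >= patience) break
        }
      }
    }
    if (length(val_idx) > 0 && is.finite(best$loss)) {
      W1 <- best$W1; b1 <- best$b1; W2 <- best$W2; b2 <- best$b2
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, mu = mu, sg = sg,
                   feature_cols = cols, n_train = nrow(train),
                   classifier = "mlp",
                   config = list(hidden = hidden, dropout_rate = dropout_rate,
                                 epochs = epochs, seed = seed,
                                 learning_rate = learning_rate,
                                 batch_size = batch_size,
                                 standardize = standardize)),
              class = "sc_mlp")
  })
}

#' @export
predict.sc_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$feature_cols])
  x <- sweep(sweep(x, 2, object$mu), 2, object$sg, `/`)
  H <- pmax(x %*% object$W1 + rep(object$b1, each = nrow(x)), 0)
  Z <- H %*% object$W2 + rep(object$b2, each = nrow(x))
  as.integer(max.col(Z, ties.method = "first") - 1L)
}

#' Evaluate a classifier on a held-out test set
#'
#' @param model an `sc_svm` or `sc_mlp`.
#' @param test test tibble from [split_dataset()].
#' @return A list of class `sc_eval`: `accuracy` and `chance_rate` in
#'   percent (chance = majority-class frequency of the test set), sample
#'   counts, per-class counts, classifier tag and config snapshot.
#' @export
evaluate <- function(model, test) {
  if (nrow(test) == 0) abort("test set is empty.")
  pred <- predict(model, test)
  truth <- as.integer(test$label)
  acc <- 100 * mean(pred == truth)
  per_class <- dplyr::count(tibble::tibble(label = truth), .data$label,
                            name = "n")
  chance <- 100 * max(per_class$n) / nrow(test)
  structure(list(accuracy = acc, chance_rate = chance,
                 n_train = model$n_train, n_test = nrow(test),
                 per_class = per_class, classifier = model$classifier,
                 config = model$config),
            class = "sc_eval")
}

#' @export
print.sc_eval <- function(x, ...) {
  cat(sprintf("<sc_eval: %s accuracy %.2f%% (chance %.2f%%), n_test = %d>\n",
              x$classifier, x$accuracy, x$chance_rate, x$n_test))
  invisible(x)
}

#' @export
glance.sc_eval <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, accuracy = x$accuracy,
                 chance_rate = x$chance_rate, n_train = x$n_train,
                 n_test = x$n_test)
}

#' @export
tidy.sc_eval <- function(x, ...) x$per_class

#' Relative error reduction between two accuracies
#'
#' `100 * ((100 - baseline) - (100 - new)) / (100 - baseline)`: the percent
#' of the baseline's error eliminated by the new classifier. Positive when
#' the new accuracy is higher.
#'
#' @param acc_baseline,acc_new accuracies in percent; the baseline must be
#'   below 100.
#' @return A single number (percent).
#' @export
error_reduction <- function(acc_baseline, acc_new) {
  if (!is.numeric(acc_baseline) || !is.numeric(acc_new)) {
    abort("accuracies must be numeric.")
  }
  if (acc_baseline >= 100) abort("baseline accuracy must be below 100%.")
  if (acc_baseline < 0 || acc_new < 0 || acc_new > 100) {
    abort("accuracies must lie in [0, 100].")
  }
  100 * ((100 - acc_baseline) - (100 - acc_new)) / (100 - acc_baseline)
}

#' Repeated split/train/evaluate benchmark
#'
#' Convenience wrapper running [split_dataset()], one classifier, and
#' [evaluate()] over `repeats` seeded splits; accuracy is then naturally
#' reported as mean over repeats.
#'
#' @param features feature tibble.
#' @param classifier `"svm"` or `"mlp"`.
#' @param spec base [split_spec()]; its seed is advanced per repeat.
#' @param repeats number of independent splits.
#' @param ... passed to the trainer.
#' @return A tibble with one row per repeat: `repeat_id`, `seed`,
#'   `classifier`, `accuracy`, `chance_rate`, `n_train`, `n_test`.
#' @export
benchmark_features <- function(features, classifier = c("svm", "mlp"),
                               spec = split_spec(), repeats = 1, ...) {
  classifier <- match.arg(classifier)
  purrr::map_dfr(seq_len(repeats), function(r) {
    sp <- spec
    sp$seed <- derive_seed(spec$seed, r)
    parts <- split_dataset(features, sp)
    model <- if (classifier == "svm") {
      train_linear_svm(parts$train, ...)
    } else {
      train_mlp(parts$train, seed = derive_seed(sp$seed, 2), ...)
    }
    ev <- evaluate(model, parts$test)
    dplyr::mutate(glance(ev), repeat_id = r, seed = sp$seed, .before = 1)
  })
}
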