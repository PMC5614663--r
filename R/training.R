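#' Training configuration
#'
#' Mini-batch SGD with momentum and "step" learning-rate decay: the rate
#' is multiplied by `gamma` every `step_size` epochs. The published
#' recipe trains with batch size 32, base rate 0.001 and 50 epochs; the
#' decay constants are the CIFAR-10-quick convention. The momentum and
#' weight-decay knobs are exposed separately (momentum 0.9,
#' weight decay 0.004; decay applies to kernels only, not biases).
#'
#' @param batch_size Mini-batch size N.
#' @param base_lr Base learning rate.
#' @param step_size Epochs between learning-rate drops.
#' @param gamma Learning-rate multiplier at each drop.
#' @param momentum SGD momentum in `[0, 1)`.
#' @param weight_decay L2 penalty coefficient on kernel weights.
#' @param epochs Training epochs.
#' @param seed Integer RNG seed controlling initialization and shuffles.
#' @param eval_every Evaluate test accuracy every this many epochs (the
#'   final epoch is always evaluated); other epochs record `NA`.
#' @return A `"train_config"` list.
#' @export
train_config <- function(batch_size = 32L, base_lr = 0.001,
                         step_size = 20L, gamma = 0.1, momentum = 0.9,
                         weight_decay = 0.004, epochs = 50L, seed = 1L,
                         eval_every = 1L) {
  stopifnot(batch_size >= 1, base_lr > 0, step_size >= 1, gamma > 0,
            momentum >= 0, momentum < 1, weight_decay >= 0, epochs >= 1,
            eval_every >= 1)
  structure(list(batch_size = as.integer(batch_size), base_lr = base_lr,
                 step_size = as.integer(step_size), gamma = gamma,
                 momentum = momentum, weight_decay = weight_decay,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 eval_every = as.integer(eval_every)),
            class = "train_config")
}

#' Summed cross-entropy loss
#'
#' `sum_i -log(p_i[label_i])`: the loss is the SUM over the supplied
#' samples (not the mean), matching the convention under which training
#' loss is reported; the optimizer scales gradients by `1/N` internally.
#' Posterior entries are floored at `1e-12` before the log so the loss
#' stays finite.
#'
#' @param posteriors `N x L` matrix of class posteriors (rows sum to 1).
#' @param labels Integer vector of `N` 0-based class labels.
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(posteriors, labels) {
  posteriors <- rbind(posteriors)
  labels <- as.integer(labels)
  if (nrow(posteriors) != length(labels))
    stop("posterior rows and labels differ in length")
  if (any(labels < 0) || any(labels >= ncol(posteriors)))
    stop("label out of range [0, L)")
  p <- posteriors[cbind(seq_along(labels), labels + 1L)]
  sum(-log(pmax(p, 1e-12)))
}

check_init_shapes <- function(spec, init) {
  for (ly in learnable_layers(spec)) {
    shp <- layer_weight_shapes(ly)
    entry <- init[[ly$name]]
    if (is.null(entry)) stop("init is missing layer ", ly$name)
    for (nm in names(shp)) {
      if (is.null(shp[[nm]])) next
      have <- entry[[nm]]
      want <- shp[[nm]]
      dims_ok <- !is.null(have) &&
        (identical(as.integer(dim(have)), as.integer(want)) ||
           (is.null(dim(have)) && length(have) == want))
      if (!dims_ok)
        stop(sprintf("init shape mismatch at %s$%s", ly$name, nm))
    }
  }
  invisible(TRUE)
}

#' Train a network with mini-batch SGD
#'
#' Minimizes the summed cross-entropy ([cross_entropy_loss()]) over
#' shuffled mini-batches with momentum SGD and step learning-rate decay.
#' When `init` is supplied, optimization starts from it (pretrained-model
#' semantics, as used by the IRL loop); otherwise weights are
#' Xavier-initialized from `config$seed`. Fully reproducible for a fixed
#' seed on a fixed BLAS.
#'
#' @param spec A `"gpdnet_spec"`.
#' @param train_set Training [image_set()] (non-empty).
#' @param config A [train_config()].
#' @param init Optional starting `"weight_store"` matching `spec`.
#' @param test_set Optional [image_set()] whose accuracy is recorded in
#'   the history.
#' @return `list(weights, history)` where `history` is a data frame with
#'   one row per epoch: `epoch`, `loss` (summed over the training set)
#'   and `accuracy` (test accuracy or `NA`).
#' @export
train_network <- function(spec, train_set, config = train_config(),
                          init = NULL, test_set = NULL) {
  stopifnot(inherits(spec, "gpdnet_spec"),
            inherits(train_set, "gpd_image_set"),
            inherits(config, "train_config"))
  if (length(train_set) == 0L) stop("training set is empty")
  if (!is.null(init)) check_init_shapes(spec, init)

  weights <- if (is.null(init)) initialize_weights(spec, config$seed)
             else init
  velocity <- ws_map(weights, function(a) { a[] <- 0; a },
                     include_bias = TRUE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n <- length(train_set)
  L <- spec$num_classes
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        accuracy = NA_real_)
  for (epoch in seq_len(config$epochs)) {
    lr <- config$base_lr * config$gamma^((epoch - 1L) %/% config$step_size)
    ord <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      ids <- ord[start:min(start + config$batch_size - 1L, n)]
      nb <- length(ids)
      xb <- train_set$images[, , , ids, drop = FALSE]
      yb <- train_set$labels[ids]
      fw <- nn_forward(spec, weights, xb, keep_cache = TRUE)
      epoch_loss <- epoch_loss + cross_entropy_loss(fw$post, yb)
      dlogits <- t(fw$post)                      # L x nb
      dlogits[cbind(yb + 1L, seq_len(nb))] <-
        dlogits[cbind(yb + 1L, seq_len(nb))] - 1
      dlogits <- dlogits / nb
      grads <- nn_backward(spec, weights, fw$cache, dlogits)
      for (lname in names(grads)) {
        for (nm in names(grads[[lname]])) {
          g <- grads[[lname]][[nm]]
          if (startsWith(nm, "W") && config$weight_decay > 0)
            g <- g + config$weight_decay * weights[[lname]][[nm]]
          v <- config$momentum * velocity[[lname]][[nm]] - lr * g
          velocity[[lname]][[nm]] <- v
          weights[[lname]][[nm]] <- weights[[lname]][[nm]] + v
        }
      }
    }
    history$loss[epoch] <- epoch_loss
    if (!is.null(test_set) &&
        (epoch %% config$eval_every == 0L || epoch == config$epochs))
      history$accuracy[epoch] <- evaluate_accuracy(spec, weights, test_set)
  }
  list(weights = weights, history = history)
}

#' Top-1 classification accuracy
#'
#' Fraction of images whose maximum-posterior class equals the label.
#' Ties break toward the lowest class index, so an all-zero network
#' (uniform posterior) predicts class 0 for every image.
#'
#' @inheritParams train_network
#' @param weights A `"weight_store"`.
#' @param test_set Non-empty [image_set()].
#' @param batch_size Evaluation batch size.
#' @return Fraction in `[0, 1]`.
#' @export
evaluate_accuracy <- function(spec, weights, test_set, batch_size = 128L) {
  stopifnot(inherits(test_set, "gpd_image_set"))
  n <- length(test_set)
  if (n == 0L) stop("test set is empty")
  correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1L, n)
    post <- nn_forward(spec, weights,
                       test_set$images[, , , ids, drop = FALSE])$post
    pred <- max.col(post, ties.method = "first") - 1L
    correct <- correct + sum(pred == test_set$labels[ids])
  }
  correct / n
}

#' Fit a GPDNet classifier
#'
#' The main model-fitting entry point: builds the requested variant,
#' trains it with [train_network()] and returns a fitted-model object
#' with the usual methods (`print`, `summary`, `coef`, `predict`,
#' `plot`).
#'
#' @param train_set Training [image_set()].
#' @param variant `"fire"` (compact, fully convolutional, 14,368 kernel
#'   weights for 3 classes) or `"baseline"` (dense-head CIFAR-10-quick
#'   style, 144,928).
#' @param config A [train_config()].
#' @param test_set Optional held-out [image_set()] tracked during
#'   training.
#' @param init Optional starting `"weight_store"`.
#' @param spec Optional explicit `"gpdnet_spec"` overriding `variant`.
#' @return An object of class `"gpdnet"`: list with `spec`, `weights`,
#'   `history`, `config`, `variant`.
#' @examples
#' \donttest{
#' set <- generate_synthetic_gpd(60, seed = 1, difficulty = "easy")
#' sp <- split_train_test(set, per_class_test = 20, seed = 1)
#' fit <- gpdnet(sp$train, config = train_config(epochs = 3, seed = 1),
#'               test_set = sp$test)
#' print(fit)
#' }
#' @export
gpdnet <- function(train_set, variant = c("fire", "baseline"),
                   config = train_config(), test_set = NULL, init = NULL,
                   spec = NULL) {
  variant <- match.arg(variant)
  if (is.null(spec))
    spec <- build_gpdnet(length(train_set$class_names),
                         use_fire = variant == "fire")
  res <- train_network(spec, train_set, config, init = init,
                       test_set = test_set)
  structure(list(spec = spec, weights = res$weights,
                 history = res$history, config = config,
                 variant = variant, call = match.call()),
            class = "gpdnet")
}

#' @export
print.gpdnet <- function(x, ...) {
  cat(sprintf("fitted GPDNet (%s variant), %d classes\n", x$variant,
              x$spec$num_classes))
  cat(sprintf("kernel weights: %d; epochs: %d; final loss: %.4f\n",
              count_parameters(x$spec), nrow(x$history),
              x$history$loss[nrow(x$history)]))
  acc <- x$history$accuracy[nrow(x$history)]
  if (!is.na(acc)) cat(sprintf("final test accuracy: %.4f\n", acc))
  invisible(x)
}

#' @export
summary.gpdnet <- function(object, ...) {
  print(object)
  print(object$spec)
  invisible(object)
}

#' @export
coef.gpdnet <- function(object, ...) object$weights

#' Predict from a fitted GPDNet
#'
#' @param object A fitted `"gpdnet"`.
#' @param newdata An [image_set()] or `(H, W, 3[, N])` array.
#' @param type `"prob"` for the posterior matrix, `"class"` for 0-based
#'   predicted labels (ties to the lowest index).
#' @param ... Unused.
#' @return `N x L` posterior matrix or integer vector of labels.
#' @export
predict.gpdnet <- function(object, newdata, type = c("prob", "class"),
                           ...) {
  type <- match.arg(type)
  post <- forward(object$spec, object$weights, newdata)
  if (type == "prob") post
  else max.col(post, ties.method = "first") - 1L
}

#' @export
plot.gpdnet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch",
       ylab = "training loss (sum)", main = "loss", ...)
  if (any(!is.na(h$accuracy)))
    plot(h$epoch, h$accuracy, type = "b", xlab = "epoch",
         ylab = "test accuracy", ylim = c(0, 1), main = "accuracy", ...)
  invisible(x)
}

#' @export
residuals.gpdnet <- function(object, newdata, ...) {
  post <- predict(object, newdata)
  if (!inherits(newdata, "gpd_image_set"))
    stop("residuals need a labeled image set")
  1 - post[cbind(seq_len(nrow(post)), newdata$labels + 1L)]
}
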