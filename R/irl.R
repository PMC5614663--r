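#' IRL configuration
#'
#' Iterative reinforced learning: zero every weight whose magnitude is
#' at or below a threshold, then retrain with the modified model as the
#' pretrained start; repeat. Zeroed weights are free to relearn — no
#' sparsity mask is ever applied (deliberately unlike dense-sparse-dense
#' training, whose masked sparse stage IRL omits).
#'
#' @param threshold Magnitude cutoff (default 0.001); the comparison is
#'   inclusive, `|w| <= threshold`.
#' @param iterations Number of prune-and-retrain iterations (>= 1).
#' @param apply_to_biases Also prune bias vectors (default `FALSE`:
#'   kernels only, matching the weights-only parameter accounting).
#' @return An `"irl_config"` list.
#' @export
irl_config <- function(threshold = 0.001, iterations = 1L,
                       apply_to_biases = FALSE) {
  if (threshold < 0) stop("threshold must be >= 0")
  stopifnot(iterations >= 1)
  structure(list(threshold = threshold,
                 iterations = as.integer(iterations),
                 apply_to_biases = isTRUE(apply_to_biases)),
            class = "irl_config")
}

#' Zero all small-magnitude weights
#'
#' Sets every kernel weight with `|w| <= threshold` (inclusive) to
#' exactly zero, leaving all other values bit-identical. Biases are
#' untouched unless `apply_to_biases`.
#'
#' @param weights A `"weight_store"`.
#' @param threshold Non-negative magnitude cutoff.
#' @param apply_to_biases Also process bias vectors.
#' @return `list(weights = modified store, zeroed = count)` where
#'   `zeroed` counts entries that were nonzero and became zero.
#' @export
zero_small_weights <- function(weights, threshold,
                               apply_to_biases = FALSE) {
  if (threshold < 0) stop("threshold must be >= 0")
  zeroed <- 0L
  out <- ws_map(weights, function(a) {
    hit <- abs(a) <= threshold & a != 0
    zeroed <<- zeroed + sum(hit)
    a[hit] <- 0
    a
  }, include_bias = apply_to_biases)
  list(weights = out, zeroed = as.integer(zeroed))
}

#' Run iterative reinforced learning
#'
#' Iteration 0 trains from Xavier scratch (or from `init` when given).
#' Each subsequent iteration zeroes small weights in the previous final
#' model ([zero_small_weights()]) and retrains with that modified store
#' as the pretrained start, under the same training budget but a fresh
#' deterministic seed (`config$seed + iteration`). Test accuracy and the
#' zeroed-weight count are recorded after every iteration.
#'
#' @param spec A `"gpdnet_spec"`.
#' @param train_set,test_set Training and held-out [image_set()]s.
#' @param config A [train_config()].
#' @param irl An [irl_config()].
#' @param init Optional pre-trained `"weight_store"` used as iteration 0
#'   instead of training from scratch (its accuracy is measured, not
#'   retrained); used by [sweep_irl()] to share one scratch model.
#' @param keep_weights Keep every per-iteration weight store in the
#'   returned object (default `TRUE`).
#' @return An `"irl_trace"`: list with `trace` (data frame: `iteration`,
#'   `zeroed`, `accuracy`), `weights` (final store), `checkpoints`
#'   (per-iteration stores, if kept), `config`, `irl`.
#' @export
run_irl <- function(spec, train_set, test_set, config = train_config(),
                    irl = irl_config(), init = NULL, keep_weights = TRUE) {
  stopifnot(inherits(irl, "irl_config"))
  n_iter <- irl$iterations
  trace <- data.frame(iteration = 0:n_iter, zeroed = 0L,
                      accuracy = NA_real_)
  checkpoints <- if (keep_weights) vector("list", n_iter + 1L)

  if (is.null(init)) {
    res <- train_network(spec, train_set, config, test_set = NULL)
    current <- res$weights
  } else {
    check_init_shapes(spec, init)
    current <- init
  }
  trace$accuracy[1] <- evaluate_accuracy(spec, current, test_set)
  if (keep_weights) checkpoints[[1]] <- current

  for (k in seq_len(n_iter)) {
    zs <- zero_small_weights(current, irl$threshold, irl$apply_to_biases)
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    res <- train_network(spec, train_set, cfg_k, init = zs$weights,
                         test_set = NULL)
    current <- res$weights
    trace$zeroed[k + 1L] <- zs$zeroed
    trace$accuracy[k + 1L] <- evaluate_accuracy(spec, current, test_set)
    if (keep_weights) checkpoints[[k + 1L]] <- current
  }
  structure(list(trace = trace, weights = current,
                 checkpoints = checkpoints, config = config, irl = irl),
            class = "irl_trace")
}

#' @export
print.irl_trace <- function(x, ...) {
  cat(sprintf("IRL trace: threshold %g, %d iterations\n",
              x$irl$threshold, x$irl$iterations))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' @export
plot.irl_trace <- function(x, ...) {
  plot(x$trace$iteration, x$trace$accuracy, type = "b",
       xlab = "IRL iteration", ylab = "test accuracy", ylim = c(0, 1),
       ...)
  invisible(x)
}

#' Sweep IRL over thresholds
#'
#' Runs the full IRL loop once per threshold, sharing a single scratch
#' model (iteration 0) across thresholds so the iteration-0 row is
#' identical in every column. The result is shaped like the published
#' threshold-by-iteration accuracy grid: rows are iterations 0..K,
#' columns thresholds.
#'
#' @inheritParams run_irl
#' @param thresholds Non-empty numeric vector of distinct thresholds.
#' @param iterations Iterations per threshold.
#' @return An `"irl_sweep"`: list with `accuracy` (matrix, `(K+1) x
#'   length(thresholds)`), `zeroed` (same shape), `thresholds`.
#' @export
sweep_irl <- function(spec, train_set, test_set, config = train_config(),
                      thresholds = 0.001, iterations = 1L) {
  if (!length(thresholds)) stop("thresholds must be non-empty")
  if (any(thresholds < 0)) stop("thresholds must be >= 0")
  if (anyDuplicated(thresholds)) stop("duplicate thresholds")
  scratch <- train_network(spec, train_set, config, test_set = NULL)$weights
  acc <- zeroed <- matrix(NA_real_, iterations + 1L, length(thresholds),
                          dimnames = list(iteration = 0:iterations,
                                          threshold = thresholds))
  for (j in seq_along(thresholds)) {
    tr <- run_irl(spec, train_set, test_set, config,
                  irl_config(thresholds[j], iterations), init = scratch,
                  keep_weights = FALSE)
    acc[, j] <- tr$trace$accuracy
    zeroed[, j] <- tr$trace$zeroed
  }
  structure(list(accuracy = acc, zeroed = zeroed,
                 thresholds = thresholds),
            class = "irl_sweep")
}

#' @export
print.irl_sweep <- function(x, ...) {
  cat("IRL threshold x iteration accuracy sweep\n")
  print(round(x$accuracy, 4))
  invisible(x)
}
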