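# Shared fixtures: tiny networks and stores built in code.

# Small fully convolutional net covering every layer kind used by the
# fire variant; cheap enough for finite-difference gradient checks.
tiny_fire_spec <- function() {
  network_spec(list(
    conv_layer("c1", 3, 4, 3, pad = 1),
    pool_layer("max", 3, 2),
    fire_layer("f2", 4, 2, 3, 3),
    pool_layer("avg", 3, 2),
    conv_layer("cls", 6, 3, 1, relu = FALSE),
    global_avg_pool_layer(),
    softmax_layer()), num_classes = 3, input_size = 12)
}

tiny_dense_spec <- function() {
  network_spec(list(
    conv_layer("c1", 3, 4, 5, pad = 2),
    pool_layer("max", 3, 2),
    flatten_layer(),
    dense_layer("d1", 4 * 4 * 4, 6),
    dense_layer("d2", 6, 3, relu = FALSE),
    softmax_layer()), num_classes = 3, input_size = 8)
}

# Random store with biases nudged off zero so no ReLU pre-activation
# sits exactly at the kink (where the subgradient and a central
# difference legitimately disagree).
random_store <- function(spec, seed = 1) {
  w <- initialize_weights(spec, seed)
  set.seed(seed + 1000)
  for (l in names(w))
    for (nm in names(w[[l]]))
      if (startsWith(nm, "b"))
        w[[l]][[nm]][] <- runif(length(w[[l]][[nm]]), 0.01, 0.05)
  w
}

# Hand-built store holding one kernel vector, for threshold/binning
# examples where exact values matter.
manual_store <- function(values, bias = NULL) {
  entry <- list(W = array(values, dim = c(1, 1, 1, length(values))))
  if (!is.null(bias)) entry$b <- bias
  structure(list(layer1 = entry), class = "weight_store")
}

random_batch <- function(h, w, n, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3 * n), c(h, w, 3, n))
}

# Random valid posterior rows.
random_posteriors <- function(n, L, seed = 1) {
  set.seed(seed)
  p <- matrix(stats::rexp(n * L), n, L)
  p / rowSums(p)
}

# The quick desk-scale training configuration used throughout the
# tests: a larger base rate with a short step schedule, because these
# runs take two orders of magnitude fewer SGD iterations than the
# published 50-epoch schedule.
quick_config <- function(epochs, seed = 1, eval_every = epochs) {
  train_config(epochs = epochs, seed = seed, base_lr = 0.015,
               step_size = 6L, gamma = 0.3, eval_every = eval_every)
}
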