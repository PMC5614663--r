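test_that("threshold zeroing follows the inclusive magnitude rule", {
  st <- manual_store(c(0.0005, -0.002, 0.3))
  zs <- zero_small_weights(st, 0.001)
  expect_equal(as.vector(zs$weights$layer1$W), c(0, -0.002, 0.3))
  expect_identical(zs$zeroed, 1L)

  # threshold 0: only exact zeros qualify, nothing is newly zeroed
  zs0 <- zero_small_weights(st, 0)
  expect_identical(zs0$weights, st)
  expect_identical(zs0$zeroed, 0L)

  expect_error(zero_small_weights(st, -0.1), ">= 0")

  # biases untouched unless asked
  stb <- manual_store(c(0.0005, 0.5), bias = c(0.0002, 0.9))
  zb <- zero_small_weights(stb, 0.001)
  expect_identical(zb$weights$layer1$b, stb$layer1$b)
  zb2 <- zero_small_weights(stb, 0.001, apply_to_biases = TRUE)
  expect_equal(zb2$weights$layer1$b, c(0, 0.9))
})

test_that("a total threshold flattens the network to the uniform posterior", {
  spec <- tiny_fire_spec()
  w <- random_store(spec, 2)
  # biases too: positive biases would otherwise keep the logits apart
  zs <- zero_small_weights(w, Inf, apply_to_biases = TRUE)
  p <- forward(spec, zs$weights, random_batch(12, 12, 3, seed = 2))
  expect_identical(p, matrix(1 / 3, 3, 3))
})

test_that("zeroing properties hold over random stores and thresholds", {
  set.seed(77)
  spec <- tiny_fire_spec()
  for (i in 1:50) {
    w <- initialize_weights(spec, i)
    t <- stats::runif(1, 0, 0.15)
    zs <- zero_small_weights(w, t)
    vals <- unlist(lapply(zs$weights, function(l)
      lapply(names(l)[startsWith(names(l), "W")], function(nm) l[[nm]])),
      use.names = FALSE)
    # no surviving weight in (0, t]
    expect_false(any(vals != 0 & abs(vals) <= t))
    # brute-force count agreement
    orig <- unlist(lapply(w, function(l)
      lapply(names(l)[startsWith(names(l), "W")], function(nm) l[[nm]])),
      use.names = FALSE)
    expect_identical(zs$zeroed, sum(orig != 0 & abs(orig) <= t))
    # idempotence
    again <- zero_small_weights(zs$weights, t)
    expect_identical(again$weights, zs$weights)
    expect_identical(again$zeroed, 0L)
    # monotone destruction
    t2 <- t + stats::runif(1, 0, 0.1)
    expect_gte(zero_small_weights(w, t2)$zeroed, zs$zeroed)
  }
})

make_tiny_split <- function(seed = 1) {
  set <- generate_synthetic_gpd(40, seed = seed, difficulty = "easy",
                                size = 12)
  split_train_test(set, per_class_test = 10, seed = seed)
}

test_that("the IRL loop records a trace and resumes from pruned models", {
  spec <- tiny_fire_spec()
  sp <- make_tiny_split()
  cfg <- train_config(epochs = 2, seed = 5, base_lr = 0.01, eval_every = 2)
  tr <- run_irl(spec, sp$train, sp$test, cfg, irl_config(0.001, 1))
  expect_identical(nrow(tr$trace), 2L)
  expect_identical(tr$trace$iteration, 0:1)
  expect_true(all(tr$trace$accuracy >= 0 & tr$trace$accuracy <= 1))
  expect_true(all(tr$trace$zeroed >= 0))
  expect_identical(length(tr$checkpoints), 2L)
  expect_output(print(tr), "IRL trace")
  # magnitude histograms before and after IRL are directly comparable;
  # the redistribution itself is data-dependent and not asserted
  pre <- suppressWarnings(bin_weight_magnitudes(tr$checkpoints[[1]]))
  post <- suppressWarnings(bin_weight_magnitudes(tr$checkpoints[[2]]))
  expect_identical(sum(pre), sum(post))
  expect_identical(length(pre), length(post))
})

test_that("threshold zero reduces IRL to plain continued training", {
  spec <- tiny_fire_spec()
  sp <- make_tiny_split(2)
  cfg <- train_config(epochs = 2, seed = 9, base_lr = 0.01, eval_every = 2)
  tr <- run_irl(spec, sp$train, sp$test, cfg, irl_config(0, 2))
  # manual chain with the same per-iteration seed policy
  w <- train_network(spec, sp$train, cfg)$weights
  for (k in 1:2) {
    ck <- cfg; ck$seed <- cfg$seed + k
    w <- train_network(spec, sp$train, ck, init = w)$weights
  }
  expect_identical(tr$weights, w)
  expect_true(all(tr$trace$zeroed == 0L))
})

test_that("the threshold sweep shares its scratch model and shapes like the grid", {
  spec <- tiny_fire_spec()
  sp <- make_tiny_split(3)
  cfg <- train_config(epochs = 1, seed = 11, base_lr = 0.01, eval_every = 1)
  sw <- sweep_irl(spec, sp$train, sp$test, cfg,
                  thresholds = c(0.001, 0.01), iterations = 2)
  expect_identical(dim(sw$accuracy), c(3L, 2L))
  # shared scratch model: identical iteration-0 row
  expect_identical(sw$accuracy[1, 1], sw$accuracy[1, 2])
  expect_error(sweep_irl(spec, sp$train, sp$test, cfg,
                         thresholds = c(0.001, 0.001), iterations = 1),
               "duplicate")
  expect_error(sweep_irl(spec, sp$train, sp$test, cfg,
                         thresholds = numeric(0), iterations = 1),
               "non-empty")
})

test_that("a destructive threshold collapses accuracy to the majority class", {
  spec <- tiny_fire_spec()
  sp <- make_tiny_split(4)
  cfg <- train_config(epochs = 2, seed = 13, base_lr = 0.01, eval_every = 2)
  tr <- run_irl(spec, sp$train, sp$test, cfg, irl_config(1e6, 1))
  # every kernel was zeroed going into the retraining
  expect_identical(tr$trace$zeroed[2], count_parameters(spec))
  # with dead kernels only biases can move: accuracy collapses toward
  # the majority-class fraction (1/3 on this balanced split)
  expect_lt(tr$trace$accuracy[2], 0.5)
})
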