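test_that("published parameter counts are reproduced exactly", {
  fire <- build_gpdnet(3, use_fire = TRUE)
  base <- build_gpdnet(3, use_fire = FALSE)
  expect_identical(count_parameters(fire, include_bias = FALSE), 14368L)
  expect_identical(count_parameters(base, include_bias = FALSE), 144928L)
  expect_identical(count_parameters(fire, include_bias = TRUE), 14563L)
  expect_identical(count_parameters(base, include_bias = TRUE), 145123L)
  # widening the output layer only adds 64 weights per extra class
  expect_identical(count_parameters(build_gpdnet(10, FALSE)), 145376L)
  expect_error(build_gpdnet(1, TRUE), "num_classes")
})

test_that("fire-module weight count equals its three constituent convolutions", {
  set.seed(11)
  for (i in 1:20) {
    cin <- sample(1:64, 1); s <- sample(1:32, 1)
    e1 <- sample(1:64, 1); e3 <- sample(1:64, 1)
    shp <- gpdnet:::layer_weight_shapes(fire_layer("f", cin, s, e1, e3))
    got <- sum(vapply(shp[startsWith(names(shp), "W")], prod, 0))
    # brute force: materialize the squeeze / expand-1x1 / expand-3x3
    # kernels and count their elements
    brute <- length(array(0, c(1, 1, cin, s))) +
      length(array(0, c(1, 1, s, e1))) +
      length(array(0, c(3, 3, s, e3)))
    expect_identical(as.integer(got), as.integer(brute))
  }
})

test_that("network_spec rejects inconsistent channel chains", {
  expect_error(network_spec(list(
    conv_layer("c1", 3, 8, 3, pad = 1),
    conv_layer("c2", 16, 3, 1, relu = FALSE),   # expects 16, gets 8
    global_avg_pool_layer(), softmax_layer()), 3, 8), "channels")
  expect_error(network_spec(list(
    conv_layer("c1", 3, 4, 3, pad = 1),
    global_avg_pool_layer(), softmax_layer()), 3, 8), "num_classes")
})

test_that("Xavier initialization is seeded, bounded and layer-aware", {
  spec <- build_gpdnet(3, TRUE)
  w1 <- initialize_weights(spec, 7)
  w2 <- initialize_weights(spec, 7)
  w3 <- initialize_weights(spec, 8)
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
  # bounds: |w| <= sqrt(6 / (fan_in + fan_out)), biases exactly zero
  conv1 <- w1$conv1
  a <- sqrt(6 / (5 * 5 * 3 + 5 * 5 * 32))
  expect_true(all(abs(conv1$W) <= a))
  expect_true(all(conv1$b == 0))
  e3 <- w1$fire2$W_expand3
  a3 <- sqrt(6 / (9 * 16 + 9 * 32))
  expect_true(all(abs(e3) <= a3))
  expect_gt(max(abs(e3)), 0.5 * a3)   # actually spread over the range
})

test_that("convolution kernel matches a naive R convolution", {
  # independent oracle: direct quadruple loop, double precision
  naive_conv <- function(x, w, b, stride, pad) {
    d <- dim(x); k <- dim(w)
    Ho <- (d[1] + 2 * pad - k[1]) %/% stride + 1
    Wo <- (d[2] + 2 * pad - k[2]) %/% stride + 1
    xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
    y <- array(0, c(Ho, Wo, k[4], d[4]))
    for (n in seq_len(d[4])) for (co in seq_len(k[4]))
      for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
        patch <- xp[(i - 1) * stride + seq_len(k[1]),
                    (j - 1) * stride + seq_len(k[2]), , n]
        y[i, j, co, n] <- sum(patch * w[, , , co]) + b[co]
      }
    y
  }
  set.seed(3)
  x <- array(runif(10 * 10 * 3 * 2), c(10, 10, 3, 2))
  w <- array(rnorm(3 * 3 * 3 * 4, sd = 0.3), c(3, 3, 3, 4))
  b <- rnorm(4, sd = 0.1)
  for (stride in 1:2) for (pad in 0:1) {
    got <- gpdnet:::conv_forward_cpp(x, w, b, stride, pad, FALSE)
    want <- naive_conv(x, w, b, stride, pad)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("pooling matches a naive ceil-mode R implementation", {
  naive_pool <- function(x, window, stride, kind) {
    d <- dim(x)
    Ho <- (d[1] - window + stride - 1) %/% stride + 1
    Wo <- (d[2] - window + stride - 1) %/% stride + 1
    y <- array(0, c(Ho, Wo, d[3], d[4]))
    for (n in seq_len(d[4])) for (c in seq_len(d[3]))
      for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
        hs <- (i - 1) * stride + 1; he <- min(hs + window - 1, d[1])
        ws <- (j - 1) * stride + 1; we <- min(ws + window - 1, d[2])
        v <- x[hs:he, ws:we, c, n]
        y[i, j, c, n] <- if (kind == "max") max(v) else mean(v)
      }
    y
  }
  set.seed(4)
  x <- array(rnorm(13 * 13 * 2 * 3), c(13, 13, 2, 3))
  for (kind in c("max", "avg")) {
    got <- gpdnet:::pool_forward_cpp(x, 3L, 2L,
                                     if (kind == "max") 0L else 1L)$y
    expect_equal(got, naive_pool(x, 3, 2, kind), tolerance = 1e-12)
  }
  # ceil mode reproduces the 32 -> 16 -> 8 -> 4 spatial chain
  x32 <- array(0, c(32, 32, 1, 1))
  expect_identical(dim(gpdnet:::pool_forward_cpp(x32, 3L, 2L, 0L)$y)[1], 16L)
})

test_that("analytic gradients agree with central differences", {
  for (spec in list(tiny_fire_spec(), tiny_dense_spec())) {
    w <- random_store(spec, 5)
    n <- 4
    xb <- random_batch(spec$input_size, spec$input_size, n, seed = 9)
    yb <- c(0L, 1L, 2L, 1L)
    lossfn <- function(w)
      cross_entropy_loss(gpdnet:::nn_forward(spec, w, xb)$post, yb) / n
    fw <- gpdnet:::nn_forward(spec, w, xb, keep_cache = TRUE)
    dl <- t(fw$post)
    dl[cbind(yb + 1L, seq_len(n))] <- dl[cbind(yb + 1L, seq_len(n))] - 1
    dl <- dl / n
    gr <- gpdnet:::nn_backward(spec, w, fw$cache, dl)
    eps <- 1e-3   # forward runs in single precision
    set.seed(21)
    for (l in names(gr)) for (nm in names(gr[[l]])) {
      a <- w[[l]][[nm]]
      for (i in sample(length(a), min(6, length(a)))) {
        wp <- w; wp[[l]][[nm]][i] <- a[i] + eps
        wm <- w; wm[[l]][[nm]][i] <- a[i] - eps
        num <- (lossfn(wp) - lossfn(wm)) / (2 * eps)
        ana <- gr[[l]][[nm]][i]
        expect_lt(abs(num - ana), 5e-4 + 0.02 * (abs(num) + abs(ana)))
      }
    }
  }
})

test_that("forward produces normalized posteriors for any valid input", {
  spec <- build_gpdnet(3, TRUE)
  w <- initialize_weights(spec, 2)
  p32 <- forward(spec, w, random_batch(32, 32, 5, seed = 1))
  expect_equal(dim(p32), c(5L, 3L))
  expect_true(all(p32 >= 0))
  expect_equal(rowSums(p32), rep(1, 5), tolerance = 1e-5)
  # fully convolutional head: larger inputs are fine
  p64 <- forward(spec, w, random_batch(64, 64, 2, seed = 2))
  expect_equal(dim(p64), c(2L, 3L))
  expect_equal(rowSums(p64), rep(1, 2), tolerance = 1e-5)
  # undersized or mis-channeled input is rejected
  expect_error(forward(spec, w, array(0.1, c(16, 16, 3, 1))), "spatial")
  expect_error(forward(spec, w, array(0.1, c(32, 32, 4, 1))), "channels")
  # dense-head baseline fixes the input size
  specb <- build_gpdnet(3, FALSE)
  wb <- initialize_weights(specb, 2)
  expect_equal(rowSums(forward(specb, wb, random_batch(32, 32, 3, seed = 3))),
               rep(1, 3), tolerance = 1e-5)
  expect_error(forward(specb, wb, array(0.1, c(64, 64, 3, 1))), "exactly")
})

test_that("all-zero weights give the exact uniform posterior", {
  spec <- build_gpdnet(3, TRUE)
  p <- forward(spec, zero_weights(spec), random_batch(32, 32, 4, seed = 5))
  expect_identical(p, matrix(1 / 3, 4, 3))
})

test_that("forward is permutation-equivariant over the batch axis", {
  spec <- tiny_fire_spec()
  w <- random_store(spec, 3)
  x <- random_batch(12, 12, 6, seed = 8)
  perm <- c(4, 1, 6, 2, 5, 3)
  p <- forward(spec, w, x)
  pp <- forward(spec, w, x[, , , perm, drop = FALSE])
  expect_equal(pp, p[perm, ], tolerance = 1e-6)
})

test_that("fire expand branches computed separately match the module", {
  # dual route: run the squeeze and each expand branch as standalone
  # convolutions and concatenate by hand (1x1 branch first)
  spec <- tiny_fire_spec()
  w <- random_store(spec, 13)
  x <- random_batch(12, 12, 3, seed = 14)
  fw <- gpdnet:::nn_forward(spec, w, x, keep_cache = TRUE)
  cc <- fw$cache[[3]]   # the fire layer
  f <- w$f2
  s <- gpdnet:::relu(gpdnet:::conv_forward_cpp(cc$x, f$W_squeeze,
                                               f$b_squeeze, 1L, 0L, FALSE))
  e1 <- gpdnet:::relu(gpdnet:::conv_forward_cpp(s, f$W_expand1,
                                                f$b_expand1, 1L, 0L, FALSE))
  e3 <- gpdnet:::relu(gpdnet:::conv_forward_cpp(s, f$W_expand3,
                                                f$b_expand3, 1L, 1L, FALSE))
  expect_equal(cc$e1, e1, tolerance = 1e-6)
  expect_equal(cc$e3, e3, tolerance = 1e-6)
  joint <- gpdnet:::concat_channels(e1, e3)
  expect_equal(dim(joint)[3], 6L)
  expect_equal(joint[, , 1:3, ], e1[, , , ], tolerance = 0)
})
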