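#' Layer specification constructors
#'
#' Low-level building blocks for [network_spec()]. Most users only need
#' [build_gpdnet()], which assembles the two published GPDNet variants;
#' the constructors are exported so small custom networks can be built
#' for experiments and tests.
#'
#' @param in_channels,out_channels Channel counts (>= 1).
#' @param kernel Square kernel edge length in pixels.
#' @param stride Stride in pixels.
#' @param pad Zero padding in pixels (>= 0).
#' @param bias Whether the layer carries a bias vector.
#' @param relu Whether a ReLU follows the layer (final classifier layers
#'   set this to `FALSE`).
#' @param name Layer name; keys the matching entry of a weight store.
#' @return A layer specification list with class `"gpd_layer"`.
#' @name layer_spec
NULL

#' @rdname layer_spec
#' @export
conv_layer <- function(name, in_channels, out_channels, kernel,
                       stride = 1L, pad = 0L, bias = TRUE, relu = TRUE) {
  stopifnot(in_channels >= 1, out_channels >= 1, kernel >= 1,
            stride >= 1, pad >= 0)
  structure(list(type = "conv", name = name,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 pad = as.integer(pad), bias = isTRUE(bias),
                 relu = isTRUE(relu)),
            class = "gpd_layer")
}

#' @rdname layer_spec
#' @param squeeze_channels,expand1x1_channels,expand3x3_channels Fire-module
#'   channel counts: the 1x1 squeeze layer and the two parallel expand
#'   branches (1x1 and 3x3) whose outputs are concatenated channel-wise,
#'   1x1 branch first.
#' @export
fire_layer <- function(name, in_channels, squeeze_channels,
                       expand1x1_channels, expand3x3_channels) {
  stopifnot(in_channels >= 1, squeeze_channels >= 1,
            expand1x1_channels >= 1, expand3x3_channels >= 1)
  structure(list(type = "fire", name = name,
                 in_channels = as.integer(in_channels),
                 squeeze_channels = as.integer(squeeze_channels),
                 expand1x1_channels = as.integer(expand1x1_channels),
                 expand3x3_channels = as.integer(expand3x3_channels),
                 out_channels = as.integer(expand1x1_channels +
                                             expand3x3_channels)),
            class = "gpd_layer")
}

#' @rdname layer_spec
#' @param kind Pooling kind, `"max"` or `"avg"`.
#' @param window Pooling window edge length (>= stride).
#' @export
pool_layer <- function(kind = c("max", "avg"), window = 3L, stride = 2L) {
  kind <- match.arg(kind)
  stopifnot(stride >= 1, window >= stride)
  structure(list(type = "pool", kind = kind, window = as.integer(window),
                 stride = as.integer(stride)),
            class = "gpd_layer")
}

#' @rdname layer_spec
#' @param in_features,out_features Dense-layer dimensions.
#' @export
dense_layer <- function(name, in_features, out_features, relu = TRUE) {
  stopifnot(in_features >= 1, out_features >= 1)
  structure(list(type = "dense", name = name,
                 in_features = as.integer(in_features),
                 out_features = as.integer(out_features),
                 relu = isTRUE(relu)),
            class = "gpd_layer")
}

#' @rdname layer_spec
#' @export
global_avg_pool_layer <- function() {
  structure(list(type = "gap"), class = "gpd_layer")
}

#' @rdname layer_spec
#' @export
flatten_layer <- function() {
  structure(list(type = "flatten"), class = "gpd_layer")
}

#' @rdname layer_spec
#' @export
softmax_layer <- function() {
  structure(list(type = "softmax"), class = "gpd_layer")
}

#' Assemble a validated network specification
#'
#' Chains layer specifications into a network, checking that channel
#' counts are consistent from layer to layer and that the network ends in
#' a softmax over `num_classes`.
#'
#' @param layers List of layer specifications (see [layer_spec]).
#' @param num_classes Number of output classes (>= 2).
#' @param input_size Native input edge length in pixels (the fire variant
#'   is fully convolutional and also accepts larger inputs).
#' @return An object of class `"gpdnet_spec"`.
#' @export
network_spec <- function(layers, num_classes, input_size = 32L) {
  if (num_classes < 2) stop("num_classes must be >= 2")
  spec <- structure(list(layers = layers,
                         num_classes = as.integer(num_classes),
                         input_size = as.integer(input_size)),
                    class = "gpdnet_spec")
  spec_infer_shapes(spec, input_size)   # validates channel chaining
  spec
}

#' Build a GPDNet variant
#'
#' Constructs the compact three-stage classifier for 32x32 RGB lesion
#' images. With `use_fire = TRUE` the network is the fire-module variant:
#' a 5x5 convolution (3 to 32 channels), max pool, a fire module
#' (squeeze 16, expand 32+32), average pool, a second fire module
#' (squeeze 16, expand 32+32), average pool, a 1x1 classifier convolution
#' to `num_classes`, global average pooling and softmax. This fully
#' convolutional head accepts any input of at least 32 pixels.
#' With `use_fire = FALSE` it is the CIFAR-10-quick-style baseline with
#' three 5x5 convolutions and two dense layers (input fixed at 32x32).
#'
#' For 3 classes the kernel-weight (bias-free) counts are 14,368 (fire)
#' and 144,928 (baseline), a roughly tenfold reduction.
#'
#' @param num_classes Number of classes (default 3: erosion, polyp, ulcer).
#' @param use_fire `TRUE` for the fire-module variant, `FALSE` for the
#'   dense-head baseline.
#' @return A `"gpdnet_spec"` object.
#' @examples
#' spec <- build_gpdnet(3, use_fire = TRUE)
#' count_parameters(spec)                      # 14368
#' count_parameters(spec, include_bias = TRUE) # 14563
#' @export
build_gpdnet <- function(num_classes = 3L, use_fire = TRUE) {
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (use_fire) {
    layers <- list(
      conv_layer("conv1", 3L, 32L, 5L, pad = 2L),
      pool_layer("max", 3L, 2L),
      fire_layer("fire2", 32L, 16L, 32L, 32L),
      pool_layer("avg", 3L, 2L),
      fire_layer("fire3", 64L, 16L, 32L, 32L),
      pool_layer("avg", 3L, 2L),
      conv_layer("classifier", 64L, as.integer(num_classes), 1L,
                 relu = FALSE),
      global_avg_pool_layer(),
      softmax_layer())
  } else {
    layers <- list(
      conv_layer("conv1", 3L, 32L, 5L, pad = 2L),
      pool_layer("max", 3L, 2L),
      conv_layer("conv2", 32L, 32L, 5L, pad = 2L),
      pool_layer("avg", 3L, 2L),
      conv_layer("conv3", 32L, 64L, 5L, pad = 2L),
      pool_layer("avg", 3L, 2L),
      flatten_layer(),
      dense_layer("ip1", 1024L, 64L),
      dense_layer("ip2", 64L, as.integer(num_classes), relu = FALSE),
      softmax_layer())
  }
  network_spec(layers, num_classes, 32L)
}

#' Trace activation shapes through a network
#'
#' Walks the layer list propagating the (height, width, channels) shape,
#' validating channel consistency and that dense layers see the flattened
#' feature count they expect.
#'
#' @param spec A `"gpdnet_spec"`.
#' @param input_size Input edge length in pixels.
#' @return A list of `c(H, W, C)` shapes, one per layer output (dense and
#'   softmax outputs reported as `c(1, 1, features)`).
#' @export
spec_infer_shapes <- function(spec, input_size = spec$input_size) {
  h <- w <- as.integer(input_size)
  ch <- 3L
  flat <- NULL
  shapes <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    switch(ly$type,
      conv = {
        if (ly$in_channels != ch)
          stop(sprintf("layer %d (%s): expects %d channels, gets %d",
                       i, ly$name, ly$in_channels, ch))
        h <- (h + 2L * ly$pad - ly$kernel) %/% ly$stride + 1L
        w <- (w + 2L * ly$pad - ly$kernel) %/% ly$stride + 1L
        if (h < 1L || w < 1L) stop("input too small for conv layer ", ly$name)
        ch <- ly$out_channels
      },
      fire = {
        if (ly$in_channels != ch)
          stop(sprintf("layer %d (%s): expects %d channels, gets %d",
                       i, ly$name, ly$in_channels, ch))
        ch <- ly$out_channels
      },
      pool = {
        if (ly$window > h || ly$window > w)
          stop("input too small for pooling window")
        h <- (h - ly$window + ly$stride - 1L) %/% ly$stride + 1L
        w <- (w - ly$window + ly$stride - 1L) %/% ly$stride + 1L
      },
      gap = { h <- 1L; w <- 1L },
      flatten = { flat <- h * w * ch; h <- 1L; w <- 1L; ch <- flat },
      dense = {
        if (ly$in_features != ch)
          stop(sprintf("layer %d (%s): expects %d features, gets %d",
                       i, ly$name, ly$in_features, ch))
        ch <- ly$out_features
      },
      softmax = {
        if (ch != spec$num_classes)
          stop("softmax input dimension != num_classes")
      },
      stop("unknown layer type: ", ly$type))
    shapes[[i]] <- c(h, w, ch)
  }
  shapes
}

layer_weight_shapes <- function(ly) {
  switch(ly$type,
    conv = list(
      W = c(ly$kernel, ly$kernel, ly$in_channels, ly$out_channels),
      b = if (ly$bias) ly$out_channels),
    fire = list(
      W_squeeze = c(1L, 1L, ly$in_channels, ly$squeeze_channels),
      b_squeeze = ly$squeeze_channels,
      W_expand1 = c(1L, 1L, ly$squeeze_channels, ly$expand1x1_channels),
      b_expand1 = ly$expand1x1_channels,
      W_expand3 = c(3L, 3L, ly$squeeze_channels, ly$expand3x3_channels),
      b_expand3 = ly$expand3x3_channels),
    dense = list(
      W = c(ly$in_features, ly$out_features),
      b = ly$out_features),
    NULL)
}

learnable_layers <- function(spec) {
  Filter(function(ly) ly$type %in% c("conv", "fire", "dense"), spec$layers)
}

#' Count learnable parameters
#'
#' Sums the sizes of all kernel arrays (convolution, fire-module and
#' dense weights). By default bias vectors are excluded — the convention
#' under which the fire variant counts exactly 14,368 weights and the
#' baseline 144,928.
#'
#' @param spec A `"gpdnet_spec"`.
#' @param include_bias Also count bias vectors.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, include_bias = FALSE) {
  total <- 0L
  for (ly in learnable_layers(spec)) {
    shp <- layer_weight_shapes(ly)
    for (nm in names(shp)) {
      if (is.null(shp[[nm]])) next
      if (!include_bias && startsWith(nm, "b")) next
      total <- total + prod(shp[[nm]])
    }
  }
  as.integer(total)
}

#' Initialize a weight store
#'
#' Draws every kernel from the Xavier/Glorot uniform scheme,
#' `U(-a, a)` with `a = sqrt(6 / (fan_in + fan_out))` (for convolutions
#' the fans include the kernel area), and sets every bias to zero.
#' Deterministic for a fixed seed.
#'
#' @param spec A `"gpdnet_spec"`.
#' @param seed Integer RNG seed.
#' @return A `"weight_store"`: a named list, one entry per learnable
#'   layer, each holding kernel arrays (names starting `W`) and bias
#'   vectors (names starting `b`).
#' @export
initialize_weights <- function(spec, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  store <- list()
  for (ly in learnable_layers(spec)) {
    shp <- layer_weight_shapes(ly)
    entry <- list()
    for (nm in names(shp)) {
      if (is.null(shp[[nm]])) next
      d <- shp[[nm]]
      if (startsWith(nm, "W")) {
        if (length(d) == 4L) {          # conv kernel (kh, kw, cin, cout)
          fan_in <- d[1] * d[2] * d[3]
          fan_out <- d[1] * d[2] * d[4]
        } else {                        # dense (in, out)
          fan_in <- d[1]
          fan_out <- d[2]
        }
        a <- sqrt(6 / (fan_in + fan_out))
        entry[[nm]] <- array(stats::runif(prod(d), -a, a), dim = d)
      } else {
        entry[[nm]] <- numeric(d)
      }
    }
    store[[ly$name]] <- entry
  }
  structure(store, class = "weight_store")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Make an all-zero weight store for a network
#'
#' Useful as a degenerate reference: a fully zeroed network outputs the
#' uniform posterior for every input.
#'
#' @inheritParams count_parameters
#' @return A `"weight_store"` of zeros.
#' @export
zero_weights <- function(spec) {
  store <- initialize_weights(spec, seed = 0L)
  for (l in names(store))
    for (nm in names(store[[l]]))
      store[[l]][[nm]][] <- 0
  store
}

# Apply f to every kernel array (and optionally biases); returns the
# modified store. f takes the numeric array and returns one of equal shape.
ws_map <- function(weights, f, include_bias = FALSE) {
  for (l in names(weights)) {
    for (nm in names(weights[[l]])) {
      if (!include_bias && !startsWith(nm, "W")) next
      weights[[l]][[nm]] <- f(weights[[l]][[nm]])
    }
  }
  weights
}

# Concatenate all kernel values (and optionally biases) into one vector.
ws_values <- function(weights, include_bias = FALSE) {
  out <- lapply(names(weights), function(l) {
    keep <- names(weights[[l]])
    if (!include_bias) keep <- keep[startsWith(keep, "W")]
    unlist(weights[[l]][keep], use.names = FALSE)
  })
  unlist(out, use.names = FALSE)
}

#' @export
print.gpdnet_spec <- function(x, ...) {
  cat(sprintf("GPDNet network spec: %d layers, %d classes, %dx%d input\n",
              length(x$layers), x$num_classes, x$input_size, x$input_size))
  for (ly in x$layers) {
    desc <- switch(ly$type,
      conv = sprintf("conv %s: %d -> %d, %dx%d, stride %d, pad %d",
                     ly$name, ly$in_channels, ly$out_channels, ly$kernel,
                     ly$kernel, ly$stride, ly$pad),
      fire = sprintf("fire %s: %d -> squeeze %d -> expand %d+%d",
                     ly$name, ly$in_channels, ly$squeeze_channels,
                     ly$expand1x1_channels, ly$expand3x3_channels),
      pool = sprintf("%s pool %dx%d stride %d", ly$kind, ly$window,
                     ly$window, ly$stride),
      dense = sprintf("dense %s: %d -> %d", ly$name, ly$in_features,
                      ly$out_features),
      gap = "global average pool",
      flatten = "flatten",
      softmax = "softmax")
    cat("  -", desc, "\n")
  }
  cat(sprintf("kernel weights: %d (with biases: %d)\n",
              count_parameters(x), count_parameters(x, TRUE)))
  invisible(x)
}
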