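#' Labeled image set container
#'
#' Bundles a batch of RGB images with integer class labels. Labels are
#' 0-based and fixed to the class order erosion = 0, polyp = 1,
#' ulcer = 2 for the gastric-lesion problem; other label sets are
#' allowed for generic use.
#'
#' @param images `(H, W, 3, N)` array with values in `[0, 1]`.
#' @param labels Integer vector of length `N`, values in
#'   `0 .. length(class_names) - 1`.
#' @param class_names Character vector naming the classes, index order.
#' @return An object of class `"gpd_image_set"`.
#' @export
image_set <- function(images, labels,
                      class_names = c("erosion", "polyp", "ulcer")) {
  images <- as_batch(images)
  labels <- as.integer(labels)
  if (dim(images)[4] != length(labels))
    stop("number of images and labels differ")
  if (length(labels) && (min(labels) < 0 ||
                         max(labels) >= length(class_names)))
    stop("labels out of range for class_names")
  if (length(labels)) {
    rng <- range(images)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("pixel values must lie in [0, 1]")
  }
  structure(list(images = images, labels = labels,
                 class_names = class_names),
            class = "gpd_image_set")
}

#' @export
length.gpd_image_set <- function(x) length(x$labels)

#' @export
print.gpd_image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("labeled image set: %d images, %dx%dx%d\n", d[4], d[1],
              d[2], d[3]))
  tb <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                     labels = x$class_names))
  print(tb)
  invisible(x)
}

# Index subset (1-based positions), keeping class names.
subset_set <- function(set, idx) {
  image_set(set$images[, , , idx, drop = FALSE], set$labels[idx],
            set$class_names)
}

# Smooth random field in [-1, 1]: coarse uniform grid upsampled
# bilinearly to size x size.
smooth_field <- function(size, cells = 4L) {
  coarse <- matrix(stats::runif(cells * cells, -1, 1), cells, cells)
  bilinear_resize_plane(coarse, size, size)
}

# Difficulty presets: motif contrast, additive pixel noise sd, and
# geometric jitter (fraction of the image edge). Chosen so that, under
# the matched training budgets used in the tests, a scratch-trained
# fire network separates the easy preset almost perfectly, sits in a
# mid band with headroom on medium, and degrades further on hard.
difficulty_params <- function(difficulty) {
  switch(difficulty,
    easy   = list(contrast = 1.00, noise = 0.02, jitter = 0.04),
    medium = list(contrast = 0.45, noise = 0.18, jitter = 0.14),
    hard   = list(contrast = 0.25, noise = 0.30, jitter = 0.22),
    stop("unknown difficulty: ", difficulty))
}

# One synthetic lesion image on a mucosa-like background.
# cls: 0 erosion, 1 polyp, 2 ulcer.
synth_image <- function(cls, size, pars) {
  gx <- matrix(rep(seq(0, 1, length.out = size), each = size), size)
  gy <- t(gx)
  base <- c(0.78, 0.45, 0.42)                 # pink-red mucosa
  shade <- smooth_field(size)
  img <- array(0, c(size, size, 3))
  for (k in 1:3) img[, , k] <- base[k] + 0.06 * shade

  jit <- function(n = 1) stats::runif(n, -pars$jitter, pars$jitter)
  cx <- 0.5 + jit(); cy <- 0.5 + jit()
  d <- sqrt((gx - cx)^2 + (gy - cy)^2)

  if (cls == 1L) {                            # polyp: bright protrusion
    r <- stats::runif(1, 0.18, 0.28)
    bump <- exp(-(d / r)^2)
    hl <- exp(-(((gx - cx + 0.25 * r)^2 + (gy - cy + 0.25 * r)^2) /
                  (0.3 * r)^2))
    tint <- c(0.16, 0.10, 0.10) * pars$contrast
    for (k in 1:3)
      img[, , k] <- img[, , k] + tint[k] * bump + 0.10 * pars$contrast * hl
  } else if (cls == 0L) {                     # erosion: scattered patches
    npatch <- sample(5:9, 1)
    for (p in seq_len(npatch)) {
      px <- stats::runif(1, 0.15, 0.85); py <- stats::runif(1, 0.15, 0.85)
      pr <- stats::runif(1, 0.03, 0.08)
      blob <- exp(-(((gx - px)^2 + (gy - py)^2) / pr^2))
      img[, , 1] <- img[, , 1] + 0.06 * pars$contrast * blob
      img[, , 2] <- img[, , 2] - 0.14 * pars$contrast * blob
      img[, , 3] <- img[, , 3] - 0.12 * pars$contrast * blob
    }
  } else {                                    # ulcer: dark ring, pale crater
    r <- stats::runif(1, 0.20, 0.30)
    ring <- exp(-((d - r)^2 / (0.35 * r)^2))
    crater <- exp(-(d / (0.55 * r))^2)
    dark <- c(0.28, 0.20, 0.16) * pars$contrast
    pale <- c(0.14, 0.16, 0.08) * pars$contrast
    for (k in 1:3)
      img[, , k] <- img[, , k] - dark[k] * ring + pale[k] * crater
  }

  img <- img + array(stats::rnorm(size * size * 3, 0, pars$noise),
                     c(size, size, 3))
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic three-class lesion-texture dataset
#'
#' Procedural stand-in for clinical gastroscopy crops: three visually
#' distinct textures on a mucosa-like pink-red background. Class
#' "erosion" scatters small reddish patches, "polyp" renders a bright
#' circular protrusion with a radial luminance gradient and highlight,
#' "ulcer" a dark annulus with a pale crater center. The difficulty
#' preset scales motif contrast down and additive Gaussian noise and
#' geometric jitter up, controlling class separability. Deterministic
#' for a fixed seed.
#'
#' @param n_per_class Images generated per class (classes are exactly
#'   balanced).
#' @param seed Integer RNG seed.
#' @param difficulty `"easy"`, `"medium"` or `"hard"`.
#' @param size Image edge length in pixels (default 32; larger sources
#'   can be generated as raw material for [augment()]).
#' @return A [image_set()] with `3 * n_per_class` images.
#' @export
generate_synthetic_gpd <- function(n_per_class, seed = 1L,
                                   difficulty = c("easy", "medium", "hard"),
                                   size = 32L) {
  difficulty <- match.arg(difficulty)
  stopifnot(n_per_class >= 1, size >= 8)
  pars <- difficulty_params(difficulty)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- 3L * n_per_class
  labels <- rep(0:2, each = n_per_class)
  images <- array(0, c(size, size, 3, n))
  for (i in seq_len(n))
    images[, , , i] <- synth_image(labels[i], size, pars)
  image_set(images, labels)
}

# Bilinear resize of one (H, W) plane via EBImage.
bilinear_resize_plane <- function(m, h, w) {
  EBImage::resize(m, w = h, h = w, filter = "bilinear")
}

#' Resize an image to the network input size
#'
#' Bilinear resize of an `(H, W, 3)` RGB image to `target x target`,
#' with values clamped to `[0, 1]`. An image already at the target size
#' is returned unchanged.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param target Output edge length (default 32).
#' @return `(target, target, 3)` array.
#' @export
resize_to_input <- function(image, target = 32L) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("expected an (H, W, 3) image")
  if (d[1] == target && d[2] == target) return(image)
  out <- array(0, c(target, target, 3))
  for (k in 1:3)
    out[, , k] <- bilinear_resize_plane(image[, , k], target, target)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Augmentation configuration
#'
#' Random crop plus translation, the protocol used to expand the source
#' images before resizing everything to the 32x32 network input.
#'
#' @param crops Candidate square ROI edge lengths in pixels. The default
#'   `c(475, 400, 320)` suits full-size 560x475 endoscopy frames; pass
#'   sizes at or below the source size for small sources.
#' @param shift Maximum absolute translation in pixels applied to the
#'   crop window (default 10).
#' @param times Output multiplier: scalar, or one value per class. The
#'   per-class output count is `round(times * n_class)`; non-integer
#'   multipliers distribute the extra crops over the first source
#'   images of the class.
#' @param output_size Final edge length (fixed at 32 by the pipeline).
#' @return An `"augment_config"` list.
#' @export
augment_config <- function(crops = c(475L, 400L, 320L), shift = 10L,
                           times = 3, output_size = 32L) {
  stopifnot(all(crops >= 1), shift >= 0, all(times > 0))
  structure(list(crops = as.integer(crops), shift = as.integer(shift),
                 times = times, output_size = as.integer(output_size)),
            class = "augment_config")
}

#' Expand an image set by random crop and translation
#'
#' Each source image yields one or more derived images: a random square
#' ROI (edge length drawn from `config$crops`) is cropped at a randomly
#' translated position, then resized to the output size. Labels are
#' preserved.
#'
#' @param set A [image_set()]; sources must be at least as large as the
#'   largest configured crop.
#' @param config An [augment_config()].
#' @param seed Integer RNG seed.
#' @return A [image_set()] of `output_size` images.
#' @export
augment <- function(set, config = augment_config(), seed = 1L) {
  stopifnot(inherits(set, "gpd_image_set"),
            inherits(config, "augment_config"))
  d <- dim(set$images)
  if (max(config$crops) > min(d[1], d[2]))
    stop(sprintf("crop size %d larger than source %dx%d",
                 max(config$crops), d[1], d[2]))
  L <- length(set$class_names)
  times <- config$times
  if (length(times) == 1L) times <- rep(times, L)
  if (length(times) != L) stop("times must be scalar or one per class")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # per-source derived counts: floor everywhere, remainder to the
  # earliest sources of each class
  counts <- integer(length(set$labels))
  for (cl in seq_len(L) - 1L) {
    idx <- which(set$labels == cl)
    if (!length(idx)) next
    target <- round(times[cl + 1L] * length(idx))
    k <- target %/% length(idx)
    counts[idx] <- k
    extra <- target - k * length(idx)
    if (extra > 0) counts[idx[seq_len(extra)]] <- counts[idx[seq_len(extra)]] + 1L
  }

  total <- sum(counts)
  os <- config$output_size
  images <- array(0, c(os, os, 3, total))
  labels <- integer(total)
  j <- 0L
  for (i in seq_along(set$labels)) {
    if (counts[i] == 0L) next
    src <- set$images[, , , i]
    for (rep_i in seq_len(counts[i])) {
      s <- config$crops[sample.int(length(config$crops), 1L)]
      base_h <- (d[1] - s) %/% 2L + 1L
      base_w <- (d[2] - s) %/% 2L + 1L
      h0 <- base_h + if (config$shift > 0)
        sample(-config$shift:config$shift, 1L) else 0L
      w0 <- base_w + if (config$shift > 0)
        sample(-config$shift:config$shift, 1L) else 0L
      h0 <- min(max(h0, 1L), d[1] - s + 1L)
      w0 <- min(max(w0, 1L), d[2] - s + 1L)
      crop <- src[h0:(h0 + s - 1L), w0:(w0 + s - 1L), , drop = FALSE]
      j <- j + 1L
      images[, , , j] <- resize_to_input(crop, os)
      labels[j] <- set$labels[i]
    }
  }
  image_set(images, labels, set$class_names)
}

#' Split into training and test sets, per class
#'
#' Shuffles each class independently and moves `per_class_test` of its
#' images into the test set; the remainder form the training set. The
#' split is an exact partition: no image is lost or duplicated.
#'
#' @param set A [image_set()].
#' @param per_class_test Test images per class (default 300, the
#'   standard protocol for this problem).
#' @param seed Integer RNG seed for the shuffles.
#' @return `list(train = , test = )` of [image_set()] objects.
#' @export
split_train_test <- function(set, per_class_test = 300L, seed = 1L) {
  stopifnot(inherits(set, "gpd_image_set"), per_class_test >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in seq_along(set$class_names) - 1L) {
    idx <- which(set$labels == cl)
    if (length(idx) <= per_class_test && per_class_test > 0)
      stop(sprintf("class %s has %d images, need more than %d",
                   set$class_names[cl + 1L], length(idx), per_class_test))
    if (per_class_test > 0)
      test_idx <- c(test_idx, sample(idx)[seq_len(per_class_test)])
  }
  train_idx <- setdiff(seq_along(set$labels), test_idx)
  list(train = subset_set(set, train_idx),
       test = subset_set(set, sort(test_idx)))
}

#' Write / read an image set as a directory of PNG files
#'
#' Layout: `root/<class_name>/<id>.png`, 8-bit RGB. Reading maps
#' subdirectory names onto `class_names` order.
#'
#' @param set A [image_set()].
#' @param dir Directory root.
#' @return `write_image_dir` returns `dir` invisibly; `read_image_dir`
#'   returns a [image_set()].
#' @export
write_image_dir <- function(set, dir) {
  for (cl in seq_along(set$class_names) - 1L) {
    cdir <- file.path(dir, set$class_names[cl + 1L])
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    idx <- which(set$labels == cl)
    for (k in seq_along(idx)) {
      img <- set$images[, , , idx[k]]
      png::writePNG(img, file.path(cdir, sprintf("%05d.png", k)))
    }
  }
  invisible(dir)
}

#' @rdname write_image_dir
#' @param class_names Class order; defaults to the sorted subdirectory
#'   names.
#' @export
read_image_dir <- function(dir, class_names = NULL) {
  if (is.null(class_names))
    class_names <- sort(list.dirs(dir, recursive = FALSE,
                                  full.names = FALSE))
  if (!length(class_names)) stop("no class subdirectories under ", dir)
  imgs <- list(); labels <- integer(0)
  for (cl in seq_along(class_names) - 1L) {
    files <- sort(list.files(file.path(dir, class_names[cl + 1L]),
                             pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
      imgs[[length(imgs) + 1L]] <- a[, , 1:3]
      labels <- c(labels, cl)
    }
  }
  if (!length(imgs)) stop("no PNG images found under ", dir)
  d <- dim(imgs[[1]])
  images <- array(0, c(d[1], d[2], 3, length(imgs)))
  for (i in seq_along(imgs)) images[, , , i] <- imgs[[i]]
  image_set(images, labels, class_names)
}
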