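#' Save / load a weight store
#'
#' The store is written as a single RDS archive (one named array per
#' layer), which round-trips bit-exactly, plus a JSON sidecar
#' (`<file>.json`) describing the network layout and parameter counts so
#' an archive is self-describing without loading it.
#'
#' @param weights A `"weight_store"`.
#' @param file Archive path.
#' @param spec Optional `"gpdnet_spec"` recorded in the sidecar.
#' @return `save_weights` returns `file` invisibly; `load_weights`
#'   returns the `"weight_store"`.
#' @export
save_weights <- function(weights, file, spec = NULL) {
  stopifnot(inherits(weights, "weight_store"))
  saveRDS(weights, file)
  sidecar <- list(
    format = "gpdnet-weight-store",
    layers = lapply(names(weights), function(l)
      list(name = l,
           arrays = lapply(weights[[l]], function(a)
             as.integer(if (is.null(dim(a))) length(a) else dim(a))))))
  names(sidecar$layers) <- names(weights)
  if (!is.null(spec)) {
    sidecar$num_classes <- spec$num_classes
    sidecar$input_size <- spec$input_size
    sidecar$kernel_weights <- count_parameters(spec)
    sidecar$total_parameters <- count_parameters(spec, TRUE)
    sidecar$spec <- spec_to_list(spec)
  }
  jsonlite::write_json(sidecar, paste0(file, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname save_weights
#' @export
load_weights <- function(file) {
  w <- readRDS(file)
  if (!inherits(w, "weight_store")) stop("not a weight-store archive")
  w
}

spec_to_list <- function(spec) {
  list(num_classes = spec$num_classes, input_size = spec$input_size,
       layers = lapply(spec$layers, function(ly) unclass(ly)))
}

spec_from_list <- function(x) {
  layers <- lapply(x$layers, function(ly)
    structure(ly, class = "gpd_layer"))
  network_spec(layers, x$num_classes, x$input_size)
}

#' Save / load a network spec as JSON
#'
#' @param spec A `"gpdnet_spec"`.
#' @param file JSON path.
#' @return `save_spec` returns `file` invisibly; `load_spec` the spec.
#' @export
save_spec <- function(spec, file) {
  jsonlite::write_json(spec_to_list(spec), file, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname save_spec
#' @export
load_spec <- function(file) {
  spec_from_list(jsonlite::read_json(file, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE))
}

#' Save / load an image set as a packed archive
#'
#' Single-file alternative to the directory-of-PNG layout: the packed
#' pixel array and label vector in one RDS archive with a JSON manifest
#' sidecar.
#'
#' @param set A [image_set()].
#' @param file Archive path.
#' @return `save_image_set` returns `file` invisibly; `load_image_set`
#'   the set.
#' @export
save_image_set <- function(set, file) {
  stopifnot(inherits(set, "gpd_image_set"))
  saveRDS(set, file)
  d <- dim(set$images)
  jsonlite::write_json(
    list(format = "gpdnet-image-set", n = d[4], height = d[1],
         width = d[2], channels = d[3], class_names = set$class_names,
         per_class = as.integer(tabulate(set$labels + 1L,
                                         length(set$class_names)))),
    paste0(file, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' @rdname save_image_set
#' @export
load_image_set <- function(file) {
  s <- readRDS(file)
  if (!inherits(s, "gpd_image_set")) stop("not an image-set archive")
  s
}
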