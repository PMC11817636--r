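#' Declarative layer specification
#'
#' One layer of an [architecture_spec()]. Only the fields required by the
#' layer `kind` need to be supplied.
#'
#' @param kind one of `conv2d`, `conv3d`, `maxpool3d`, `flatten`, `dense`,
#'   `dropout`, `softmax_output`.
#' @param filters,units integer output width (convolution / dense).
#' @param kernel,stride integer kernel size and stride (convolutions).
#' @param padding `"same"` (the only mode used by these architectures).
#' @param activation `"relu"`, `"softmax"` or `"none"`.
#' @param init `"he_uniform"` or `"default"` (Glorot-uniform).
#' @param rate dropout rate (dropout only).
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kind, filters = NULL, units = NULL, kernel = NULL,
                       stride = NULL, padding = "same",
                       activation = "none", init = "default", rate = NULL) {
  kind <- match.arg(kind, c("conv2d", "conv3d", "maxpool3d", "flatten",
                            "dense", "dropout", "softmax_output"))
  if (kind %in% c("conv2d", "conv3d")) {
    stopifnot(is_count(filters), is_count(kernel), kernel >= 1,
              is_count(stride), stride >= 1)
  }
  if (kind %in% c("dense", "softmax_output")) stopifnot(is_count(units))
  if (kind == "dropout") stopifnot(is.numeric(rate), rate >= 0, rate < 1)
  structure(list(kind = kind, filters = filters, units = units,
                 kernel = kernel, stride = stride, padding = padding,
                 activation = activation, init = init, rate = rate),
            class = "layer_spec")
}

#' Architecture specification
#'
#' Ordered layer list plus input shape and class count, from which a model
#' can be instantiated ([nn_build()] internally) and its parameters counted
#' in closed form ([count_parameters()]).
#'
#' @param name architecture name.
#' @param input_shape `(H, W, B)` for 2D models or `(H, W, B, 1)` for 3D.
#' @param layers list of [layer_spec()]s; the last must be a
#'   `softmax_output` whose `units` equals `class_count`.
#' @param class_count number of output classes.
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(name, input_shape, layers, class_count) {
  last <- layers[[length(layers)]]
  if (!identical(last$kind, "softmax_output") || last$units != class_count) {
    stopf("last layer must be softmax_output with units == class_count")
  }
  structure(list(name = name, input_shape = as.integer(input_shape),
                 layers = layers, class_count = as.integer(class_count)),
            class = "architecture_spec")
}

#' The six-layer 2D CNN
#'
#' Six 2D convolutional layers with ReLU activation, filter schedule
#' (8, 8, 16, 16, 32, 32), kernel 3, same padding, stride 1 in the odd
#' layers and stride 2 in the even layers (so each pair halves the spatial
#' resolution and there are no pooling layers), followed by flatten and a
#' single dense softmax head. Band images are treated as input channels, so
#' spectral features are mixed from the first layer but no 3D convolution
#' is performed. For a 128 x 128 x 8 input and 3 classes this totals
#' exactly 43,123 trainable parameters.
#'
#' @param input_shape `(H, W, B)`; spatial size must be at least 16.
#' @param class_count number of classes (default 3).
#' @return An [architecture_spec()].
#' @examples
#' count_parameters(spec_cnn2d(c(128, 128, 8), 3))
#' @export
spec_cnn2d <- function(input_shape = c(128, 128, 8), class_count = 3L) {
  stopifnot(length(input_shape) == 3L, all(input_shape[1:2] >= 16))
  filters <- c(8, 8, 16, 16, 32, 32)
  strides <- c(1, 2, 1, 2, 1, 2)
  layers <- mapply(function(f, s) {
    layer_spec("conv2d", filters = f, kernel = 3L, stride = s,
               activation = "relu", init = "he_uniform")
  }, filters, strides, SIMPLIFY = FALSE)
  layers <- c(layers, list(layer_spec("flatten"),
                           layer_spec("softmax_output", units = class_count)))
  architecture_spec("cnn2d", input_shape, layers, class_count)
}

#' The VGG-16 variant with 3D convolutions
#'
#' Thirteen 3D convolutional layers in five blocks with filter schedule
#' (64,64 | 128,128 | 256,256,256 | 256,256,256 | 512,512,512) — note the
#' fourth block keeps 256 filters rather than the canonical 512 — kernel 3,
#' stride 1, same padding, ReLU and He-uniform initialisation; each block
#' is followed by a (2,2,2) 3D max pooling with ceil-mode so the 8-deep
#' band axis survives all five pools (8-4-2-1-1-1). The head is flatten,
#' dense(ReLU) + dropout(0.5) twice, then a dense softmax. The hidden dense
#' widths default to the canonical 4096 and are exposed because narrower
#' heads are useful at reduced input sizes.
#'
#' @param input_shape `(H, W, B, 1)`: two spatial axes, the band axis as
#'   convolution depth, one channel.
#' @param class_count number of classes (default 3).
#' @param dense_units widths of the two hidden dense layers.
#' @param dropout_rate dropout after each hidden dense layer (default 0.5).
#' @return An [architecture_spec()].
#' @export
spec_vgg16_3d <- function(input_shape = c(128, 128, 8, 1), class_count = 3L,
                          dense_units = c(4096L, 4096L), dropout_rate = 0.5) {
  stopifnot(length(input_shape) == 4L, input_shape[3] >= 1)
  blocks <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                 c(256, 256, 256), c(512, 512, 512))
  layers <- list()
  for (bl in blocks) {
    for (f in bl) {
      layers[[length(layers) + 1L]] <-
        layer_spec("conv3d", filters = f, kernel = 3L, stride = 1L,
                   activation = "relu", init = "he_uniform")
    }
    layers[[length(layers) + 1L]] <- layer_spec("maxpool3d")
  }
  layers[[length(layers) + 1L]] <- layer_spec("flatten")
  for (u in dense_units) {
    layers[[length(layers) + 1L]] <-
      layer_spec("dense", units = u, activation = "relu", init = "he_uniform")
    layers[[length(layers) + 1L]] <- layer_spec("dropout", rate = dropout_rate)
  }
  layers[[length(layers) + 1L]] <-
    layer_spec("softmax_output", units = class_count)
  architecture_spec("vgg16_3d", input_shape, layers, class_count)
}

#' Closed-form trainable parameter count of an architecture
#'
#' Walks the layer list propagating shapes: a convolution contributes
#' `kernel_volume * in_channels * filters + filters`, a dense layer
#' `in * units + units`; pooling, flatten and dropout contribute nothing.
#' Equals the instantiated model's trainable total.
#'
#' @param spec an [architecture_spec()].
#' @return integer parameter count.
#' @examples
#' count_parameters(spec_cnn2d(c(128, 128, 8), 3)) # 43123
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  shape <- spec$input_shape
  total <- 0
  for (ls in spec$layers) {
    if (ls$kind %in% c("conv2d", "conv3d")) {
      nd <- if (ls$kind == "conv2d") 2L else 3L
      C <- shape[nd + 1L]
      total <- total + ls$kernel^nd * C * ls$filters + ls$filters
      shape <- c(vapply(shape[seq_len(nd)], .conv_out, integer(1),
                        s = ls$stride), ls$filters)
    } else if (ls$kind == "maxpool3d") {
      shape <- c(vapply(shape[1:3], .conv_out, integer(1), s = 2L), shape[4])
    } else if (ls$kind == "flatten") {
      shape <- prod(shape)
    } else if (ls$kind %in% c("dense", "softmax_output")) {
      total <- total + shape * ls$units + ls$units
      shape <- ls$units
    }
    if (any(shape < 1)) stopf("shape collapsed to zero at '%s'", ls$kind)
  }
  as.integer(total)
}

#' Build a trainable model from an architecture specification
#'
#' Instantiates weights (He-uniform or Glorot-uniform per layer spec) and
#' precomputes the gather tables used by the convolution layers.
#'
#' @param spec an [architecture_spec()].
#' @param seed optional integer seed for the weight draws.
#' @return A `trainable_model` whose `parameter_count` equals
#'   [count_parameters()] of the spec.
#' @export
build_model <- function(spec, seed = NULL) nn_build(spec, seed)

#' Weighted categorical cross-entropy on normalized scores
#'
#' `CE = -sum_i w_i * t_i * log(s_i)`, averaged over the batch. With unit
#' weights this is the plain categorical cross-entropy; class weights scale
#' each sample's contribution by the weight of its true class. Scores must
#' already be softmax-normalized; a small floor (1e-7) guards the log.
#'
#' @param truth_onehot N x C one-hot matrix (or length-C vector).
#' @param scores N x C matrix of class probabilities, rows summing to 1.
#' @param weights per-class weights (default all 1).
#' @return scalar loss.
#' @examples
#' weighted_categorical_cross_entropy(c(0, 1, 0), c(0.2, 0.5, 0.3)) # -log(0.5)
#' @export
weighted_categorical_cross_entropy <- function(truth_onehot, scores,
                                               weights = NULL) {
  if (is.null(dim(scores))) {
    scores <- matrix(scores, 1)
    truth_onehot <- matrix(truth_onehot, 1)
  }
  if (any(abs(rowSums(scores) - 1) > 1e-5)) {
    stopf("scores are not softmax-normalized (rows must sum to 1)")
  }
  C <- ncol(scores)
  w <- weights %||% rep(1, C)
  per <- -rowSums(truth_onehot * rep(w, each = nrow(scores)) *
                    log(pmax(scores, 1e-7)))
  mean(per)
}
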