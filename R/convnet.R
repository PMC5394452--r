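#' Tile-classification ConvNets
#'
#' Three small convolutional architectures score 50 x 50 px YUV tiles as
#' invasive vs non-invasive:
#'
#' * `three_layer`: one conv+pool stage with 256 feature maps, a fully
#'   connected layer of 256 units, and a 2-unit softmax output;
#' * `four_layer`: conv+pool stages of 16 then 32 maps, 128 fully connected
#'   units, 2 outputs;
#' * `six_layer`: four conv+pool stages of 16 maps, 128 fully connected
#'   units, 2 outputs.
#'
#' Every conv stage uses a 5 x 5 kernel with zero padding 2 ("same") and
#' 2 x 2 L2-norm pooling with stride 2; the nonlinearity is ReLU. Training
#' is plain stochastic gradient descent over shuffled mini-batches with a
#' per-update learning-rate decay `rate_t = lr / (1 + decay * t)`.
#'
#' @name convnet
NULL

#' Describe one of the three candidate architectures
#'
#' @param arch_name one of `"three_layer"`, `"four_layer"`, `"six_layer"`.
#' @param input_side_px network input side in pixels (default 50, a 200 um
#'   tile at 4 um/pixel); must be at least 16.
#' @return An object of class `convnet_spec` with the ordered layer
#'   descriptors, input geometry and conv/pool hyper-geometry.
#' @export
build_convnet <- function(arch_name = c("three_layer", "four_layer", "six_layer"),
                          input_side_px = 50L) {
  arch_name <- tryCatch(match.arg(arch_name),
                        error = function(e) stop_wsi(
                          "unknown architecture: ", arch_name[1],
                          class = "configuration_error"))
  input_side_px <- as.integer(input_side_px)
  if (input_side_px < 16L)
    stop_wsi("input side must be at least 16 px", class = "configuration_error")
  conv_maps <- switch(arch_name,
                      three_layer = 256L,
                      four_layer = c(16L, 32L),
                      six_layer = rep(16L, 4L))
  fc_units <- switch(arch_name, three_layer = 256L, 128L)
  layers <- c(lapply(conv_maps, function(m)
                list(kind = "conv+pool", units = m, kernel = 5L, pad = 2L, pool = 2L)),
              list(list(kind = "fully_connected", units = fc_units)),
              list(list(kind = "softmax_output", units = 2L)))
  spec <- structure(list(arch_name = arch_name, layers = layers,
                         conv_maps = conv_maps, fc_units = fc_units,
                         kernel = 5L, pad = 2L, pool = 2L,
                         input_side_px = input_side_px, input_channels = 3L),
                    class = "convnet_spec")
  # fails here if the geometry cannot support the stage stack
  cnn_flat_dim_cpp(input_side_px, input_side_px, 3L, conv_maps, 5L, 2L, 2L)
  spec
}

#' @export
print.convnet_spec <- function(x, ...) {
  cat(sprintf("<convnet_spec '%s'> input %d x %d x %d\n", x$arch_name,
              x$input_side_px, x$input_side_px, x$input_channels))
  for (l in x$layers)
    cat(sprintf("  %-16s %d units\n", l$kind, l$units))
  invisible(x)
}

#' Training configuration
#'
#' Defaults are the recipe used throughout: 25 epochs, mini-batch 32,
#' learning rate 1e-3 with per-update decay 1e-7, ReLU nonlinearity and
#' L2-norm pooling (both fixed by the architectures), seeded weight
#' initialization and shuffling, and 8-fold positive-class augmentation.
#'
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param learning_rate base SGD step size.
#' @param learning_rate_decay per-update decay of the base rate.
#' @param seed integer seed controlling initialization and shuffling.
#' @param augmentation_factor orientations per positive patch (1-8).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 25L, batch_size = 32L, learning_rate = 1e-3,
                         learning_rate_decay = 1e-7, seed = 1L,
                         augmentation_factor = 8L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 learning_rate_decay = learning_rate_decay,
                 nonlinearity = "ReLU", pooling = "L2-norm",
                 seed = as.integer(seed),
                 augmentation_factor = as.integer(augmentation_factor)),
            class = "train_config")
}

#' Train a tile-classification ConvNet
#'
#' Fits the network by stochastic gradient descent on labeled, normalized
#' patches. The run is fully reproducible given `config$seed`: weight
#' initialization and per-epoch shuffling are driven by one seeded
#' generator. Per-epoch training loss (mean negative log-likelihood) and
#' accuracy are recorded.
#'
#' @param spec a [build_convnet()] architecture.
#' @param patches a normalized `patch_set` (see [normalize_patches()]) whose
#'   labels contain both classes.
#' @param config a [train_config()].
#' @param norm_stats the frozen [fit_normalization()] object the patches
#'   were standardized with; stored on the model so inference can reuse it.
#' @return An object of class `convnet`: `spec`, `weights`, `norm_stats`,
#'   `history` (per-epoch loss/accuracy), `config`, `seed`.
#' @export
train_convnet <- function(spec, patches, config = train_config(),
                          norm_stats = NULL) {
  stopifnot(inherits(spec, "convnet_spec"), inherits(patches, "patch_set"))
  if (!isTRUE(patches$normalized))
    stop_wsi("patches must be normalized before training", class = "usage_error")
  y <- match(patches$labels, c("negative", "positive")) - 1L
  if (anyNA(y))
    stop_wsi("all patches must be labeled positive or negative",
             class = "training_error")
  if (length(unique(y)) < 2L)
    stop_wsi("training set must contain both classes", class = "training_error")
  if (patches$side != spec$input_side_px)
    stop_wsi(sprintf("patch side %d does not match network input %d",
                     patches$side, spec$input_side_px), class = "shape_error")
  fit <- cnn_train_cpp(patches$x, y,
                       spec$input_side_px, spec$input_side_px, 3L,
                       spec$conv_maps, spec$fc_units,
                       spec$kernel, spec$pad, spec$pool,
                       config$epochs, config$batch_size,
                       config$learning_rate, config$learning_rate_decay,
                       config$seed)
  structure(list(spec = spec, weights = fit$weights, norm_stats = norm_stats,
                 history = fit$history, config = config, seed = config$seed),
            class = "convnet")
}

#' @export
print.convnet <- function(x, ...) {
  h <- x$history
  cat(sprintf("<convnet '%s'> trained %d epochs; final loss %.4f, accuracy %.4f\n",
              x$spec$arch_name, nrow(h), h$loss[nrow(h)], h$accuracy[nrow(h)]))
  invisible(x)
}

#' @export
summary.convnet <- function(object, ...) {
  print(object$spec)
  h <- object$history
  cat(sprintf("epochs %d | batch %d | lr %g | decay %g | seed %d\n",
              object$config$epochs, object$config$batch_size,
              object$config$learning_rate, object$config$learning_rate_decay,
              object$seed))
  cat(sprintf("training loss %.4f -> %.4f, accuracy %.4f -> %.4f\n",
              h$loss[1], h$loss[nrow(h)], h$accuracy[1], h$accuracy[nrow(h)]))
  invisible(object)
}

#' @export
coef.convnet <- function(object, ...) object$weights

#' Plot the training history of a fitted ConvNet
#'
#' @param x a `convnet`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.convnet <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = x$spec$arch_name, ...)
  invisible(x)
}

#' Predict class probabilities for tile patches
#'
#' Probabilities are a pure function of the weights and the input: two
#' values per patch (non-invasive, invasive), each in `[0, 1]` and summing
#' to one, independent of batch composition and patch order.
#'
#' @param object a fitted `convnet`.
#' @param patches a normalized `patch_set` matching the network input
#'   geometry.
#' @param ... unused.
#' @return An `n x 2` matrix with columns `p_negative`, `p_positive`.
#' @export
predict.convnet <- function(object, patches, ...) {
  stopifnot(inherits(patches, "patch_set"))
  if (!isTRUE(patches$normalized))
    stop_wsi("patches must be normalized with the model's frozen stats",
             class = "usage_error")
  spec <- object$spec
  if (patches$side != spec$input_side_px)
    stop_wsi("patch geometry does not match the network input", class = "shape_error")
  p <- cnn_predict_cpp(patches$x, object$weights,
                       spec$input_side_px, spec$input_side_px, 3L,
                       spec$conv_maps, spec$fc_units,
                       spec$kernel, spec$pad, spec$pool)
  colnames(p) <- c("p_negative", "p_positive")
  p
}

#' Save or load a model checkpoint
#'
#' The checkpoint bundles weights, architecture, frozen normalization
#' statistics, training configuration and seed.
#'
#' @param model a `convnet`.
#' @param path checkpoint file path (RDS).
#' @export
save_convnet <- function(model, path) {
  stopifnot(inherits(model, "convnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_convnet
#' @export
load_convnet <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "convnet"))
  m
}
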