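#' Network architecture configuration
#'
#' A five-level encoder-decoder ("U-net" style) heatmap regressor: one
#' 3x3 convolution + ReLU per encoder level with 2x2 max pooling between
#' levels, a decoder mirroring the encoder with nearest-neighbour
#' upsampling and skip-connection concatenation, and a final 1x1
#' convolution with a sigmoid bounding the 6 output channels to `[0, 1]`.
#' Filter counts double per level starting from `base_filters`.
#'
#' @param input_size Input side length in pixels (default 512); must be
#'   divisible by `2^(n_levels - 1)`.
#' @param n_levels Number of resolution levels (default 5).
#' @param out_channels Output channels (6 bone-axis heatmaps).
#' @param base_filters Filters at the finest level (default 16).
#' @return A `model_config` object.
#' @export
model_config <- function(input_size = 512, n_levels = 5, out_channels = 6,
                        base_filters = 16) {
  stopifnot(n_levels >= 2, out_channels == 6, base_filters >= 1)
  if (input_size %% 2^(n_levels - 1) != 0) {
    stop("configuration error: input_size must be divisible by 2^(n_levels-1)",
         call. = FALSE)
  }
  structure(list(input_size = as.integer(input_size),
                 n_levels = as.integer(n_levels),
                 out_channels = as.integer(out_channels),
                 base_filters = as.integer(base_filters)),
            class = "model_config")
}

#' Training protocol configuration
#'
#' Defaults are the fixed protocol used for the full-scale clinical
#' model: Adam, at most 12 epochs, minibatch size 7, initial learning
#' rate 1e-4, validation every 200 iterations, early stopping after 10
#' consecutive non-improving validations.
#'
#' @param max_epochs Maximum passes over the training set (default 12).
#' @param minibatch_size Images per gradient step (default 7).
#' @param initial_learning_rate Adam learning rate (default 1e-4).
#' @param validation_frequency Iterations between validation evaluations
#'   (default 200).
#' @param validation_patience Consecutive non-improving validations
#'   tolerated before stopping (default 10).
#' @param seed Integer seed for minibatch shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(max_epochs = 12, minibatch_size = 7,
                         initial_learning_rate = 1e-4,
                         validation_frequency = 200,
                         validation_patience = 10, seed = 1L) {
  stopifnot(max_epochs >= 1, minibatch_size >= 1,
            initial_learning_rate > 0, validation_frequency >= 1,
            validation_patience >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 minibatch_size = as.integer(minibatch_size),
                 initial_learning_rate = initial_learning_rate,
                 validation_frequency = as.integer(validation_frequency),
                 validation_patience = as.integer(validation_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Filters at level l (1-based).
level_filters <- function(config, l) {
  config$base_filters * 2^(l - 1)
}

# Expected weight shapes for a config; used by the initializer and by the
# checkpoint loader for structural validation.
weight_shapes <- function(config) {
  NL <- config$n_levels
  shapes <- list()
  cin <- 1
  for (l in seq_len(NL)) {
    f <- level_filters(config, l)
    shapes[[paste0("enc", l, "_W")]] <- c(9 * cin, f)
    shapes[[paste0("enc", l, "_b")]] <- f
    cin <- f
  }
  for (l in seq_len(NL - 1)) {
    f <- level_filters(config, l)
    fup <- level_filters(config, l + 1)
    shapes[[paste0("dec", l, "_W")]] <- c(9 * (fup + f), f)
    shapes[[paste0("dec", l, "_b")]] <- f
  }
  shapes[["out_W"]] <- c(level_filters(config, 1), config$out_channels)
  shapes[["out_b"]] <- config$out_channels
  shapes
}

#' Build an untrained network
#'
#' Allocates He-initialized weights (Xavier for the sigmoid output head)
#' for the encoder-decoder described by a [model_config()].
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return A `ba_network`: list with `config`, `weights`, and an empty
#'   training `history`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  shapes <- weight_shapes(config)
  weights <- with_seed(seed, {
    lapply(names(shapes), function(nm) {
      s <- shapes[[nm]]
      if (length(s) == 2) {
        sd <- if (nm == "out_W") sqrt(1 / s[1]) else sqrt(2 / s[1])
        matrix(stats::rnorm(prod(s), sd = sd), s[1], s[2])
      } else {
        numeric(s)
      }
    })
  })
  names(weights) <- names(shapes)
  # start the sigmoid head at the typical heatmap foreground prior
  # (~5-8% of pixels): avoids the early collapse into the all-background
  # solution, whose saturated sigmoid passes almost no gradient
  weights$out_b <- rep(-2.5, config$out_channels)
  structure(list(config = config, weights = weights, history = NULL),
            class = "ba_network")
}

#' Root-mean-square error between two heatmap stacks
#'
#' @param predicted,target Arrays of identical dimension.
#' @return Non-negative scalar; 0 iff the stacks are identical.
#' @export
rmse_loss <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target))) {
    stop("shape mismatch between predicted and target stacks",
         call. = FALSE)
  }
  sqrt(mean((predicted - target)^2))
}

# Build (image, target-heatmap) pairs from ba_samples.
training_pairs <- function(samples) {
  list(x = lapply(samples, function(s) s$image),
       y = lapply(samples, function(s) make_heatmaps(s$annotation)))
}

#' Train the network on (image, heatmap) pairs
#'
#' Minimizes the per-image RMSE (averaged over each minibatch) with Adam.
#' The validation loss is evaluated every `validation_frequency`
#' iterations; training stops early after `validation_patience`
#' consecutive non-improving validations, or at `max_epochs`. The
#' checkpoint with the best validation loss is returned.
#'
#' @param network A `ba_network` from [build_model()].
#' @param train,val Lists of `ba_sample`s (with annotations), or lists
#'   with elements `x` (image matrices) and `y` (target heatmap arrays) as
#'   produced by the internal pair builder.
#' @param config A [train_config()].
#' @return The trained `ba_network`; `history` holds the per-iteration
#'   training loss and the validation-loss trace, plus the iteration
#'   count and best validation loss.
#' @export
train_model <- function(network, train, val, config = train_config()) {
  stopifnot(inherits(network, "ba_network"),
            inherits(config, "train_config"))
  if (length(train) == 0) stop("empty training set", call. = FALSE)
  tp <- if (is.list(train) && !is.null(train$x)) train else
    training_pairs(train)
  vp <- if (length(val) == 0) list(x = list(), y = list()) else
    if (is.list(val) && !is.null(val$x)) val else training_pairs(val)
  size <- network$config$input_size
  for (img in tp$x) {
    if (!all(dim(img) == c(size, size))) {
      stop("training image size does not match the network input size (",
           size, ")", call. = FALSE)
    }
  }
  res <- cpp_unet_train(network$weights, tp$x, tp$y, vp$x, vp$y,
                        network$config$n_levels,
                        config$initial_learning_rate,
                        config$minibatch_size, config$max_epochs,
                        config$validation_frequency,
                        config$validation_patience, config$seed)
  network$weights <- res$weights
  network$history <- list(trace = res$history,
                          iterations = res$iterations,
                          best_val = res$best_val)
  network
}

#' Predict the 6-channel heatmap stack for one image
#'
#' @param network A `ba_network`.
#' @param image Standardized square matrix matching the network's
#'   `input_size`.
#' @return Array `input_size` x `input_size` x 6, values in `[0, 1]`,
#'   channels named in bone order.
#' @export
predict_heatmaps <- function(network, image) {
  stopifnot(inherits(network, "ba_network"), is.matrix(image))
  size <- network$config$input_size
  if (!all(dim(image) == c(size, size))) {
    stop("wrong input size: expected ", size, " x ", size, ", got ",
         nrow(image), " x ", ncol(image), call. = FALSE)
  }
  out <- cpp_unet_forward(network$weights, image,
                          network$config$n_levels)
  dimnames(out) <- list(NULL, NULL, BONE_LABELS)
  out
}

#' Save / load a network checkpoint
#'
#' Single-file serialized weights plus the model configuration. The
#' loader re-derives the expected weight shapes from the stored
#' configuration and refuses a checkpoint whose weights do not match.
#'
#' @param network A `ba_network`.
#' @param path File path.
#' @return `load_model` returns the `ba_network`; `save_model` returns
#'   `path` invisibly.
#' @export
save_model <- function(network, path) {
  stopifnot(inherits(network, "ba_network"))
  saveRDS(list(format = "boneaxis_checkpoint", config = network$config,
               weights = network$weights, history = network$history),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "boneaxis_checkpoint")) {
    stop("not a boneaxis checkpoint: ", path, call. = FALSE)
  }
  shapes <- weight_shapes(obj$config)
  for (nm in names(shapes)) {
    w <- obj$weights[[nm]]
    s <- shapes[[nm]]
    ok <- if (length(s) == 2) is.matrix(w) && all(dim(w) == s) else
      is.numeric(w) && length(w) == s
    if (is.null(w) || !ok) {
      stop("corrupt checkpoint: weight ", nm,
           " does not match the stored configuration", call. = FALSE)
    }
  }
  structure(list(config = obj$config, weights = obj$weights,
                 history = obj$history),
            class = "ba_network")
}
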