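# Training backend wrapper: turns a repaired architecture into a compiled
# network plan, initializes weights, trains with SGD + momentum under the
# piecewise learning-rate schedule, and predicts class probabilities.

#' Training configuration
#'
#' Defaults follow the study protocol: SGD with momentum 0.9, initial
#' learning rate 1e-4 dropped multiplicatively by 20% every 5 epochs
#' (piecewise schedule), mini-batch 32, L2 regularization 1e-4 on weights,
#' validation every 50 iterations.
#'
#' @param epochs Training epochs (5 for screening, 50 for final training).
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial learning rate.
#' @param lr_drop Multiplicative factor applied every `lr_period` epochs.
#' @param lr_period Epochs between learning-rate drops.
#' @param momentum SGD momentum.
#' @param l2 L2 regularization coefficient (weights only, not biases).
#' @param validation_frequency Iterations between validation evaluations.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 32, initial_lr = 1e-4,
                         lr_drop = 0.8, lr_period = 5, momentum = 0.9,
                         l2 = 1e-4, validation_frequency = 50, seed = 1) {
  stopifnot(batch_size >= 1, initial_lr > 0, lr_drop > 0, lr_drop <= 1,
            lr_period >= 1, momentum >= 0, momentum < 1, l2 >= 0)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_drop = lr_drop,
                 lr_period = as.integer(lr_period), momentum = momentum,
                 l2 = l2,
                 validation_frequency = as.integer(validation_frequency),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Piecewise learning-rate schedule
#'
#' `lr(e) = initial_lr * lr_drop ^ floor(e / lr_period)` for 0-based epoch
#' `e`; nonincreasing by construction.
#'
#' @param config A [train_config()].
#' @param epochs Number of epochs to tabulate (defaults to the config's).
#' @return Numeric vector of per-epoch learning rates.
#' @export
lr_schedule <- function(config, epochs = config$epochs) {
  e <- seq_len(epochs) - 1
  config$initial_lr * config$lr_drop^floor(e / config$lr_period)
}

# Lower a repaired arch_spec to the primitive plan consumed by the compiled
# backend: feature layers, then gap, hidden fcs, and the output fc.
net_plan <- function(arch) {
  stopifnot(inherits(arch, "arch_spec"))
  tb <- propagate_shapes(arch)
  if (any(!tb$feasible))
    stop("architecture has infeasible layers; repair first", call. = FALSE)
  plan <- list()
  cin <- arch$input_shape[3]
  fcs <- list()
  for (ly in arch$layers) {
    if (ly$type == "conv") {
      plan[[length(plan) + 1]] <- list(type = "conv", fs = ly$filter_size,
                                       stride = ly$stride, cin = cin,
                                       cout = ly$num_filters)
      cin <- ly$num_filters
    } else if (ly$type == "multibranch") {
      plan[[length(plan) + 1]] <- list(type = "mb", nb = ly$num_branches,
                                       cin = cin,
                                       cout = ly$filters_per_branch)
      cin <- ly$num_branches * ly$filters_per_branch
    } else if (ly$type == "pool") {
      plan[[length(plan) + 1]] <- list(type = "pool", pool = ly$pool_type,
                                       fs = ly$filter_size,
                                       stride = ly$stride)
    } else {
      fcs[[length(fcs) + 1]] <- ly
    }
  }
  plan[[length(plan) + 1]] <- list(type = "gap")
  for (ly in fcs) {
    plan[[length(plan) + 1]] <- list(type = "fc", cin = cin,
                                     cout = ly$num_neurons, relu = TRUE)
    cin <- ly$num_neurons
  }
  plan[[length(plan) + 1]] <- list(type = "fc", cin = cin,
                                   cout = arch$num_classes, relu = FALSE)
  plan
}

# He-normal initialization: sd = sqrt(2 / fan_in) for every weight matrix,
# zero biases. Returns the flat weight list the backend consumes.
init_weights <- function(plan, seed = 1) {
  local_seed(seed, {
    weights <- list()
    for (pl in plan) {
      if (pl$type %in% c("conv", "mb")) {
        nb <- if (pl$type == "mb") pl$nb else 1L
        for (b in seq_len(nb)) {
          fs <- if (pl$type == "mb") 2L * b - 1L else pl$fs
          fan_in <- fs^2 * pl$cin
          weights[[length(weights) + 1]] <-
            matrix(rnorm(pl$cout * fan_in, sd = sqrt(2 / fan_in)),
                   nrow = pl$cout)
          weights[[length(weights) + 1]] <- numeric(pl$cout)
        }
      } else if (pl$type == "fc") {
        weights[[length(weights) + 1]] <-
          matrix(rnorm(pl$cout * pl$cin, sd = sqrt(2 / pl$cin)),
                 nrow = pl$cout)
        weights[[length(weights) + 1]] <- numeric(pl$cout)
      }
    }
    weights
  })
}

#' Learnable values enumerated by the training backend
#'
#' Independent cross-check for [count_parameters()]: builds the compiled
#' network for `arch` and sums the element counts of every weight tensor
#' the backend actually allocates.
#'
#' @param arch A repaired `arch_spec`.
#' @return Total number of learnable scalars.
#' @export
backend_parameter_count <- function(arch) {
  plan <- net_plan(arch)
  weights <- init_weights(plan, seed = 0)
  sum(cpp_weight_sizes(plan, weights))
}

# Dataset images (H, W, C, N in 0..255) -> centered float array.
.prep_images <- function(images) images / 255 - 0.5

#' Train a decoded architecture
#'
#' Trains with softmax cross-entropy using SGD with momentum, L2 on
#' weights, and the piecewise learning-rate schedule of
#' [lr_schedule()]. Training/validation accuracy and loss are recorded
#' every `validation_frequency` iterations. Deterministic under the config
#' seed (single-threaded backend; weight init and batch order come from
#' R's RNG).
#'
#' @param arch A repaired, feasible `arch_spec` matching the data shape.
#' @param train,validation `image_dataset` objects.
#' @param config A [train_config()].
#' @return Object of class `nas_model`: `arch`, `plan`, `weights`,
#'   `curves` (data frame), `val_accuracy`, `val_loss`, `ok`.
#' @export
train_model <- function(arch, train, validation, config = train_config()) {
  stopifnot(inherits(arch, "arch_spec"), inherits(config, "train_config"))
  shp <- dim(train$images)[1:3]
  if (!all(shp == arch$input_shape))
    stop("data shape ", paste(shp, collapse = "x"),
         " does not match architecture input ",
         paste(arch$input_shape, collapse = "x"), call. = FALSE)
  plan <- net_plan(arch)
  weights <- init_weights(plan, seed = derive_seed(config$seed, 1))
  n <- length(train$labels)
  order0 <- local_seed(derive_seed(config$seed, 2), {
    unlist(lapply(seq_len(config$epochs), function(e) sample.int(n) - 1L))
  })
  res <- cpp_train_net(plan, weights,
                       .prep_images(train$images),
                       as.integer(train$labels - 1L),
                       .prep_images(validation$images),
                       as.integer(validation$labels - 1L),
                       lr_schedule(config), config$momentum, config$l2,
                       config$batch_size, as.integer(order0),
                       config$validation_frequency)
  curves <- as.data.frame(res$curves)
  structure(list(arch = arch, plan = plan, weights = res$weights,
                 curves = curves, val_accuracy = res$val_accuracy,
                 val_loss = res$val_loss, ok = res$ok,
                 class_names = train$class_names, config = config),
            class = "nas_model")
}

#' Predict class probabilities
#'
#' @param object A trained `nas_model`.
#' @param newdata An `image_dataset` or an image array `(H, W, C, N)` with
#'   intensities in 0..255.
#' @param ... Unused.
#' @return `N x K` matrix of class probabilities (rows sum to 1).
#' @export
predict.nas_model <- function(object, newdata, ...) {
  images <- if (inherits(newdata, "image_dataset")) newdata$images else newdata
  probs <- cpp_predict_net(object$plan, object$weights,
                           .prep_images(images))
  colnames(probs) <- object$class_names
  probs
}

#' @export
print.nas_model <- function(x, ...) {
  cat(sprintf("<nas_model> %s; val accuracy %.4f\n",
              if (isTRUE(x$ok)) "trained" else "aborted (non-finite loss)",
              x$val_accuracy))
  invisible(x)
}
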