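#' Specification of an AlexNet-shaped network
#'
#' Eight weighted layers: five convolutional (96, 256, 384, 384, 256
#' kernels at multiplier 1.0, sizes 11/5/3/3/3, classic strides and
#' padding, response normalization and 3x3 max pooling after layers 1, 2
#' and 5) and three fully connected (4096, 4096, `n_classes`), with ReLU
#' after every weighted layer and dropout after the first two fully
#' connected ones. The 3-D variant extends kernels and pooling in depth,
#' clipping kernel depth to the available extent with same-padding.
#'
#' @param dimensionality `"2D"` (227x227x3 images) or `"3D"` (227x227x5
#'   cubes).
#' @param width Width multiplier on filter counts and fully connected
#'   sizes; 1.0 is full scale, smaller values give desk-scale networks.
#' @param n_classes Number of output classes.
#' @param dropout Dropout rate after the first two fully connected layers.
#' @param init `"random"`, or a path to an external checkpoint written by
#'   [save_net()] whose weights initialize the network.
#' @return A `net_spec` list.
#' @export
net_spec <- function(dimensionality = c("2D", "3D"), width = 1.0,
                     n_classes = 2L, dropout = 0.5, init = "random") {
  dimensionality <- match.arg(dimensionality)
  if (width <= 0) abort("width multiplier must be positive")
  structure(list(dimensionality = dimensionality, width = width,
                 n_classes = as.integer(n_classes), dropout = dropout,
                 init = init),
            class = "net_spec")
}

scaled <- function(n, width) max(1L, as.integer(round(n * width)))

#' Build a trainable network from a specification
#'
#' @param spec A [net_spec()].
#' @param input_dim Input dimensions; defaults to `c(227, 227, 3)` for 2-D
#'   and `c(227, 227, 5)` for 3-D specifications. Anything else errors.
#' @return A `conv_net` object holding the layer stack (with precomputed
#'   patch index tables) and the spec.
#' @export
build_net <- function(spec, input_dim = NULL) {
  is3d <- spec$dimensionality == "3D"
  expected <- if (is3d) c(227L, 227L, 5L) else c(227L, 227L, 3L)
  input_dim <- input_dim %||% expected
  if (!identical(as.integer(input_dim), expected)) {
    abort(sprintf("input must be %s for a %s network",
                  paste(expected, collapse = "x"), spec$dimensionality))
  }
  w <- spec$width
  dims <- if (is3d) c(227L, 227L, 5L, 1L) else c(227L, 227L, 1L, 3L)
  kd <- function(nominal) if (is3d) nominal else 1L
  layers <- list()
  push <- function(l) layers[[length(layers) + 1]] <<- l
  cur <- function() layers[[length(layers)]]$out_dims

  push(layer_conv(dims, scaled(96, w), 11L, kd(11L), 4L, 0L))
  push(layer_relu(cur()))
  push(layer_lrn(cur()))
  push(layer_pool(cur(), kd = kd(3L)))
  push(layer_conv(cur(), scaled(256, w), 5L, kd(5L), 1L, 2L))
  push(layer_relu(cur()))
  push(layer_lrn(cur()))
  push(layer_pool(cur(), kd = kd(3L)))
  push(layer_conv(cur(), scaled(384, w), 3L, kd(3L), 1L, 1L))
  push(layer_relu(cur()))
  push(layer_conv(cur(), scaled(384, w), 3L, kd(3L), 1L, 1L))
  push(layer_relu(cur()))
  push(layer_conv(cur(), scaled(256, w), 3L, kd(3L), 1L, 1L))
  push(layer_relu(cur()))
  push(layer_pool(cur(), kd = kd(3L)))
  push(layer_flatten(cur()))
  push(layer_fc(cur(), scaled(4096, w)))
  push(layer_relu(cur()))
  push(layer_dropout(cur(), spec$dropout))
  push(layer_fc(cur(), scaled(4096, w)))
  push(layer_relu(cur()))
  push(layer_dropout(cur(), spec$dropout))
  push(layer_fc(cur(), spec$n_classes))

  net <- structure(list(layers = layers, spec = spec,
                        input_dim = as.integer(input_dim),
                        classes = c("calm", "distress")),
                   class = "conv_net")
  if (!identical(spec$init, "random")) net <- load_net(spec$init, net)
  net
}

#' @export
print.conv_net <- function(x, ...) {
  nw <- sum(vapply(x$layers, function(l) {
    if (!is.null(l$W)) length(l$W) + length(l$b) else 0L
  }, numeric(1)))
  cat(sprintf("<conv_net> %s, width %.2g, %d layers, %s parameters\n",
              x$spec$dimensionality, x$spec$width, length(x$layers),
              format(nw, big.mark = ",")))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: stochastic gradient descent
#' with momentum 0.9, constant learning rate 0.001, L2 weight decay 0.001
#' on convolutional weights, mini-batches of 12, validation every 50
#' iterations; 40 epochs x 103 iterations for 2-D networks (250 x 50 for
#' 3-D ones).
#'
#' @param epochs Training epochs.
#' @param iterations Iterations per epoch; `NULL` derives
#'   `floor(n_train / batch_size)` at training time (a configured value
#'   wins over the derived one, with a warning on mismatch).
#' @param batch_size Mini-batch size.
#' @param learning_rate Constant learning rate.
#' @param momentum SGD momentum.
#' @param l2_decay L2 weight decay applied to convolutional weights.
#' @param validate_every Validation interval in iterations.
#' @param seed RNG seed for shuffling, dropout and initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 40, iterations = NULL, batch_size = 12,
                         learning_rate = 0.001, momentum = 0.9,
                         l2_decay = 0.001, validate_every = 50,
                         seed = 1L) {
  vals <- c(epochs, batch_size, learning_rate, momentum, validate_every)
  if (any(vals <= 0) || l2_decay < 0) {
    abort("training parameters must be positive")
  }
  structure(list(epochs = as.integer(epochs), iterations = iterations,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 l2_decay = l2_decay,
                 validate_every = as.integer(validate_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

as_input_tensor <- function(img, input_dim) {
  if (inherits(img, "spectral_cube")) {
    x <- array(img$values, c(dim(img$values)[1:2], dim(img$values)[3], 1L))
  } else if (inherits(img, "rgb_image") ||
             (is.array(img) && length(dim(img)) == 3)) {
    a <- unclass(img)
    if (max(a) > 1) a <- a / 255
    x <- array(a, c(dim(a)[1:2], 1L, dim(a)[3]))
  } else {
    abort("unsupported image object")
  }
  got <- c(dim(x)[1], dim(x)[2], if (dim(x)[3] > 1) dim(x)[3] else dim(x)[4])
  if (!identical(as.integer(got), as.integer(input_dim))) {
    abort(sprintf("image dims %s do not match network input %s",
                  paste(got, collapse = "x"),
                  paste(input_dim, collapse = "x")))
  }
  x
}

encode_labels <- function(labels, classes) {
  y <- match(labels, classes)
  if (anyNA(y)) {
    abort(paste0("labels must be among: ", paste(classes, collapse = ", ")))
  }
  y
}

net_params <- function(net) {
  which(vapply(net$layers, function(l) !is.null(l$W), logical(1)))
}

#' Train a network with SGD and momentum
#'
#' Constant learning rate, momentum, L2 decay on convolutional weights,
#' softmax cross-entropy loss. Iterations per epoch default to
#' `floor(n_train / batch_size)`; a value configured in `cfg` wins, with a
#' warning when the two disagree. The trace records training-batch loss
#' and accuracy, plus validation loss and accuracy at every validation
#' checkpoint when a validation set is supplied.
#'
#' @param net A `conv_net` from [build_net()].
#' @param images List of `rgb_image`/`spectral_cube` objects.
#' @param labels Character vector of class labels, parallel to `images`.
#' @param cfg A [train_config()].
#' @param val_images,val_labels Optional validation set.
#' @return The trained `conv_net`, with a `trace` tibble attached
#'   (`iteration`, `epoch`, `train_loss`, `train_acc`, `val_loss`,
#'   `val_acc`).
#' @export
train_net <- function(net, images, labels, cfg = train_config(),
                      val_images = NULL, val_labels = NULL) {
  if (length(images) != length(labels)) {
    abort("images and labels must have equal length")
  }
  set.seed(cfg$seed)
  y <- encode_labels(labels, net$classes)
  xs <- lapply(images, as_input_tensor, input_dim = net$input_dim)
  n <- length(xs)
  derived <- iterations_per_epoch(n, cfg$batch_size)
  iters <- cfg$iterations %||% derived
  if (!is.null(cfg$iterations) && cfg$iterations != derived) {
    warn(sprintf(
      "configured %d iterations/epoch differs from derived %d; using %d",
      cfg$iterations, derived, cfg$iterations))
  }
  pidx <- net_params(net)
  vel <- lapply(net$layers[pidx], function(l) {
    list(W = l$W * 0, b = l$b * 0)
  })
  trace <- list()
  total_iter <- 0L
  for (ep in seq_len(cfg$epochs)) {
    order_ix <- sample.int(n)
    ptr <- 1L
    for (it in seq_len(iters)) {
      if (ptr + cfg$batch_size - 1L > n) {
        order_ix <- sample.int(n)
        ptr <- 1L
      }
      batch <- order_ix[ptr:(ptr + cfg$batch_size - 1L)]
      ptr <- ptr + cfg$batch_size
      gsum <- NULL
      loss <- 0
      correct <- 0L
      for (bi in batch) {
        fw <- net_forward(net, xs[[bi]], training = TRUE)
        sl <- softmax_loss(fw$scores, y[bi])
        loss <- loss + sl$loss
        if (which.max(fw$scores) == y[bi]) correct <- correct + 1L
        g <- net_backward(net, fw$caches, sl$dscores)
        if (is.null(gsum)) gsum <- g
        else for (li in pidx) {
          gsum[[li]]$W <- gsum[[li]]$W + g[[li]]$W
          gsum[[li]]$b <- gsum[[li]]$b + g[[li]]$b
        }
      }
      loss <- loss / cfg$batch_size
      if (!is.finite(loss)) {
        abort(sprintf("training loss diverged (non-finite) at iteration %d",
                      total_iter + 1L))
      }
      for (k in seq_along(pidx)) {
        li <- pidx[k]
        gW <- gsum[[li]]$W / cfg$batch_size
        gb <- gsum[[li]]$b / cfg$batch_size
        if (net$layers[[li]]$type == "conv") {
          gW <- gW + cfg$l2_decay * net$layers[[li]]$W
        }
        vel[[k]]$W <- cfg$momentum * vel[[k]]$W - cfg$learning_rate * gW
        vel[[k]]$b <- cfg$momentum * vel[[k]]$b - cfg$learning_rate * gb
        net$layers[[li]]$W <- net$layers[[li]]$W + vel[[k]]$W
        net$layers[[li]]$b <- net$layers[[li]]$b + vel[[k]]$b
      }
      total_iter <- total_iter + 1L
      if (total_iter %% cfg$validate_every == 0 && !is.null(val_images)) {
        vm <- score_set(net, val_images, val_labels)
        trace[[length(trace) + 1]] <- tibble(
          iteration = total_iter, epoch = ep, train_loss = loss,
          train_acc = correct / cfg$batch_size,
          val_loss = vm$loss, val_acc = vm$acc)
      } else if (total_iter %% cfg$validate_every == 0) {
        trace[[length(trace) + 1]] <- tibble(
          iteration = total_iter, epoch = ep, train_loss = loss,
          train_acc = correct / cfg$batch_size,
          val_loss = NA_real_, val_acc = NA_real_)
      }
    }
  }
  net$trace <- if (length(trace) > 0) dplyr::bind_rows(trace) else
    tibble(iteration = integer(), epoch = integer(),
           train_loss = numeric(), train_acc = numeric(),
           val_loss = numeric(), val_acc = numeric())
  net
}

score_set <- function(net, images, labels) {
  y <- encode_labels(labels, net$classes)
  loss <- 0
  correct <- 0L
  for (i in seq_along(images)) {
    x <- as_input_tensor(images[[i]], net$input_dim)
    sc <- net_forward(net, x, training = FALSE)$scores
    loss <- loss + softmax_loss(sc, y[i])$loss
    if (which.max(sc) == y[i]) correct <- correct + 1L
  }
  list(loss = loss / length(images), acc = correct / length(images))
}

#' Predict class labels for a set of images
#'
#' @param net A trained `conv_net`.
#' @param images List of images/cubes.
#' @return Character vector of predicted labels (argmax score).
#' @export
predict_classes <- function(net, images) {
  vapply(images, function(img) {
    x <- as_input_tensor(img, net$input_dim)
    net$classes[which.max(net_forward(net, x)$scores)]
  }, character(1))
}

#' Confusion counts on a test set
#'
#' Distress is the positive class: TP counts distress epochs identified as
#' distress, TN calm epochs identified as calm.
#'
#' @param net A trained `conv_net`.
#' @param images Non-empty list of test images.
#' @param labels True labels, parallel to `images`.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`.
#' @export
evaluate_net <- function(net, images, labels) {
  if (length(images) == 0) abort("test set is empty")
  pred <- predict_classes(net, images)
  confusion_counts(truth = labels, predicted = pred)
}

#' Tally confusion counts (distress positive)
#' @param truth,predicted Character vectors over calm/distress.
#' @return One-row tibble `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  tibble(tp = sum(truth == "distress" & predicted == "distress"),
         tn = sum(truth == "calm" & predicted == "calm"),
         fp = sum(truth == "calm" & predicted == "distress"),
         fn = sum(truth == "distress" & predicted == "calm"))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `Se = 100 TP / (TP + FN)`, `Sp = 100 TN / (TN + FP)`,
#' `Acc = 100 (TP + TN) / (TP + TN + FP + FN)`, in percent.
#'
#' @param counts A data frame with columns `tp`, `tn`, `fp`, `fn` (one or
#'   more rows).
#' @return A tibble with columns `se`, `sp`, `acc` (percent).
#' @export
confusion_metrics <- function(counts) {
  if (any(counts$tp + counts$fn == 0) || any(counts$tn + counts$fp == 0)) {
    abort("metrics undefined: one class is absent from the test set")
  }
  tibble(se = 100 * counts$tp / (counts$tp + counts$fn),
         sp = 100 * counts$tn / (counts$tn + counts$fp),
         acc = 100 * (counts$tp + counts$tn) /
           (counts$tp + counts$tn + counts$fp + counts$fn))
}

round_half_up <- function(x) floor(x + 0.5)

#' Iterations per epoch implied by the training-set size
#'
#' `floor(n_train / batch_size)`: 1244 training images at batches of 12
#' give 103 iterations per epoch.
#'
#' @param n_train Training-set size.
#' @param batch_size Mini-batch size.
#' @return Integer iteration count (at least 1).
#' @export
iterations_per_epoch <- function(n_train, batch_size) {
  max(1L, as.integer(n_train) %/% as.integer(batch_size))
}

#' Per-class 80/20 hold-out split
#'
#' Samples `round(fraction * class size)` items of each class (round half
#' up, without replacement) for training; the remainder tests. The
#' canonical split takes 658 of 822 calm and 586 of 732 distress epochs.
#'
#' @param manifest A data frame with a `class` column (one row per image).
#' @param train_fraction Training fraction per class.
#' @return A list with integer row indices `train` and `test`.
#' @export
holdout_split <- function(manifest, train_fraction = 0.8) {
  classes <- unique(manifest$class)
  if (any(table(manifest$class) == 0) || length(classes) < 1) {
    abort("manifest must contain at least one non-empty class")
  }
  train <- integer(0)
  for (cl in classes) {
    rows <- which(manifest$class == cl)
    if (length(rows) == 0) abort(paste0("empty class: ", cl))
    k <- round_half_up(train_fraction * length(rows))
    train <- c(train, sample(rows, min(k, length(rows))))
  }
  test <- setdiff(seq_len(nrow(manifest)), train)
  if (length(test) == 0) warn("empty test set (train_fraction = 1?)")
  list(train = sort(train), test = test)
}

#' Run the hold-out classification experiment
#'
#' Repeats `n_cycles` independent cycles: per-class 80/20 hold-out split,
#' network (re)initialization and training, evaluation on the held-out
#' images, and sensitivity/specificity/accuracy computation. Per-cycle
#' seeds derive deterministically from the master seed.
#'
#' @param images List of images/cubes.
#' @param manifest Data frame with a `class` column, parallel to `images`.
#' @param spec A [net_spec()].
#' @param cfg A [train_config()].
#' @param n_cycles Number of validation cycles.
#' @param seed Master seed.
#' @param train_fraction Per-class training fraction.
#' @return A `distress_experiment` object: per-cycle counts and metrics
#'   plus mean/std aggregates; see [tidy()] and [glance()] methods.
#' @export
run_experiment <- function(images, manifest, spec = net_spec("2D", 0.1),
                           cfg = train_config(epochs = 5),
                           n_cycles = 10, seed = 1L,
                           train_fraction = 0.8) {
  if (length(images) != nrow(manifest)) {
    abort("images and manifest must be parallel")
  }
  set.seed(seed)
  cycle_seeds <- sample.int(.Machine$integer.max - 1L, n_cycles)
  rows <- vector("list", n_cycles)
  for (cy in seq_len(n_cycles)) {
    res <- tryCatch({
      set.seed(cycle_seeds[cy])
      split <- holdout_split(manifest, train_fraction)
      cfg_cy <- cfg
      cfg_cy$seed <- cycle_seeds[cy]
      net <- build_net(spec)
      net <- train_net(net, images[split$train],
                       manifest$class[split$train], cfg_cy,
                       val_images = images[split$test],
                       val_labels = manifest$class[split$test])
      counts <- evaluate_net(net, images[split$test],
                             manifest$class[split$test])
      dplyr::bind_cols(tibble(cycle = cy, seed = cycle_seeds[cy]),
                       counts, confusion_metrics(counts))
    }, error = function(e) {
      abort(sprintf("cycle %d failed: %s", cy, conditionMessage(e)))
    })
    rows[[cy]] <- res
  }
  cycles <- dplyr::bind_rows(rows)
  if (n_cycles == 1) {
    warn("single cycle: standard deviations reported as 0")
  }
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  summary <- tibble(
    se_mean = mean(cycles$se), se_sd = sd0(cycles$se),
    sp_mean = mean(cycles$sp), sp_sd = sd0(cycles$sp),
    acc_mean = mean(cycles$acc), acc_sd = sd0(cycles$acc))
  structure(list(cycles = cycles, summary = summary, spec = spec,
                 cfg = cfg, seed = seed),
            class = "distress_experiment")
}

#' @export
print.distress_experiment <- function(x, ...) {
  cat(sprintf("<distress_experiment> %d cycles (%s, width %.2g)\n",
              nrow(x$cycles), x$spec$dimensionality, x$spec$width))
  cat(sprintf("  Se %.2f (sd %.2f) | Sp %.2f (sd %.2f) | Acc %.2f (sd %.2f)\n",
              x$summary$se_mean, x$summary$se_sd, x$summary$sp_mean,
              x$summary$sp_sd, x$summary$acc_mean, x$summary$acc_sd))
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `distress_experiment`.
#' @param ... Unused.
#' @export
tidy.distress_experiment <- function(x, ...) x$cycles

#' @rdname run_experiment
#' @export
glance.distress_experiment <- function(x, ...) x$summary

#' Save network weights to a checkpoint file
#'
#' JSON checkpoint embedding a fingerprint of the network specification;
#' [load_net()] refuses weights whose fingerprint disagrees with the
#' receiving network.
#'
#' @param net A `conv_net`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_net <- function(net, path) {
  fp <- spec_fingerprint(net$spec)
  weights <- lapply(net$layers, function(l) {
    if (is.null(l$W)) NULL else list(W = as.vector(l$W), dimW = dim(l$W),
                                     b = l$b)
  })
  jsonlite::write_json(list(fingerprint = fp, weights = weights), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load checkpoint weights into a network
#'
#' @param path Checkpoint written by [save_net()].
#' @param net A freshly built `conv_net` with a matching specification.
#' @return The network with loaded weights.
#' @export
load_net <- function(path, net) {
  ck <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(ck$fingerprint, spec_fingerprint(net$spec))) {
    abort("checkpoint fingerprint does not match the network spec")
  }
  if (length(ck$weights) != length(net$layers)) {
    abort("checkpoint layer count does not match the network")
  }
  for (i in seq_along(net$layers)) {
    w <- ck$weights[[i]]
    if (!is.null(net$layers[[i]]$W)) {
      if (is.null(w$W)) abort(sprintf("layer %d missing from checkpoint", i))
      dims <- unlist(w$dimW)
      net$layers[[i]]$W <- matrix(unlist(w$W), dims[1], dims[2])
      net$layers[[i]]$b <- unlist(w$b)
    }
  }
  net
}

spec_fingerprint <- function(spec) {
  paste(spec$dimensionality, format(spec$width), spec$n_classes,
        format(spec$dropout), sep = "|")
}
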