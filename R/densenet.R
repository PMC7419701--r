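# Densely connected 3D convolutional classifier: correlation volumes in,
# network-membership probabilities out. Within a dense block every layer
# receives the channel-concatenation of all preceding outputs; transitions
# compress channels with a 1-cubic convolution and average-pool; a global
# average pool feeds the K-way softmax head. All learnable layers (stem and
# block convolutions, transition convolutions, final fully connected layer)
# count toward `total_layers`:
#   total_layers = 1 (stem) + sum(layers per block)
#                + (n_dense_blocks - 1) (transition convs) + 1 (head).
# The reference configuration (3 blocks, 49 layers) therefore runs 15 layers
# per block; block layers alternate between the configured cubic kernel
# edges (3, 5, 3, 5, ...).

#' Classifier configuration
#'
#' @param n_dense_blocks Number of dense blocks (>= 1).
#' @param total_layers Total count of learnable layers (see the accounting
#'   rule in the package source header of this file / the manifest).
#' @param kernel_edges Odd cubic convolution edge lengths, cycled across the
#'   layers of each block.
#' @param growth_rate Channels added by each dense-block layer.
#' @param n_stem_channels Channels produced by the stem convolution.
#' @param use_batch_norm Apply batch normalization before each convolution?
#' @param pooling Pooling operator; only `"average"` is supported.
#' @param n_classes Number of networks K.
#' @param patience_validations Early stopping: training stops once validation
#'   accuracy has not improved for this many consecutive validations.
#' @param split_fractions Train/validation fractions used when an example set
#'   is built by the same configuration.
#' @param stem_pool Average-pool (stride 2) right after the stem convolution?
#' @param compression Channel compression factor of transitions.
#' @param lr,momentum SGD step size and momentum.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param validate_every Validate every this many epochs.
#' @param bn_eps,bn_momentum Batch-norm stabilizer and running-stat update.
#' @return Object of class `densenet3d_config`.
#' @export
densenet3d_config <- function(n_dense_blocks = 2, total_layers = 8,
                              kernel_edges = c(3, 5), growth_rate = 6,
                              n_stem_channels = 8, use_batch_norm = TRUE,
                              pooling = "average", n_classes = 6,
                              patience_validations = 3,
                              split_fractions = c(0.7, 0.3),
                              stem_pool = TRUE, compression = 0.5,
                              lr = 0.05, momentum = 0.9, batch_size = 32,
                              max_epochs = 30, validate_every = 1,
                              bn_eps = 1e-5, bn_momentum = 0.1) {
  if (n_dense_blocks < 1) stopf("need at least one dense block")
  if (any(kernel_edges %% 2 != 1))
    stopf("configuration error: kernel edges must be odd, got %s",
          paste(kernel_edges, collapse = ", "))
  if (!identical(pooling, "average"))
    stopf("configuration error: only average pooling is supported")
  inner <- total_layers - 2L - (n_dense_blocks - 1L)
  if (inner < n_dense_blocks)
    stopf(paste0("configuration error: total_layers = %d cannot be met: ",
                 "1 stem + %d transition conv(s) + 1 head leave %d block ",
                 "layers for %d blocks (need >= 1 per block)"),
          total_layers, n_dense_blocks - 1L, inner, n_dense_blocks)
  base <- inner %/% n_dense_blocks
  extra <- inner %% n_dense_blocks
  layers_per_block <- rep(base, n_dense_blocks) +
    c(rep(1L, extra), rep(0L, n_dense_blocks - extra))
  structure(list(n_dense_blocks = as.integer(n_dense_blocks),
                 total_layers = as.integer(total_layers),
                 layers_per_block = as.integer(layers_per_block),
                 kernel_edges = as.integer(kernel_edges),
                 growth_rate = as.integer(growth_rate),
                 n_stem_channels = as.integer(n_stem_channels),
                 use_batch_norm = isTRUE(use_batch_norm),
                 pooling = pooling,
                 n_classes = as.integer(n_classes),
                 patience_validations = as.integer(patience_validations),
                 split_fractions = split_fractions,
                 stem_pool = isTRUE(stem_pool),
                 compression = compression,
                 lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 validate_every = as.integer(validate_every),
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "densenet3d_config")
}

# architecture walk shared by builder, forward and backward
arch_plan <- function(cfg) {
  plan <- list()
  C <- cfg$n_stem_channels
  plan$stem <- list(k = cfg$kernel_edges[1], in_ch = 1L, out_ch = C)
  plan$blocks <- vector("list", cfg$n_dense_blocks)
  for (b in seq_len(cfg$n_dense_blocks)) {
    layers <- vector("list", cfg$layers_per_block[b])
    for (l in seq_along(layers)) {
      k <- cfg$kernel_edges[(l - 1L) %% length(cfg$kernel_edges) + 1L]
      layers[[l]] <- list(k = k, in_ch = C, out_ch = cfg$growth_rate)
      C <- C + cfg$growth_rate
    }
    plan$blocks[[b]] <- layers
    if (b < cfg$n_dense_blocks) {
      out <- max(1L, as.integer(floor(C * cfg$compression)))
      plan$transitions[[b]] <- list(k = 1L, in_ch = C, out_ch = out)
      C <- out
    }
  }
  plan$head <- list(in_ch = C, out_ch = cfg$n_classes)
  plan
}

#' Build an untrained classifier model
#'
#' Instantiates the parameter tensors (He-initialized convolutions, unit
#' batch-norm scales) and the layer manifest, whose number of learnable
#' layers equals `config$total_layers` by the accounting rule documented in
#' this module.
#'
#' @param config A [densenet3d_config()].
#' @param input_shape Edge lengths of the input correlation volume.
#' @param seed RNG seed for weight initialization.
#' @return Object of class `densenet3d` with fields `config`, `input_shape`,
#'   `manifest` (data frame of learnable layers), `params`.
#' @export
build_model <- function(config, input_shape, seed = 1) {
  stopifnot(inherits(config, "densenet3d_config"))
  input_shape <- as.integer(input_shape)
  if (min(input_shape) < max(config$kernel_edges))
    stopf("input edge %d is smaller than the largest kernel edge %d",
          min(input_shape), max(config$kernel_edges))
  plan <- arch_plan(config)
  params <- list()
  manifest <- list()
  add_conv <- function(name, spec, where) {
    fan_in <- spec$k^3 * spec$in_ch
    W <- array(rnorm(spec$k^3 * spec$in_ch * spec$out_ch,
                     sd = sqrt(2 / fan_in)),
               dim = c(spec$k, spec$k, spec$k, spec$in_ch, spec$out_ch))
    params[[paste0(name, ".conv")]] <<- list(type = "conv", k = spec$k,
                                             W = W, b = numeric(spec$out_ch))
    manifest[[length(manifest) + 1L]] <<-
      data.frame(layer = paste0(name, ".conv"), kind = "conv3d",
                 kernel = spec$k, in_ch = spec$in_ch, out_ch = spec$out_ch,
                 stage = where)
  }
  add_bn <- function(name, C) {
    if (!config$use_batch_norm) return(invisible())
    params[[paste0(name, ".bn")]] <<- list(type = "bn", gamma = rep(1, C),
                                           beta = numeric(C),
                                           mean = numeric(C), var = rep(1, C))
  }
  with_seed(seed, {
    add_conv("stem", plan$stem, "stem")
    for (b in seq_along(plan$blocks)) {
      for (l in seq_along(plan$blocks[[b]])) {
        nm <- sprintf("b%d.l%d", b, l)
        add_bn(nm, plan$blocks[[b]][[l]]$in_ch)
        add_conv(nm, plan$blocks[[b]][[l]], sprintf("dense block %d", b))
      }
      if (b < length(plan$blocks)) {
        nm <- sprintf("t%d", b)
        add_bn(nm, plan$transitions[[b]]$in_ch)
        add_conv(nm, plan$transitions[[b]], "transition")
      }
    }
    add_bn("head", plan$head$in_ch)
    W <- matrix(rnorm(plan$head$in_ch * config$n_classes,
                      sd = sqrt(2 / plan$head$in_ch)),
                plan$head$in_ch, config$n_classes)
    params[["head.fc"]] <- list(type = "fc", W = W,
                                b = numeric(config$n_classes))
    manifest[[length(manifest) + 1L]] <-
      data.frame(layer = "head.fc", kind = "dense", kernel = NA,
                 in_ch = plan$head$in_ch, out_ch = config$n_classes,
                 stage = "classifier head")
  })
  manifest <- do.call(rbind, manifest)
  if (nrow(manifest) != config$total_layers)
    stopf("internal accounting error: %d learnable layers != total_layers %d",
          nrow(manifest), config$total_layers)
  structure(list(config = config, input_shape = input_shape,
                 manifest = manifest, params = params,
                 plan = plan, trained = FALSE, history = NULL),
            class = "densenet3d")
}

# ----- elementary layer ops ------------------------------------------------

conv_apply <- function(p, x) {
  .conv3d_fwd_cpp(x, dim(x), as.numeric(p$W), p$k, p$b)
}

bn_apply <- function(p, x, eps, training) {
  d <- dim(x)
  .bn_fwd_cpp(x, prod(d[1:3]), d[4], d[5], p$gamma, p$beta,
              p$mean, p$var, eps, training)
}

relu_apply <- function(x) {
  y <- pmax(x, 0)
  dim(y) <- dim(x)
  y
}

concat_ch <- function(x, h) {
  d <- dim(x)
  dh <- dim(h)
  out <- array(0, dim = c(d[1:3], d[4] + dh[4], d[5]))
  out[, , , seq_len(d[4]), ] <- x
  out[, , , d[4] + seq_len(dh[4]), ] <- h
  out
}

gap_apply <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = prod(d[1:3]))
  t(matrix(colMeans(m), d[4], d[5]))          # N x C
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. When `training` is TRUE batch statistics are used for BN and
# a cache for backpropagation is kept.
net_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  p <- model$params
  cache <- if (training) list(inputs = list()) else NULL
  save <- function(key, val) if (training) cache$inputs[[key]] <<- val
  bnv <- list()

  bn_relu <- function(name, h) {
    key <- paste0(name, ".bn")
    if (cfg$use_batch_norm) {
      save(key, h)
      r <- bn_apply(p[[key]], h, cfg$bn_eps, training)
      if (training) bnv[[key]] <<- list(mean = r$mean, var = r$var)
      h <- r$y
    }
    save(paste0(name, ".relu"), h)
    relu_apply(h)
  }

  save("stem.conv", x)
  h <- conv_apply(p[["stem.conv"]], x)
  if (cfg$stem_pool) {
    save("stem.pool", dim(h))
    h <- .avgpool3d_fwd_cpp(h, dim(h), 2L)
  }
  for (b in seq_along(model$plan$blocks)) {
    for (l in seq_along(model$plan$blocks[[b]])) {
      nm <- sprintf("b%d.l%d", b, l)
      g <- bn_relu(nm, h)
      save(paste0(nm, ".conv"), g)
      out <- conv_apply(p[[paste0(nm, ".conv")]], g)
      h <- concat_ch(h, out)
    }
    if (b < length(model$plan$blocks)) {
      nm <- sprintf("t%d", b)
      g <- bn_relu(nm, h)
      save(paste0(nm, ".conv"), g)
      h <- conv_apply(p[[paste0(nm, ".conv")]], g)
      save(paste0(nm, ".pool"), dim(h))
      h <- .avgpool3d_fwd_cpp(h, dim(h), 2L)
    }
  }
  h <- bn_relu("head", h)
  save("head.gap", dim(h))
  feats <- gap_apply(h)
  save("head.fc", feats)
  logits <- feats %*% p[["head.fc"]]$W +
    matrix(p[["head.fc"]]$b, nrow(feats), ncol(p[["head.fc"]]$W), byrow = TRUE)
  if (training) cache$bn <- bnv
  list(logits = logits, cache = cache)
}

# Backward pass; returns gradients named like the parameters.
net_backward <- function(model, cache, glogits) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  ins <- cache$inputs

  bwd_bn_relu <- function(name, g) {
    x_pre_relu <- ins[[paste0(name, ".relu")]]
    g <- g * (x_pre_relu > 0)
    dim(g) <- dim(x_pre_relu)
    if (cfg$use_batch_norm) {
      key <- paste0(name, ".bn")
      xin <- ins[[key]]
      d <- dim(xin)
      r <- .bn_bwd_cpp(xin, g, prod(d[1:3]), d[4], d[5],
                       p[[key]]$gamma, cache$bn[[key]]$mean,
                       cache$bn[[key]]$var, cfg$bn_eps)
      grads[[key]] <<- list(gamma = r$ggamma, beta = r$gbeta)
      g <- r$gin
    }
    g
  }
  bwd_conv <- function(name, g) {
    key <- paste0(name, ".conv")
    xin <- ins[[key]]
    r <- .conv3d_bwd_cpp(xin, dim(xin), as.numeric(p[[key]]$W), p[[key]]$k,
                         length(p[[key]]$b), g)
    grads[[key]] <<- list(W = r$gw, b = r$gb)
    r$gin
  }

  feats <- ins[["head.fc"]]
  grads[["head.fc"]] <- list(W = crossprod(feats, glogits),
                             b = colSums(glogits))
  g <- glogits %*% t(p[["head.fc"]]$W)       # N x C
  dgap <- ins[["head.gap"]]
  S <- prod(dgap[1:3])
  g <- array(rep(t(g) / S, each = S), dim = dgap)
  g <- bwd_bn_relu("head", g)

  for (b in rev(seq_along(model$plan$blocks))) {
    if (b < length(model$plan$blocks)) {
      nm <- sprintf("t%d", b)
      g <- .avgpool3d_bwd_cpp(ins[[paste0(nm, ".pool")]], g, 2L)
      g <- bwd_conv(nm, g)
      g <- bwd_bn_relu(nm, g)
    }
    for (l in rev(seq_along(model$plan$blocks[[b]]))) {
      nm <- sprintf("b%d.l%d", b, l)
      spec <- model$plan$blocks[[b]][[l]]
      d <- dim(g)
      Cin <- spec$in_ch
      g_in <- g[, , , seq_len(Cin), , drop = FALSE]
      g_new <- g[, , , Cin + seq_len(spec$out_ch), , drop = FALSE]
      dim(g_new) <- c(d[1:3], spec$out_ch, d[5])
      gb <- bwd_conv(nm, g_new)
      gb <- bwd_bn_relu(nm, gb)
      dim(g_in) <- c(d[1:3], Cin, d[5])
      g <- g_in + gb
    }
  }
  if (cfg$stem_pool)
    g <- .avgpool3d_bwd_cpp(ins[["stem.pool"]], g, 2L)
  bwd_conv("stem", g)
  grads
}

# update BN running statistics from one training batch
update_running_stats <- function(params, bnstats, momentum) {
  for (key in names(bnstats)) {
    params[[key]]$mean <- (1 - momentum) * params[[key]]$mean +
      momentum * bnstats[[key]]$mean
    params[[key]]$var <- (1 - momentum) * params[[key]]$var +
      momentum * bnstats[[key]]$var
  }
  params
}

examples_as_input <- function(volumes, shape) {
  array(t(volumes), dim = c(shape, 1L, nrow(volumes)))
}

# batched evaluation: probability matrix (examples x classes)
net_predict_matrix <- function(model, volumes, batch = 256L) {
  n <- nrow(volumes)
  out <- matrix(0, n, model$config$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    x <- examples_as_input(volumes[i:j, , drop = FALSE], model$input_shape)
    out[i:j, ] <- softmax_rows(net_forward(model, x, training = FALSE)$logits)
    i <- j + 1L
  }
  out
}

# early-stop rule: stop after the first validation v such that the best
# accuracy so far occurred at or before v - patience
early_stop_index <- function(accuracies, patience) {
  best <- -Inf
  stall <- 0L
  for (v in seq_along(accuracies)) {
    if (accuracies[v] > best + 1e-12) {
      best <- accuracies[v]
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) return(v)
    }
  }
  NA_integer_
}

#' Train the classifier
#'
#' Minimizes cross-entropy on the training partition with minibatch SGD
#' (momentum), evaluating validation accuracy at fixed epoch intervals.
#' Training stops early once validation accuracy has not improved for
#' `patience_validations` consecutive validations; the parameters of the best
#' validation are restored.
#'
#' @param model An untrained [build_model()] object.
#' @param examples An `example_set` with both partitions.
#' @param seed RNG seed (batch shuffling).
#' @return The trained model, with a `history` data frame (one row per
#'   validation: epoch, accuracy, loss) and `stop_reason`
#'   (`"early-stop"` or `"max-epochs"`).
#' @export
train_classifier <- function(model, examples, seed = 1) {
  stopifnot(inherits(model, "densenet3d"), inherits(examples, "example_set"))
  cfg <- model$config
  tr <- which(examples$partition == "train")
  va <- which(examples$partition == "validation")
  if (!length(tr) || !length(va))
    stopf("example set must contain both train and validation partitions")
  if (length(unique(examples$labels[tr])) < 2)
    stopf("label degeneracy: training partition holds a single class")
  if (max(examples$labels) > cfg$n_classes)
    stopf("labels exceed the configured %d classes", cfg$n_classes)
  if (!identical(as.integer(examples$input_shape), model$input_shape))
    stopf("example input shape does not match the model input shape")

  vel <- lapply(model$params, function(p) {
    if (p$type == "conv" || p$type == "fc")
      list(W = p$W * 0, b = p$b * 0)
    else list(gamma = p$gamma * 0, beta = p$beta * 0)
  })
  history <- NULL
  best <- list(acc = -Inf, params = model$params)
  stall <- 0L
  stop_reason <- "max-epochs"

  with_seed(seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample(tr)
      i <- 1L
      while (i <= length(idx)) {
        j <- min(i + cfg$batch_size - 1L, length(idx))
        bi <- idx[i:j]
        x <- examples_as_input(examples$volumes[bi, , drop = FALSE],
                               model$input_shape)
        y <- examples$labels[bi]
        fw <- net_forward(model, x, training = TRUE)
        pr <- softmax_rows(fw$logits)
        g <- pr
        g[cbind(seq_along(y), y)] <- g[cbind(seq_along(y), y)] - 1
        g <- g / length(y)
        grads <- net_backward(model, fw$cache, g)
        for (key in names(grads)) {
          for (fld in names(grads[[key]])) {
            vel[[key]][[fld]] <- cfg$momentum * vel[[key]][[fld]] -
              cfg$lr * as.numeric(grads[[key]][[fld]])
            model$params[[key]][[fld]] <-
              model$params[[key]][[fld]] + vel[[key]][[fld]]
          }
        }
        model$params <- update_running_stats(model$params, fw$cache$bn,
                                             cfg$bn_momentum)
        i <- j + 1L
      }
      if (epoch %% cfg$validate_every == 0L) {
        pr <- net_predict_matrix(model, examples$volumes[va, , drop = FALSE])
        acc <- mean(max.col(pr, ties.method = "first") == examples$labels[va])
        vloss <- -mean(log(pmax(pr[cbind(seq_along(va), examples$labels[va])],
                                1e-12)))
        history <- rbind(history,
                         data.frame(validation = nrow(history) %||% 0 + 1,
                                    epoch = epoch, accuracy = acc,
                                    loss = vloss))
        if (acc > best$acc + 1e-12) {
          best <- list(acc = acc, params = model$params)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= cfg$patience_validations) {
            stop_reason <- "early-stop"
            break
          }
        }
      }
    }
  })
  model$params <- best$params
  model$trained <- TRUE
  model$history <- list(table = history, stop_reason = stop_reason,
                        best_accuracy = best$acc)
  model
}

#' Fit the resting-state network classifier
#'
#' The one-call fitting interface: builds the dense 3D convolutional model
#' for the example set's input shape and trains it. Methods exist for
#' `print`, `summary`, `coef`, `plot` and `predict`.
#'
#' @param examples An `example_set` from [build_training_examples()].
#' @param config A [densenet3d_config()]; `n_classes` is taken from the
#'   example set when missing.
#' @param seed RNG seed covering initialization and batch order.
#' @return Object of class `rsn_densenet` (also `densenet3d`).
#' @examples
#' \donttest{
#' atlas <- make_phantom_atlas(c(16, 16, 16), 3, 2, seed = 1)
#' # see the package vignette for a full phantom workflow
#' }
#' @export
rsn_densenet <- function(examples, config = NULL, seed = 1) {
  config <- config %||% densenet3d_config(n_classes = examples$n_classes)
  model <- build_model(config, examples$input_shape, seed = seed)
  model <- train_classifier(model, examples, seed = seed + 1L)
  class(model) <- c("rsn_densenet", class(model))
  model
}

#' @export
print.densenet3d <- function(x, ...) {
  cat(sprintf("Dense 3D CNN: %d learnable layers, %d dense blocks, kernels {%s}, %d classes%s\n",
              nrow(x$manifest), x$config$n_dense_blocks,
              paste(x$config$kernel_edges, collapse = ","),
              x$config$n_classes,
              if (x$trained) " (trained)" else " (untrained)"))
  if (x$trained)
    cat(sprintf("  best validation accuracy %.3f after %d validations (%s)\n",
                x$history$best_accuracy, nrow(x$history$table),
                x$history$stop_reason))
  invisible(x)
}

#' @export
summary.rsn_densenet <- function(object, ...) {
  print(object)
  cat("\nLayer manifest:\n")
  print(object$manifest, row.names = FALSE)
  invisible(object$manifest)
}

#' @export
coef.rsn_densenet <- function(object, ...) object$params

#' @export
plot.rsn_densenet <- function(x, ...) {
  h <- x$history$table
  if (is.null(h)) stopf("model has no training history")
  graphics::plot(h$epoch, h$accuracy, type = "b", xlab = "epoch",
                 ylab = "validation accuracy", ylim = c(0, 1), ...)
  invisible(h)
}

#' @export
predict.rsn_densenet <- function(object, newdata, ...) {
  if (inherits(newdata, "example_set"))
    return(net_predict_matrix(object, newdata$volumes))
  if (is.function(newdata))
    return(predict_volume(object, newdata, ...))
  if (is.matrix(newdata))
    return(net_predict_matrix(object, newdata))
  stopf("newdata must be an example_set, an inference stream, or a matrix")
}

#' Per-voxel network probability volume
#'
#' Runs the classifier over a per-voxel inference stream (from
#' [build_inference_examples()]) and assembles the softmax probabilities
#' into a 4D volume. Degenerate (zero-variance) seed voxels receive uniform
#' probabilities 1/K and are counted in `n_flagged`.
#'
#' @param model A trained classifier.
#' @param stream Inference stream covering the mask.
#' @param mask Logical brain/evaluation mask the stream was built over.
#' @return Object of class `probability_volume`: `probs` (x,y,z,class; zero
#'   outside the mask), `class_names`, `mask`, `n_flagged`, `frames_used`.
#' @export
predict_volume <- function(model, stream, mask) {
  stopifnot(inherits(model, "densenet3d"))
  if (!model$trained) stopf("model is not trained")
  if (!identical(as.integer(attr(stream, "input_shape")), model$input_shape))
    stopf("stream input shape does not match the model")
  if (attr(stream, "n_voxels") != sum(mask))
    stopf("coverage error: stream has %d voxels but the mask has %d",
          attr(stream, "n_voxels"), sum(mask))
  K <- model$config$n_classes
  grid <- dim(mask)
  probs <- array(0, dim = c(grid, K))
  vs <- prod(grid)
  n_flagged <- 0L
  repeat {
    chunk <- stream()
    if (is.null(chunk)) break
    pr <- net_predict_matrix(model, chunk$z)
    if (any(chunk$degenerate)) {
      pr[chunk$degenerate, ] <- 1 / K
      n_flagged <- n_flagged + sum(chunk$degenerate)
    }
    for (c in seq_len(K))
      probs[chunk$voxels + (c - 1) * vs] <- pr[, c]
  }
  structure(list(probs = probs,
                 class_names = paste0("network", seq_len(K)),
                 mask = mask, n_flagged = n_flagged,
                 frames_used = attr(stream, "frames_used")),
            class = "probability_volume")
}

#' Smooth a probability volume
#'
#' Two-stage spatial regularization of classifier output. Stage 1 (mode
#' filter): the winner-take-all label volume is mode-filtered within a
#' stride-1 cubic window (ties break toward the lowest class index) and each
#' voxel's probability vector is replaced by the mean over neighborhood
#' voxels sharing the modal label. Stage 2 (box filter): a separable
#' length-`box_length` moving average per class, renormalized per voxel.
#' Both stages preserve the mask and the per-voxel probability sum.
#'
#' @param prob A `probability_volume`.
#' @param mode_window Cubic mode-filter window (odd; 0 disables stage 1).
#' @param box_length Box-filter length (odd; 0 disables stage 2).
#' @return The smoothed `probability_volume`.
#' @export
smooth_probability <- function(prob, mode_window = 3, box_length = 3) {
  stopifnot(inherits(prob, "probability_volume"))
  if (mode_window > 0 && mode_window %% 2 != 1)
    stopf("mode_window must be odd")
  if (box_length > 0 && box_length %% 2 != 1)
    stopf("box_length must be odd")
  grid <- dim(prob$mask)
  K <- dim(prob$probs)[4]
  vs <- prod(grid)
  p <- prob$probs
  if (mode_window > 0) {
    labels <- winner_labels(p, prob$mask)
    r <- .mode_filter_cpp(as.numeric(p), labels, as.vector(prob$mask),
                          as.integer(grid), K, as.integer(mode_window))
    p <- array(r$probs, dim = dim(prob$probs))
  }
  if (box_length > 0) {
    k <- rep(1 / box_length, box_length)
    p <- array(.sepconv3d_cpp(as.numeric(p), grid[1], grid[2], grid[3], K,
                              list(k, k, k)),
               dim = dim(prob$probs))
    m <- as.vector(prob$mask)
    flat <- matrix(p, vs, K)
    flat[!m, ] <- 0
    s <- rowSums(flat)
    flat[m, ] <- flat[m, ] / s[m]
    p <- array(flat, dim = dim(prob$probs))
  }
  prob$probs <- p
  prob
}

# winner-take-all labels (1..K inside mask, 0 outside)
winner_labels <- function(probs, mask) {
  grid <- dim(mask)
  K <- dim(probs)[4]
  flat <- matrix(probs, prod(grid), K)
  lab <- max.col(flat, ties.method = "first")
  lab[!as.vector(mask)] <- 0L
  array(as.integer(lab), dim = grid)
}

#' @export
print.probability_volume <- function(x, ...) {
  cat(sprintf("Probability volume: %s grid, %d classes, %d mask voxels (%d degenerate)\n",
              paste(dim(x$mask), collapse = "x"), dim(x$probs)[4],
              sum(x$mask), x$n_flagged))
  invisible(x)
}
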