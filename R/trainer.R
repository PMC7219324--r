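#' Training configuration
#'
#' The published optimization recipe: SGD with momentum 0.9, weight decay
#' 1e-4, batch size 8, dropout 0.5 on the concatenated pooled feature, base
#' learning rate 0.0125 decayed by a half-period cosine schedule over all
#' iterations, with a linear warm-up (default spanning the first 34 epochs'
#' worth of iterations, starting at 0.1 x base).
#'
#' @param base_lr Base learning rate (eta).
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay coefficient.
#' @param dropout Dropout rate before the classifier.
#' @param warmup_epochs Epochs' worth of iterations used for linear warm-up.
#' @param warmup_start_factor Warm-up starting learning rate as a fraction of
#'   `base_lr`.
#' @param window_len Temporal window length sampled per clip.
#' @param train_scale Shorter-side scaling applied before the random crop.
#' @param crop_size Random crop side length.
#' @param slow_stride,fast_stride Pathway temporal strides.
#' @param seed RNG seed controlling init, data order, windows and crops.
#' @return A list of class `train_config`.
#' @export
train_config <- function(base_lr = 0.0125, epochs = 300L, batch_size = 8L,
                         momentum = 0.9, weight_decay = 1e-4, dropout = 0.5,
                         warmup_epochs = 34L, warmup_start_factor = 0.1,
                         window_len = 64L, train_scale = 240L,
                         crop_size = 224L, slow_stride = 8L, fast_stride = 2L,
                         seed = 1L) {
  stopifnot(base_lr > 0, batch_size >= 1L, epochs >= 1L)
  structure(list(base_lr = base_lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, dropout = dropout,
                 warmup_epochs = warmup_epochs,
                 warmup_start_factor = warmup_start_factor,
                 window_len = as.integer(window_len),
                 train_scale = as.integer(train_scale),
                 crop_size = as.integer(crop_size),
                 slow_stride = as.integer(slow_stride),
                 fast_stride = as.integer(fast_stride),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' He-style Gaussian weight initialization
#'
#' Every convolution and classifier weight is drawn from a zero-mean
#' Gaussian with variance `2 / n_l`, where `n_l` is the layer's fan-in
#' (receptive-field volume times input channels), so each layer's response
#' variance is preserved. All biases and normalization shifts start at zero;
#' normalization scales at one. Deterministic given `seed`.
#'
#' @param net A [build_network()] result.
#' @param seed Integer seed.
#' @return The initialized network.
#' @export
init_weights <- function(net, seed = 1L) {
  stopifnot(inherits(net, "pmb_network"))
  with_seed(seed, {
    for (nm in names(net$fan_in)) {
      sd <- sqrt(2 / net$fan_in[[nm]])
      p <- net$params[[nm]]
      v <- rnorm(length(p), sd = sd)
      dim(v) <- dim_or_len(p)
      net$params[[nm]] <- v
    }
  })
  net
}

#' Learning rate at a given iteration
#'
#' Half-period cosine schedule `eta * 0.5 * (cos(pi * n / n_max) + 1)` for
#' `n >= warmup_iters`, preceded by a linear ramp from
#' `warmup_start_factor * eta` to the cosine value at `warmup_iters`
#' (continuous at the join).
#'
#' @param n Iteration index (0-based), `0 <= n <= n_max`. Vectorized.
#' @param n_max Maximum training iterations.
#' @param base_lr Base learning rate eta.
#' @param warmup_iters Warm-up length in iterations.
#' @param warmup_start_factor Ramp start as a fraction of `base_lr`.
#' @return Learning rate(s).
#' @export
lr_at <- function(n, n_max, base_lr = 0.0125, warmup_iters = 0L,
                  warmup_start_factor = 0.1) {
  if (any(n < 0 | n > n_max)) stop("iteration out of [0, n_max]")
  cosine <- base_lr * 0.5 * (cos(pi * n / n_max) + 1)
  if (warmup_iters <= 0) return(cosine)
  target <- base_lr * 0.5 * (cos(pi * warmup_iters / n_max) + 1)
  start <- warmup_start_factor * base_lr
  ramp <- start + (target - start) * n / warmup_iters
  ifelse(n < warmup_iters, ramp, cosine)
}

# One SGD step with momentum and L2 weight decay; state holds velocities.
sgd_step <- function(net, grads, state, lr, momentum, weight_decay) {
  for (nm in names(net$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0 && nm %in% names(net$fan_in))
      g <- g + weight_decay * net$params[[nm]]
    v <- state[[nm]]
    v <- if (is.null(v)) g else momentum * v + g
    state[[nm]] <- v
    net$params[[nm]] <- net$params[[nm]] - lr * v
  }
  list(net = net, state = state)
}

# Assemble one training batch from in-memory clips: random window, shorter-
# side scaling, one shared random crop per clip, standardized tensors.
make_train_batch <- function(clips, cfg) {
  xs_list <- vector("list", length(clips))
  xf_list <- vector("list", length(clips))
  for (i in seq_along(clips)) {
    clip <- clips[[i]]
    w <- sample_window(n_frames(clip), "random", window_len = cfg$window_len)
    pp <- pathway_subsample(w, cfg$slow_stride, cfg$fast_stride)
    fast_frames <- clip$frames[, , , pp$fast + 1L, drop = FALSE]
    fast_frames <- scale_shorter_side(fast_frames, cfg$train_scale)
    fast_frames <- train_crop(fast_frames, cfg$crop_size)
    sub <- seq(1L, length(pp$fast), by = cfg$slow_stride %/% cfg$fast_stride)
    slow_frames <- fast_frames[, , , sub, drop = FALSE]
    xs_list[[i]] <- frames_to_tensor(slow_frames)
    xf_list[[i]] <- frames_to_tensor(fast_frames)
  }
  list(xs = stack_batch(xs_list), xf = stack_batch(xf_list))
}

# Cheap per-epoch validation: center window, center crop, single view.
validate_top1 <- function(net, clips, labels, cfg) {
  vocab <- behavior_classes()
  correct <- 0L
  for (i in seq_along(clips)) {
    clip <- clips[[i]]
    w <- sample_window(n_frames(clip), "center", window_len = cfg$window_len)
    pp <- pathway_subsample(w, cfg$slow_stride, cfg$fast_stride)
    fast_frames <- clip$frames[, , , pp$fast + 1L, drop = FALSE]
    fast_frames <- scale_shorter_side(fast_frames, cfg$train_scale)
    d <- dim(fast_frames)
    off <- c((d[1] - cfg$crop_size) %/% 2L, (d[2] - cfg$crop_size) %/% 2L)
    fast_frames <- fast_frames[off[1] + seq_len(cfg$crop_size),
                               off[2] + seq_len(cfg$crop_size), , ,
                               drop = FALSE]
    sub <- seq(1L, length(pp$fast), by = cfg$slow_stride %/% cfg$fast_stride)
    slow_frames <- fast_frames[, , , sub, drop = FALSE]
    logits <- predict_logits(net, stack_batch(list(frames_to_tensor(slow_frames))),
                             stack_batch(list(frames_to_tensor(fast_frames))))
    if (vocab[which.max(logits[, 1])] == labels[i]) correct <- correct + 1L
  }
  correct / length(clips)
}

#' Train a network with the published SGD recipe
#'
#' Minimizes cross-entropy over softmax outputs with per-iteration learning
#' rates from [lr_at()] (iteration = mini-batch step; `n_max` = steps/epoch
#' times epochs). Batch-normalization statistics are computed per batch.
#' The best-validation parameter set is checkpointed and restored at the
#' end. Fully reproducible given `cfg$seed` (initialization, shuffling,
#' window and crop draws, dropout).
#'
#' @param net A built (not necessarily initialized) `pmb_network`.
#' @param train_data,val_data Datasets: either `synthetic_dataset` objects or
#'   lists with `clips` (list of [frame_sequence()]) and `labels`.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `net` (best-validation weights) and `history`
#'   (data.frame: epoch, loss, val_top1, lr).
#' @export
train <- function(net, train_data, val_data, cfg = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(net, "pmb_network"))
  vocab <- behavior_classes()
  labels_tr <- match(train_data$labels, vocab)
  if (anyNA(labels_tr)) stop("training labels outside the class vocabulary")
  missing_cls <- setdiff(vocab, unique(train_data$labels))
  if (length(missing_cls))
    warning("training manifest has empty classes: ",
            paste(missing_cls, collapse = ", "))

  net <- init_weights(net, cfg$seed)
  set.seed(cfg$seed + 1L)

  n_tr <- length(train_data$clips)
  steps_per_epoch <- max(1L, n_tr %/% cfg$batch_size)
  n_max <- steps_per_epoch * cfg$epochs
  warmup_iters <- round(cfg$warmup_epochs * steps_per_epoch)

  state <- list()
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_top1 = numeric(0), lr = numeric(0))
  best <- list(val = -Inf, params = NULL, buffers = NULL)
  it <- 0L
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n_tr)
    ep_loss <- 0
    for (s in seq_len(steps_per_epoch)) {
      take <- perm[((s - 1L) * cfg$batch_size + 1L):min(s * cfg$batch_size, n_tr)]
      batch <- make_train_batch(train_data$clips[take], cfg)
      fw <- net_forward(net, batch$xs, batch$xf, training = TRUE,
                        dropout = cfg$dropout)
      net <- apply_bn_updates(net, fw$bn_updates)
      ce <- softmax_ce(fw$logits, labels_tr[take])
      if (!is.finite(ce$loss))
        stop(sprintf("non-finite loss at epoch %d step %d (lr=%.5g)",
                     ep, s, lr_at(it, n_max, cfg$base_lr, warmup_iters,
                                  cfg$warmup_start_factor)))
      grads <- net_backward(net, fw$cache, ce$dlogits)
      lr <- lr_at(it, n_max, cfg$base_lr, warmup_iters,
                  cfg$warmup_start_factor)
      upd <- sgd_step(net, grads, state, lr, cfg$momentum, cfg$weight_decay)
      net <- upd$net; state <- upd$state
      ep_loss <- ep_loss + ce$loss
      it <- it + 1L
    }
    val_top1 <- validate_top1(net, val_data$clips, val_data$labels, cfg)
    lr_ep <- lr_at(it - 1L, n_max, cfg$base_lr, warmup_iters,
                   cfg$warmup_start_factor)
    history <- rbind(history, data.frame(epoch = ep,
                                         loss = ep_loss / steps_per_epoch,
                                         val_top1 = val_top1, lr = lr_ep))
    if (val_top1 >= best$val) {
      best <- list(val = val_top1, params = net$params, buffers = net$buffers)
    }
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val_top1 %.3f  lr %.5f",
                      ep, ep_loss / steps_per_epoch, val_top1, lr_ep))
  }
  if (!is.null(best$params)) {
    net$params <- best$params
    net$buffers <- best$buffers
  }
  list(net = net, history = history)
}

#' Save / load a self-describing checkpoint
#'
#' Stores weights, buffers and the architecture spec so the network can be
#' rebuilt without external context.
#'
#' @param net A `pmb_network`.
#' @param path File path.
#' @return `load_checkpoint` returns the reconstructed `pmb_network`.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(spec = net$spec, params = net$params, buffers = net$buffers),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  net <- build_network(structure(x$spec, class = "pmb_arch_spec"))
  net$params <- x$params
  net$buffers <- x$buffers
  net
}
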