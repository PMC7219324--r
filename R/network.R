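#' Instantiate a PMB-SCN network from an architecture spec
#'
#' Allocates all trainable parameters (convolution weights, normalization
#' scale/shift, classifier weight and bias) and normalization running-stat
#' buffers. Convolution weights are allocated at zero; call [init_weights()]
#' for the He-style Gaussian initialization used for training.
#'
#' Residual blocks are post-activation two-layer basic blocks
#' (conv-norm-relu, conv-norm, identity or 1x1x1 projection shortcut, relu
#' after the sum). Spatial downsampling (stride 1x2x2) sits on the first
#' convolution of the first block of res3--res5; no stage downsamples time.
#'
#' @param spec A [make_arch_spec()] result.
#' @return An object of class `pmb_network` with fields `spec`, `params`,
#'   `buffers` and `fan_in`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "pmb_arch_spec"))
  shapes <- param_shapes(spec)
  params <- list()
  buffers <- list()
  fan_in <- numeric(0)
  for (nm in names(shapes)) {
    d <- shapes[[nm]]
    if (grepl("\\.bn\\.gamma$", nm)) {
      params[[nm]] <- rep(1, d)
      base <- sub("\\.gamma$", "", nm)
      buffers[[paste0(base, ".rm")]] <- rep(0, d)
      buffers[[paste0(base, ".rv")]] <- rep(1, d)
    } else if (grepl("\\.bn\\.beta$", nm) || nm == "fc.b") {
      params[[nm]] <- rep(0, d)
    } else if (nm == "fc.w") {
      params[[nm]] <- matrix(0, d[1], d[2])
      fan_in[nm] <- d[2]
    } else {
      params[[nm]] <- array(0, d)
      fan_in[nm] <- prod(d[-1])
    }
  }
  structure(list(spec = spec, params = params, buffers = buffers,
                 fan_in = fan_in),
            class = "pmb_network")
}

#' @export
print.pmb_network <- function(x, ...) {
  cat("<pmb_network>", x$spec$variant, "-", x$spec$fusion, "fusion,",
      format(count_parameters(x), big.mark = ","), "trainable parameters\n")
  invisible(x)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[-1] == db[-1]))
  y <- array(0, c(da[1] + db[1], da[-1]))
  y[seq_len(da[1]), , , , ] <- a
  y[da[1] + seq_len(db[1]), , , , ] <- b
  y
}

split_channels <- function(dy, c1) {
  list(a = dy[seq_len(c1), , , , , drop = FALSE],
       b = dy[-seq_len(c1), , , , , drop = FALSE])
}

# conv -> bn (-> relu) with caches; bn buffer updates are written into `bup`.
cbr_fw <- function(net, bup, name, x, stride, training, relu = TRUE, pad = NULL) {
  P <- net$params; B <- net$buffers
  w <- P[[paste0(name, ".w")]]
  if (is.null(pad)) pad <- same_pad(dim(w)[3:5])
  cv <- conv3d_fw(x, w, stride, pad)
  bn <- bn_fw(cv$y, P[[paste0(name, ".bn.gamma")]], P[[paste0(name, ".bn.beta")]],
              B[[paste0(name, ".bn.rm")]], B[[paste0(name, ".bn.rv")]], training)
  if (training) {
    bup[[paste0(name, ".bn.rm")]] <- bn$rmean
    bup[[paste0(name, ".bn.rv")]] <- bn$rvar
  }
  if (relu) {
    rl <- relu_fw(bn$y)
    list(y = rl$y, cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache))
  } else {
    list(y = bn$y, cache = list(conv = cv$cache, bn = bn$cache, relu = NULL))
  }
}

cbr_bw <- function(net, grads, name, dy, cache, need_dx = TRUE) {
  if (!is.null(cache$relu)) dy <- relu_bw(dy, cache$relu)
  gb <- bn_bw(dy, cache$bn)
  grads[[paste0(name, ".bn.gamma")]] <- gb$dgamma
  grads[[paste0(name, ".bn.beta")]] <- gb$dbeta
  gc_ <- conv3d_bw(gb$dx, cache$conv, need_dx)
  grads[[paste0(name, ".w")]] <- gc_$dw
  gc_$dx
}

block_fw <- function(net, bup, name, x, stride1, training) {
  has_down <- !is.null(net$params[[paste0(name, ".down.w")]])
  h1 <- cbr_fw(net, bup, paste0(name, ".conv1"), x, stride1, training, relu = TRUE)
  h2 <- cbr_fw(net, bup, paste0(name, ".conv2"), h1$y, c(1L, 1L, 1L), training,
               relu = FALSE)
  if (has_down) {
    sc <- cbr_fw(net, bup, paste0(name, ".down"), x, stride1, training, relu = FALSE)
    s <- h2$y + sc$y
    sc_cache <- sc$cache
  } else {
    s <- h2$y + x
    sc_cache <- NULL
  }
  rl <- relu_fw(s)
  list(y = rl$y, cache = list(c1 = h1$cache, c2 = h2$cache, down = sc_cache,
                              relu_out = rl$cache, has_down = has_down))
}

block_bw <- function(net, grads, name, dy, cache) {
  ds <- relu_bw(dy, cache$relu_out)
  dh1 <- cbr_bw(net, grads, paste0(name, ".conv2"), ds, cache$c2)
  dx_main <- cbr_bw(net, grads, paste0(name, ".conv1"), dh1, cache$c1)
  if (cache$has_down) {
    dx_sc <- cbr_bw(net, grads, paste0(name, ".down"), ds, cache$down)
    dx_main + dx_sc
  } else {
    dx_main + ds
  }
}

stage_fw <- function(net, bup, pathway, st, x, training) {
  caches <- vector("list", st$n_blocks)
  for (b in seq_len(st$n_blocks)) {
    stride1 <- if (b == 1L) c(1L, st$spatial_stride, st$spatial_stride) else c(1L, 1L, 1L)
    r <- block_fw(net, bup, paste0(pathway, ".", st$name, ".b", b), x, stride1, training)
    x <- r$y
    caches[[b]] <- r$cache
  }
  list(y = x, cache = caches)
}

stage_bw <- function(net, grads, pathway, st, dy, caches) {
  for (b in rev(seq_len(st$n_blocks))) {
    dy <- block_bw(net, grads, paste0(pathway, ".", st$name, ".b", b), dy, caches[[b]])
  }
  dy
}

# Full forward pass. xs: (3, slow_len, H, W, N); xf: (3, fast_len, H, W, N).
# Returns logits (n_classes x N) and, when keep_cache, everything needed for
# the backward pass. Buffer updates (training mode) are in $bn_updates.
net_forward <- function(net, xs, xf, training = FALSE, dropout = 0,
                        keep_cache = training) {
  spec <- net$spec
  bup <- new.env(parent = emptyenv())
  K <- list()

  sc1 <- cbr_fw(net, bup, "slow.conv1", xs, spec$slow$conv1_stride, training)
  sp <- maxpool3d_fw(sc1$y, spec$pool1$kernel, spec$pool1$stride, spec$pool1$pad)
  fc1 <- cbr_fw(net, bup, "fast.conv1", xf, spec$fast$conv1_stride, training)
  fp <- maxpool3d_fw(fc1$y, spec$pool1$kernel, spec$pool1$stride, spec$pool1$pad)
  K$slow_conv1 <- sc1$cache; K$slow_pool <- sp$cache
  K$fast_conv1 <- fc1$cache; K$fast_pool <- fp$cache

  xs_cur <- sp$y; xf_cur <- fp$y
  K$stages <- list()
  for (i in seq_len(4L)) {
    st_s <- spec$slow$stages[[i]]; st_f <- spec$fast$stages[[i]]
    sk <- list(name = st_s$name)
    f <- stage_fw(net, bup, "fast", st_f, xf_cur, training)
    s <- stage_fw(net, bup, "slow", st_s, xs_cur, training)
    sk$fast <- f$cache; sk$slow <- s$cache
    xf_cur <- f$y
    if (st_s$name %in% spec$lateral$stages) {
      lname <- paste0("lat.", st_s$name)
      lat <- cbr_fw(net, bup, lname, xf_cur, spec$lateral$stride, training,
                    relu = TRUE, pad = c(same_pad(spec$lateral$kernel[1]), 0L, 0L))
      sk$lat <- lat$cache
      if (spec$fusion == "concat") {
        sk$slow_ch <- dim(s$y)[1]
        xs_cur <- concat_channels(s$y, lat$y)
      } else {
        proj <- cbr_fw(net, bup, paste0(lname, ".proj"), lat$y, c(1L, 1L, 1L),
                       training, relu = FALSE)
        sk$proj <- proj$cache
        xs_cur <- s$y + proj$y
      }
    } else {
      xs_cur <- s$y
    }
    K$stages[[i]] <- sk
  }

  gs <- gap_fw(xs_cur); gf <- gap_fw(xf_cur)
  feat <- rbind(gs$y, gf$y)
  dp <- dropout_fw(feat, dropout, training)
  fc <- linear_fw(dp$y, net$params$fc.w, net$params$fc.b)
  K$gap_slow <- gs$cache; K$gap_fast <- gf$cache
  K$dropout <- dp$cache; K$fc <- fc$cache
  K$n_slow_feat <- nrow(gs$y)

  list(logits = fc$y,
       cache = if (keep_cache) K else NULL,
       bn_updates = as.list(bup))
}

# Backward pass mirroring net_forward; returns named list of gradients.
net_backward <- function(net, cache, dlogits) {
  spec <- net$spec
  grads <- new.env(parent = emptyenv())

  gl <- linear_bw(dlogits, cache$fc)
  grads$fc.w <- gl$dw; grads$fc.b <- gl$db
  dfeat <- dropout_bw(gl$dx, cache$dropout)
  ns <- cache$n_slow_feat
  d_slow <- gap_bw(dfeat[seq_len(ns), , drop = FALSE], cache$gap_slow)
  d_fast <- gap_bw(dfeat[-seq_len(ns), , drop = FALSE], cache$gap_fast)

  dxs <- d_slow  # grad w.r.t. slow tensor flowing out of stage i
  dxf <- d_fast
  for (i in rev(seq_len(4L))) {
    st_s <- spec$slow$stages[[i]]; st_f <- spec$fast$stages[[i]]
    sk <- cache$stages[[i]]
    lname <- paste0("lat.", st_s$name)
    if (st_s$name %in% spec$lateral$stages) {
      if (spec$fusion == "concat") {
        parts <- split_channels(dxs, sk$slow_ch)
        d_slow_out <- parts$a
        d_lat <- parts$b
      } else {
        d_slow_out <- dxs
        d_lat <- cbr_bw(net, grads, paste0(lname, ".proj"), dxs, sk$proj)
      }
      d_fast_from_lat <- cbr_bw(net, grads, lname, d_lat, sk$lat)
      dxf <- dxf + d_fast_from_lat
    } else {
      d_slow_out <- dxs
    }
    dxs <- stage_bw(net, grads, "slow", st_s, d_slow_out, sk$slow)
    dxf <- stage_bw(net, grads, "fast", st_f, dxf, sk$fast)
  }

  # input gradients of the stem convolutions are never consumed
  d_sp <- maxpool3d_bw(dxs, cache$slow_pool)
  cbr_bw(net, grads, "slow.conv1", d_sp, cache$slow_conv1, need_dx = FALSE)
  d_fp <- maxpool3d_bw(dxf, cache$fast_pool)
  cbr_bw(net, grads, "fast.conv1", d_fp, cache$fast_conv1, need_dx = FALSE)

  as.list(grads)
}

apply_bn_updates <- function(net, updates) {
  for (nm in names(updates)) net$buffers[[nm]] <- updates[[nm]]
  net
}

#' Forward pass producing class logits
#'
#' Generic so that evaluation utilities can also be exercised with scripted
#' stub models in tests.
#'
#' @param net Model object.
#' @param xs Slow-pathway input tensor `(3, slow_len, H, W, N)`.
#' @param xf Fast-pathway input tensor `(3, fast_len, H, W, N)`.
#' @param ... Passed to methods.
#' @return Matrix of logits, `n_classes x N`.
#' @export
predict_logits <- function(net, xs, xf, ...) UseMethod("predict_logits")

#' @rdname predict_logits
#' @export
predict_logits.pmb_network <- function(net, xs, xf, ...) {
  net_forward(net, xs, xf, training = FALSE, keep_cache = FALSE)$logits
}
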