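# Differentiable layer primitives on (C, T, H, W, N) tensors.
# Each *_fw returns list(y, cache); each *_bw takes (dy, cache) and returns
# list(dx, <param grads>). Convolutions carry no bias (normalization supplies
# the shift); the classifier is the only biased layer.

same_pad <- function(k) (k - 1L) %/% 2L

conv3d_fw <- function(x, w, stride, pad = same_pad(dim(w)[3:5])) {
  d <- dim(w)
  wm <- matrix(w, nrow = d[1])
  y <- cpp_conv3d_fwd(x, as.integer(dim(x)), wm, as.integer(d[3:5]),
                      as.integer(stride), as.integer(pad))
  list(y = y, cache = list(x = x, w = w, stride = as.integer(stride),
                           pad = as.integer(pad)))
}

conv3d_bw <- function(dy, cache, need_dx = TRUE) {
  d <- dim(cache$w)
  wm <- matrix(cache$w, nrow = d[1])
  g <- cpp_conv3d_bwd(cache$x, as.integer(dim(cache$x)), wm,
                      as.integer(d[3:5]), cache$stride, cache$pad, dy,
                      need_dx)
  dw <- g$dw
  dim(dw) <- d
  list(dx = if (need_dx) g$dx else NULL, dw = dw)
}

# Batch normalization over the channel dimension (statistics over T, H, W, N).
bn_fw <- function(x, gamma, beta, rmean, rvar, training,
                  momentum = 0.1, eps = 1e-5) {
  C <- dim(x)[1]
  xm <- matrix(x, nrow = C)
  if (training) {
    mu <- rowMeans(xm)
    cen <- xm - mu
    v <- rowMeans(cen * cen)
    new_rmean <- (1 - momentum) * rmean + momentum * mu
    m <- ncol(xm)
    unbiased <- if (m > 1) v * m / (m - 1) else v
    new_rvar <- (1 - momentum) * rvar + momentum * unbiased
  } else {
    mu <- rmean
    v <- rvar
    cen <- xm - mu
    new_rmean <- rmean
    new_rvar <- rvar
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- cen * istd
  y <- gamma * xhat + beta
  dim(y) <- dim(x)
  list(y = y,
       cache = list(xhat = xhat, istd = istd, gamma = gamma,
                    training = training, dims = dim(x)),
       rmean = new_rmean, rvar = new_rvar)
}

bn_bw <- function(dy, cache) {
  C <- cache$dims[1]
  dym <- matrix(dy, nrow = C)
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  if (cache$training) {
    m <- ncol(dym)
    dx <- (cache$gamma * cache$istd / m) * (m * dym - dbeta - xhat * dgamma)
  } else {
    dx <- cache$gamma * cache$istd * dym
  }
  dim(dx) <- cache$dims
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_bw <- function(dy, mask) dy * mask

maxpool3d_fw <- function(x, kernel, stride, pad) {
  r <- cpp_maxpool3d_fwd(x, as.integer(dim(x)), as.integer(kernel),
                         as.integer(stride), as.integer(pad))
  list(y = r$y, cache = list(argmax = r$argmax, xlen = length(x),
                             dims = dim(x)))
}

maxpool3d_bw <- function(dy, cache) {
  dx <- cpp_maxpool3d_bwd(dy, cache$argmax, cache$xlen)
  dim(dx) <- cache$dims
  dx
}

# Global average pooling over (T, H, W): (C,T,H,W,N) -> (C,N)
gap_fw <- function(x) {
  d <- dim(x)
  m <- prod(d[2:4])
  a <- array(x, c(d[1], m, d[5]))
  y <- apply(a, 3, rowMeans)
  dim(y) <- c(d[1], d[5])
  list(y = y, cache = d)
}

gap_bw <- function(dy, dims) {
  m <- prod(dims[2:4])
  per <- dy / m  # (C, N), broadcast over the m temporal-spatial positions
  dx <- aperm(array(per, c(dims[1], dims[5], m)), c(1, 3, 2))
  dim(dx) <- dims
  dx
}

dropout_fw <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  mask <- (matrix(runif(length(x)), nrow(x), ncol(x)) >= p) / (1 - p)
  list(y = x * mask, cache = mask)
}

dropout_bw <- function(dy, mask) if (is.null(mask)) dy else dy * mask

linear_fw <- function(x, w, b) {
  # x: (F, N); w: (K, F); b: (K)
  list(y = w %*% x + b, cache = list(x = x, w = w))
}

linear_bw <- function(dy, cache) {
  list(dx = t(cache$w) %*% dy,
       dw = dy %*% t(cache$x),
       db = rowSums(dy))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Cross-entropy over softmax outputs; labels are 1-based class indices.
softmax_ce <- function(logits, labels) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / n
  list(loss = loss, dlogits = dlogits, probs = p)
}
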