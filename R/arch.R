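#' Declarative architecture specification for PMB-SCN variants
#'
#' Returns the published configuration of one of the three PMB-SCN variants:
#' a dual-pathway (slow/fast) 3D residual network with two-layer basic blocks,
#' no temporal downsampling, and time-strided lateral connections carrying
#' fast-pathway features into the slow pathway after res2--res4.
#'
#' The slow pathway samples 8 frames of a 64-frame window (temporal stride 8)
#' with wide channels; the fast pathway samples 32 frames (stride 2) with
#' `beta = 1/8` of the slow channel width at every stage. Non-degenerate
#' (temporal extent 3) convolutions appear only in res4/res5 on the slow
#' pathway but in every residual stage of the fast pathway; the second layer
#' of every block is a spatial-only (1,3,3) convolution.
#'
#' `width_divisor`, `block_counts`, `slow_len` and `fast_len` allow reduced
#' configurations (used e.g. for CPU-scale training experiments) while keeping
#' every structural rule of the family intact.
#'
#' @param variant One of `"pmb-scn-34"`, `"pmb-scn-34half"`, `"pmb-scn-18"`.
#' @param n_classes Number of output classes (default 5 behaviors).
#' @param fusion Lateral fusion mode. `"concat"` (default) concatenates the
#'   time-strided lateral features onto the slow channels, widening the next
#'   stage's entry block; `"project_sum"` adds a 1x1x1 projection to the slow
#'   width followed by elementwise addition.
#' @param width_divisor Divide every channel width by this factor.
#' @param block_counts Optional length-4 override of the res2--res5 block
#'   counts.
#' @param slow_len,fast_len Temporal lengths of the two pathway inputs.
#' @param beta Fast/slow channel ratio (fixed at 1/8 in the published family).
#' @return An object of class `pmb_arch_spec`.
#' @examples
#' spec <- make_arch_spec("pmb-scn-18")
#' count_parameters(spec) / 1e6
#' @export
make_arch_spec <- function(variant = c("pmb-scn-34", "pmb-scn-34half", "pmb-scn-18"),
                           n_classes = 5L,
                           fusion = c("concat", "project_sum"),
                           width_divisor = 1L,
                           block_counts = NULL,
                           slow_len = 8L, fast_len = 32L,
                           beta = 1 / 8) {
  variant <- match.arg(variant)
  fusion <- match.arg(fusion)
  base <- switch(variant,
    "pmb-scn-34"     = list(ch = c(128L, 256L, 512L, 1024L), blocks = c(3L, 4L, 6L, 3L)),
    "pmb-scn-34half" = list(ch = c(64L, 128L, 256L, 512L),   blocks = c(3L, 4L, 6L, 3L)),
    "pmb-scn-18"     = list(ch = c(128L, 256L, 512L, 1024L), blocks = c(2L, 2L, 2L, 2L)))
  if (!is.null(block_counts)) {
    stopifnot(length(block_counts) == 4L, all(block_counts >= 1L))
    base$blocks <- as.integer(block_counts)
  }
  wd <- as.integer(width_divisor)
  stopifnot(wd >= 1L)
  slow_conv1 <- max(1L, 64L %/% wd)
  slow_ch <- pmax(1L, base$ch %/% wd)
  fast_conv1 <- max(1L, as.integer(round(slow_conv1 * beta)))
  fast_ch <- pmax(1L, as.integer(round(slow_ch * beta)))

  stage_names <- c("res2", "res3", "res4", "res5")
  mk_stages <- function(ch, slow_path) {
    lapply(seq_len(4L), function(i) {
      t1 <- if (slow_path && i <= 2L) 1L else 3L  # slow res2/res3 are spatial-only
      list(name = stage_names[i], n_blocks = base$blocks[i], channels = ch[i],
           k1 = c(t1, 3L, 3L), k2 = c(1L, 3L, 3L),
           spatial_stride = if (i == 1L) 1L else 2L)
    })
  }

  structure(list(
    variant = variant, n_classes = as.integer(n_classes), beta = beta,
    fusion = fusion, slow_len = as.integer(slow_len),
    fast_len = as.integer(fast_len),
    slow = list(conv1_channels = slow_conv1, conv1_kernel = c(1L, 7L, 7L),
                conv1_stride = c(1L, 2L, 2L), stages = mk_stages(slow_ch, TRUE)),
    fast = list(conv1_channels = fast_conv1, conv1_kernel = c(5L, 7L, 7L),
                conv1_stride = c(1L, 2L, 2L), stages = mk_stages(fast_ch, FALSE)),
    pool1 = list(kernel = c(1L, 3L, 3L), stride = c(1L, 2L, 2L),
                 pad = c(0L, 1L, 1L)),
    lateral = list(stages = c("res2", "res3", "res4"), kernel = c(5L, 1L, 1L),
                   stride = c(4L, 1L, 1L), out_mult = 2L)
  ), class = "pmb_arch_spec")
}

#' @export
print.pmb_arch_spec <- function(x, ...) {
  cat("PMB-SCN architecture spec:", x$variant, "\n")
  cat("  classes:", x$n_classes, " fusion:", x$fusion,
      " beta:", format(x$beta), "\n")
  cat("  slow: conv1", x$slow$conv1_channels, "ch, input length", x$slow_len, "\n")
  cat("  fast: conv1", x$fast$conv1_channels, "ch, input length", x$fast_len, "\n")
  for (i in seq_along(x$slow$stages)) {
    s <- x$slow$stages[[i]]; f <- x$fast$stages[[i]]
    cat(sprintf("  %s: %d blocks, slow %d ch (k1 %s), fast %d ch\n",
                s$name, s$n_blocks, s$channels,
                paste(s$k1, collapse = "x"), f$channels))
  }
  invisible(x)
}

# Channel widths entering/leaving each residual stage for one pathway.
# For the slow pathway under concat fusion, lateral features widen the
# input of res3/res4/res5 by 2*beta-width fast channels.
stage_io_channels <- function(spec, pathway = c("slow", "fast")) {
  pathway <- match.arg(pathway)
  pw <- spec[[pathway]]
  out <- vapply(pw$stages, function(s) s$channels, integer(1))
  inp <- c(pw$conv1_channels, out[-4L])
  if (pathway == "slow" && spec$fusion == "concat") {
    fast_out <- vapply(spec$fast$stages, function(s) s$channels, integer(1))
    widen <- spec$lateral$out_mult * fast_out[1:3]  # after res2..res4
    inp[2:4] <- inp[2:4] + widen
  }
  list(input = inp, output = out)
}

# Ordered named list of parameter array dimensions: the single source of
# truth for build_network(), init_weights() and count_parameters().
param_shapes <- function(spec) {
  shapes <- list()
  add <- function(name, d) shapes[[name]] <<- as.integer(d)
  add_bn <- function(name, c) {
    add(paste0(name, ".bn.gamma"), c)
    add(paste0(name, ".bn.beta"), c)
  }
  for (pw in c("slow", "fast")) {
    p <- spec[[pw]]
    add(paste0(pw, ".conv1.w"), c(p$conv1_channels, 3L, p$conv1_kernel))
    add_bn(paste0(pw, ".conv1"), p$conv1_channels)
    io <- stage_io_channels(spec, pw)
    for (i in seq_along(p$stages)) {
      st <- p$stages[[i]]
      inch <- io$input[i]
      for (b in seq_len(st$n_blocks)) {
        nm <- paste0(pw, ".", st$name, ".b", b)
        add(paste0(nm, ".conv1.w"), c(st$channels, inch, st$k1))
        add_bn(paste0(nm, ".conv1"), st$channels)
        add(paste0(nm, ".conv2.w"), c(st$channels, st$channels, st$k2))
        add_bn(paste0(nm, ".conv2"), st$channels)
        if (inch != st$channels || (b == 1L && st$spatial_stride > 1L)) {
          add(paste0(nm, ".down.w"), c(st$channels, inch, 1L, 1L, 1L))
          add_bn(paste0(nm, ".down"), st$channels)
        }
        inch <- st$channels
      }
    }
  }
  fast_out <- vapply(spec$fast$stages, function(s) s$channels, integer(1))
  slow_out <- vapply(spec$slow$stages, function(s) s$channels, integer(1))
  names(fast_out) <- names(slow_out) <-
    vapply(spec$fast$stages, function(s) s$name, character(1))
  for (stn in spec$lateral$stages) {
    cf <- fast_out[[stn]]
    cl <- spec$lateral$out_mult * cf
    add(paste0("lat.", stn, ".w"), c(cl, cf, spec$lateral$kernel))
    add_bn(paste0("lat.", stn), cl)
    if (spec$fusion == "project_sum") {
      add(paste0("lat.", stn, ".proj.w"), c(slow_out[[stn]], cl, 1L, 1L, 1L))
      add_bn(paste0("lat.", stn, ".proj"), slow_out[[stn]])
    }
  }
  nfeat <- slow_out[["res5"]] + fast_out[["res5"]]
  add("fc.w", c(spec$n_classes, nfeat))
  add("fc.b", spec$n_classes)
  shapes
}

#' Count trainable parameters
#'
#' Sums every trainable scalar (convolution and classifier weights,
#' normalization scale/shift, classifier bias) of a network or of the network
#' an architecture spec describes. Running normalization statistics are
#' buffers, not parameters, and are excluded.
#'
#' @param x A `pmb_network` or `pmb_arch_spec`.
#' @return Integer-valued count of trainable scalars.
#' @export
count_parameters <- function(x) {
  shapes <- if (inherits(x, "pmb_arch_spec")) param_shapes(x)
            else if (inherits(x, "pmb_network")) lapply(x$params, dim_or_len)
            else stop("expected a pmb_arch_spec or pmb_network")
  sum(vapply(shapes, prod, numeric(1)))
}

dim_or_len <- function(a) if (is.null(dim(a))) length(a) else dim(a)

conv_out_len <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

#' Per-stage output shapes of both pathways
#'
#' Walks the stride pyramid and reports the (channels, T, H, W) tensor shape
#' after the data layer, conv1, pool1 and each residual stage, for a given
#' spatial input size. Temporal lengths are invariant across stages within
#' each pathway (the family performs no temporal downsampling).
#'
#' @param spec A `pmb_arch_spec`.
#' @param input_size Spatial input size `c(H, W)` (a single number is squared).
#' @return A data.frame with one row per stage and pathway.
#' @examples
#' stage_output_shapes(make_arch_spec("pmb-scn-34"), 224)
#' @export
stage_output_shapes <- function(spec, input_size = c(224L, 224L)) {
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  if (min(input_size) < 32L)
    stop("input too small for the stride pyramid (needs >= 32 px)")
  rows <- list()
  for (pw in c("slow", "fast")) {
    p <- spec[[pw]]
    tlen <- if (pw == "slow") spec$slow_len else spec$fast_len
    h <- as.integer(input_size[1]); w <- as.integer(input_size[2])
    push <- function(stage, c) rows[[length(rows) + 1L]] <<-
      data.frame(stage = stage, pathway = pw, channels = c,
                 t = tlen, h = h, w = w, stringsAsFactors = FALSE)
    push("data", 3L)
    kh <- p$conv1_kernel[2]; kw <- p$conv1_kernel[3]
    h <- conv_out_len(h, kh, p$conv1_stride[2], same_pad(kh))
    w <- conv_out_len(w, kw, p$conv1_stride[3], same_pad(kw))
    push("conv1", p$conv1_channels)
    h <- conv_out_len(h, spec$pool1$kernel[2], spec$pool1$stride[2], spec$pool1$pad[2])
    w <- conv_out_len(w, spec$pool1$kernel[3], spec$pool1$stride[3], spec$pool1$pad[3])
    push("pool1", p$conv1_channels)
    for (st in p$stages) {
      if (st$spatial_stride > 1L) {
        h <- conv_out_len(h, st$k1[2], st$spatial_stride, same_pad(st$k1[2]))
        w <- conv_out_len(w, st$k1[3], st$spatial_stride, same_pad(st$k1[3]))
      }
      if (h < 1L || w < 1L) stop("input too small for the stride pyramid")
      push(st$name, st$channels)
    }
  }
  do.call(rbind, rows)
}

#' Serialize / deserialize an architecture spec as YAML
#'
#' @param spec A `pmb_arch_spec`.
#' @param path File path.
#' @return `arch_from_yaml` returns the reconstructed `pmb_arch_spec`.
#' @export
arch_to_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname arch_to_yaml
#' @export
arch_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$n_classes <- as.integer(x$n_classes)
  intify <- function(l) rapply(l, function(v) if (is.numeric(v)) as.integer(v) else v,
                               how = "replace")
  for (f in c("slow", "fast", "pool1")) x[[f]] <- intify(x[[f]])
  x$lateral$kernel <- as.integer(x$lateral$kernel)
  x$lateral$stride <- as.integer(x$lateral$stride)
  x$lateral$out_mult <- as.integer(x$lateral$out_mult)
  x$slow_len <- as.integer(x$slow_len); x$fast_len <- as.integer(x$fast_len)
  structure(x, class = "pmb_arch_spec")
}
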