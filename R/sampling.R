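#' Sample a temporal window from a clip
#'
#' Selects a contiguous (possibly wrapped) window of `window_len` frames.
#' Clips shorter than the window are loop-padded: indices wrap modulo the
#' clip length, preserving motion statistics for periodic behaviors. In
#' `"random"` mode the start is uniform on `[0, max(n_frames - window_len, 0)]`;
#' in `"uniform"` mode the start is the `k`-th of `n_windows` starts evenly
#' spaced over the same range; `"center"` picks the middle start.
#'
#' @param n_frames Clip length in frames.
#' @param mode `"random"`, `"uniform"` or `"center"`.
#' @param k Window index (1-based) for `"uniform"` mode.
#' @param n_windows Number of evenly spaced windows in `"uniform"` mode.
#' @param window_len Window length (default 64 frames).
#' @param seed Optional seed for `"random"` mode.
#' @return Object of class `window_indices`: `start` and 0-based `indices`
#'   of length `window_len`.
#' @export
sample_window <- function(n_frames, mode = c("random", "uniform", "center"),
                          k = 1L, n_windows = 10L, window_len = 64L,
                          seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 1L)
  hi <- max(n_frames - window_len, 0L)
  start <- switch(mode,
    random = with_seed(seed, sample.int(hi + 1L, 1L) - 1L),
    uniform = {
      stopifnot(k >= 1L, k <= n_windows)
      starts <- if (n_windows == 1L) 0 else seq(0, hi, length.out = n_windows)
      as.integer(round(starts[k]))
    },
    center = as.integer(hi %/% 2L))
  structure(list(start = as.integer(start),
                 indices = as.integer((start + 0:(window_len - 1L)) %%
                                        as.integer(n_frames))),
            class = "window_indices")
}

#' Subsample a window into the two pathway frame sets
#'
#' The slow pathway takes every `slow_stride`-th window position starting at
#' 0; the fast pathway every `fast_stride`-th. With the default 64-frame
#' window and strides 8/2 this yields 8 slow and 32 fast frames, the slow set
#' a subset of the fast set.
#'
#' @param w A [sample_window()] result.
#' @param slow_stride,fast_stride Temporal strides in frames.
#' @return Object of class `pathway_pair` with 0-based clip frame indices
#'   `slow` and `fast`.
#' @export
pathway_subsample <- function(w, slow_stride = 8L, fast_stride = 2L) {
  stopifnot(inherits(w, "window_indices"))
  len <- length(w$indices)
  structure(list(slow = w$indices[seq(1L, len, by = slow_stride)],
                 fast = w$indices[seq(1L, len, by = fast_stride)]),
            class = "pathway_pair")
}

# Scale a frame stack (H, W, 3, T) so its shorter spatial side equals
# `target`, preserving aspect (bilinear).
scale_shorter_side <- function(frames, target) {
  d <- dim(frames)
  if (d[1] <= d[2]) {
    nh <- as.integer(target); nw <- as.integer(round(d[2] * target / d[1]))
  } else {
    nw <- as.integer(target); nh <- as.integer(round(d[1] * target / d[2]))
  }
  if (nh == d[1] && nw == d[2]) return(frames)
  out <- EBImage::resize(frames, w = nh, h = nw)  # resizes the first two dims
  out
}

#' Spatially aligned random training crop
#'
#' Applies one random `size x size` crop identically to all frames,
#' deterministic given `seed`. Frames whose shorter side is below `size`
#' raise a geometry error; callers typically scale the shorter side to the
#' test-scale convention first.
#'
#' @param frames Array `(H, W, 3, T)` (or a [frame_sequence()]).
#' @param size Crop side length in pixels.
#' @param seed Optional seed.
#' @return Cropped array (or `frame_sequence`).
#' @export
train_crop <- function(frames, size = 224L, seed = NULL) {
  is_fs <- inherits(frames, "frame_sequence")
  arr <- if (is_fs) frames$frames else frames
  d <- dim(arr)
  if (d[1] < size || d[2] < size) stop("frame smaller than crop size")
  off <- with_seed(seed, c(sample.int(d[1] - size + 1L, 1L) - 1L,
                           sample.int(d[2] - size + 1L, 1L) - 1L))
  out <- arr[off[1] + seq_len(size), off[2] + seq_len(size), , , drop = FALSE]
  if (is_fs) frame_sequence(out, frames$fps) else out
}

#' The 30-view inference set of a test clip
#'
#' Scales the shorter spatial side to `scale` pixels preserving aspect, then
#' forms `n_temporal` uniformly spaced temporal windows and `n_spatial`
#' square `crop_size` crops placed along the longer axis at the first,
#' center and last admissible offsets. With the defaults this is the
#' 10 x 3 = 30-view protocol. Views are materialized lazily via [get_view()]
#' to keep memory bounded.
#'
#' @param seq A [frame_sequence()].
#' @param scale Shorter-side target in pixels (default 240).
#' @param crop_size Square crop side (default 240).
#' @param window_len Temporal window length (default 64).
#' @param n_temporal,n_spatial View grid (default 10 and 3).
#' @param slow_stride,fast_stride Pathway strides.
#' @return Object of class `view_set` with `n_views = n_temporal * n_spatial`.
#' @export
test_views <- function(seq, scale = 240L, crop_size = 240L, window_len = 64L,
                       n_temporal = 10L, n_spatial = 3L,
                       slow_stride = 8L, fast_stride = 2L) {
  stopifnot(inherits(seq, "frame_sequence"), n_frames(seq) >= 1L)
  scaled <- scale_shorter_side(seq$frames, scale)
  d <- dim(scaled)
  if (min(d[1], d[2]) < crop_size) stop("scaled frame smaller than crop size")
  windows <- lapply(seq_len(n_temporal), function(k)
    sample_window(n_frames(seq), "uniform", k = k, n_windows = n_temporal,
                  window_len = window_len))
  long_axis <- if (d[1] >= d[2]) 1L else 2L
  L <- d[long_axis]
  offs <- if (n_spatial == 1L) as.integer(round((L - crop_size) / 2))
          else as.integer(round(seq(0, L - crop_size, length.out = n_spatial)))
  crops <- matrix(0L, n_spatial, 2L)
  crops[, long_axis] <- offs
  structure(list(scaled = scaled, fps = seq$fps, windows = windows,
                 crops = crops, crop_size = as.integer(crop_size),
                 slow_stride = as.integer(slow_stride),
                 fast_stride = as.integer(fast_stride),
                 n_temporal = as.integer(n_temporal),
                 n_spatial = as.integer(n_spatial),
                 n_views = as.integer(n_temporal * n_spatial)),
            class = "view_set")
}

#' @export
print.view_set <- function(x, ...) {
  cat(sprintf("<view_set> %d views (%d temporal x %d spatial), %dpx crops\n",
              x$n_views, x$n_temporal, x$n_spatial, x$crop_size))
  invisible(x)
}

#' Materialize one view of a view set
#'
#' @param vs A [test_views()] result.
#' @param i View index in `1..n_views`; temporal window varies fastest.
#' @return A `pathway_pair`-like list with `slow` and `fast` cropped frame
#'   stacks `(crop, crop, 3, T)`.
#' @export
get_view <- function(vs, i) {
  stopifnot(i >= 1L, i <= vs$n_views)
  ti <- (i - 1L) %% vs$n_temporal + 1L
  si <- (i - 1L) %/% vs$n_temporal + 1L
  w <- vs$windows[[ti]]
  pp <- pathway_subsample(w, vs$slow_stride, vs$fast_stride)
  off <- vs$crops[si, ]
  sel <- function(idx) {
    fr <- vs$scaled[off[1] + seq_len(vs$crop_size),
                    off[2] + seq_len(vs$crop_size), , idx + 1L, drop = FALSE]
    fr
  }
  list(slow = sel(pp$slow), fast = sel(pp$fast))
}

# ---- tensor conversion ---------------------------------------------------

# Fixed input standardization constants (pixels scaled to [0,1] first).
INPUT_MEAN <- 0.45
INPUT_SD <- 0.225

# (H, W, 3, T) frame stack -> (3, T, H, W) standardized tensor.
frames_to_tensor <- function(frames) {
  x <- aperm(frames / 255, c(3L, 4L, 1L, 2L))
  (x - INPUT_MEAN) / INPUT_SD
}

# Stack a list of (3,T,H,W) tensors into a (3,T,H,W,N) batch.
stack_batch <- function(tensors) {
  d <- dim(tensors[[1]])
  out <- array(0, c(d, length(tensors)))
  for (i in seq_along(tensors)) out[, , , , i] <- tensors[[i]]
  out
}
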