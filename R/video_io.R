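#' Ordered decoded frames of one clip
#'
#' Container for the frames of a single video clip: an `H x W x 3 x n_frames`
#' array of 8-bit intensities (stored as integers in `[0, 255]`) plus the
#' frame rate.
#'
#' @param frames Numeric or integer array of dim `(H, W, 3, n_frames)`;
#'   a single-frame `(H, W, 3)` array is promoted.
#' @param fps Frames per second (> 0).
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps = 25) {
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  stopifnot(length(dim(frames)) == 4L, dim(frames)[3] == 3L,
            dim(frames)[4] >= 1L, fps > 0)
  storage.mode(frames) <- "integer"
  structure(list(frames = frames, fps = fps), class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %g fps (%.2f s)\n",
              d[4], d[1], d[2], x$fps, d[4] / x$fps))
  invisible(x)
}

#' @rdname frame_sequence
#' @param seq A `frame_sequence`.
#' @export
n_frames <- function(seq) dim(seq$frames)[4]

#' Read a video clip
#'
#' Reads either a directory of image frames (PNG, in lexicographic order) or
#' an AVI file. AVI support covers uncompressed 24-bit DIB streams (the
#' lossless format [write_clip()] emits); the frame rate is taken from the
#' container metadata. Frame directories carry no rate, so `fps` supplies it
#' (default 25, the conventional acquisition rate).
#'
#' @param path Path to an `.avi` file or a directory of frames.
#' @param fps Frame rate assumed for frame directories.
#' @return A [frame_sequence()].
#' @export
read_clip <- function(path, fps = 25) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) stop("empty frame directory: ", path)
    frames <- lapply(files, function(f) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
      if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
      a
    })
    d <- dim(frames[[1]])
    arr <- array(0L, c(d[1], d[2], 3L, length(frames)))
    for (i in seq_along(frames)) arr[, , , i] <- as.integer(round(frames[[i]] * 255))
    frame_sequence(arr, fps)
  } else if (file.exists(path)) {
    read_avi(path)
  } else {
    stop("no such clip: ", path)
  }
}

#' Write a video clip
#'
#' Writes a [frame_sequence()] either as an uncompressed 24-bit AVI container
#' (path ending in `.avi`; lossless, bitwise round-trip through
#' [read_clip()]) or as a directory of numbered PNG frames.
#'
#' @param seq A `frame_sequence`.
#' @param path Target `.avi` path or frame-directory path.
#' @return `path`, invisibly.
#' @export
write_clip <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"), n_frames(seq) >= 1L)
  if (grepl("\\.avi$", path, ignore.case = TRUE)) {
    write_avi(seq, path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    d <- dim(seq$frames)
    for (i in seq_len(d[4])) {
      f <- file.path(path, sprintf("frame_%06d.png", i))
      png::writePNG(seq$frames[, , , i] / 255, f)
    }
  }
  invisible(path)
}

# ---- minimal RIFF/AVI container (uncompressed 24-bit DIB video) ----------
# Frames are stored bottom-up, BGR, rows padded to 4-byte boundaries, as
# '00db' chunks inside the 'movi' list; fps is carried as dwScale/dwRate in
# the stream header.

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
fourcc <- function(s) charToRaw(s)

avi_frame_bytes <- function(frame) {
  # frame: (H, W, 3) integer in [0,255]
  d <- dim(frame)
  h <- d[1]; w <- d[2]
  a <- frame[h:1, , c(3L, 2L, 1L), drop = FALSE]     # bottom-up, BGR
  bytes <- as.raw(as.integer(aperm(a, c(3L, 2L, 1L))))  # channel, x, row
  stride <- 3L * w
  pad <- (4L - stride %% 4L) %% 4L
  if (pad > 0L) {
    m <- matrix(bytes, nrow = stride)
    m <- rbind(m, matrix(as.raw(0L), nrow = pad, ncol = h))
    bytes <- as.vector(m)
  }
  bytes
}

write_avi <- function(seq, path) {
  d <- dim(seq$frames)
  h <- d[1]; w <- d[2]; nf <- d[4]
  scale <- 1000L
  rate <- as.integer(round(seq$fps * 1000))
  stride <- 3L * w + (4L - (3L * w) %% 4L) %% 4L
  fsize <- stride * h

  avih <- c(u32(round(1e6 / seq$fps)), u32(fsize * seq$fps), u32(0), u32(0x10),
            u32(nf), u32(0), u32(1), u32(fsize), u32(w), u32(h),
            u32(0), u32(0), u32(0), u32(0))
  strh <- c(fourcc("vids"), fourcc("DIB "), u32(0), u16(0), u16(0), u32(0),
            u32(scale), u32(rate), u32(0), u32(nf), u32(fsize), u32(-1),
            u32(0), u16(0), u16(0), u16(w), u16(h))
  strf <- c(u32(40), u32(w), u32(h), u16(1), u16(24), u32(0), u32(fsize),
            u32(0), u32(0), u32(0), u32(0))

  chunk <- function(id, body) c(fourcc(id), u32(length(body)), body,
                                if (length(body) %% 2L) as.raw(0L))
  lst <- function(type, body) chunk("LIST", c(fourcc(type), body))

  strl <- lst("strl", c(chunk("strh", strh), chunk("strf", strf)))
  hdrl <- lst("hdrl", c(chunk("avih", avih), strl))

  movi_body <- fourcc("movi")
  idx <- raw(0)
  offset <- 4L  # offsets relative to the start of the 'movi' list data
  frame_chunks <- vector("list", nf)
  for (i in seq_len(nf)) {
    b <- avi_frame_bytes(seq$frames[, , , i])
    frame_chunks[[i]] <- chunk("00db", b)
    idx <- c(idx, fourcc("00db"), u32(0x10), u32(offset), u32(length(b)))
    offset <- offset + length(frame_chunks[[i]])
  }
  movi <- lst("movi", do.call(c, frame_chunks))
  idx1 <- chunk("idx1", idx)

  body <- c(fourcc("AVI "), hdrl, movi, idx1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32(length(body)), body), con)
  invisible(path)
}

read_u32 <- function(r, at) {
  sum(as.integer(r[at + 0:3]) * c(1, 256, 65536, 16777216))
}

read_avi <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(r[1:4]) != "RIFF" || rawToChar(r[9:12]) != "AVI ")
    stop("not an AVI file: ", path)
  w <- h <- nf <- NA_integer_; scale <- rate <- NA_real_
  frames_raw <- list()

  walk <- function(from, to) {
    p <- from
    while (p + 7 <= to) {
      id <- rawToChar(r[p + 0:3])
      size <- read_u32(r, p + 4)
      body_at <- p + 8
      if (id == "LIST") {
        walk(body_at + 4, body_at + size - 1)
      } else if (id == "avih") {
        w <<- read_u32(r, body_at + 32); h <<- read_u32(r, body_at + 36)
      } else if (id == "strh" && rawToChar(r[body_at + 0:3]) == "vids") {
        scale <<- read_u32(r, body_at + 20); rate <<- read_u32(r, body_at + 24)
      } else if (id == "strf") {
        bits <- read_u32(r, body_at + 14) %% 65536
        comp <- read_u32(r, body_at + 16)
        if (bits != 24 || comp != 0)
          stop("unsupported AVI codec (only uncompressed 24-bit DIB)")
      } else if (id == "00db" || id == "00dc") {
        frames_raw[[length(frames_raw) + 1L]] <<- r[body_at:(body_at + size - 1)]
      }
      p <- body_at + size + size %% 2
    }
  }
  walk(13, 8 + read_u32(r, 5))  # chunks follow the 'AVI ' form type

  if (length(frames_raw) == 0L) stop("AVI contains no video frames: ", path)
  stride <- 3L * w + (4L - (3L * w) %% 4L) %% 4L
  arr <- array(0L, c(h, w, 3L, length(frames_raw)))
  for (i in seq_along(frames_raw)) {
    m <- matrix(as.integer(frames_raw[[i]]), nrow = stride)[seq_len(3L * w), ,
                                                            drop = FALSE]
    a <- array(m, c(3L, w, h))            # channel, x, row (bottom-up, BGR)
    arr[, , , i] <- aperm(a, c(3L, 2L, 1L))[h:1, , c(3L, 2L, 1L)]
  }
  frame_sequence(arr, rate / scale)
}

# ---- manifests -----------------------------------------------------------

#' Build, read and write clip manifests
#'
#' A manifest is a data.frame with columns `clip_path`, `label`, `n_frames`,
#' `fps`, `duration_s`; labels are drawn from [behavior_classes()]. Paths may
#' be relative to the manifest's directory.
#'
#' @param clip_path,label,n_frames,fps Column vectors.
#' @return A manifest data.frame.
#' @export
manifest <- function(clip_path, label, n_frames, fps) {
  m <- data.frame(clip_path = as.character(clip_path),
                  label = as.character(label),
                  n_frames = as.integer(n_frames),
                  fps = as.numeric(fps),
                  duration_s = as.integer(n_frames) / as.numeric(fps),
                  stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  req <- c("clip_path", "label", "n_frames", "fps", "duration_s")
  if (!all(req %in% names(m))) stop("manifest is missing columns")
  bad <- setdiff(unique(m$label), behavior_classes())
  if (length(bad)) stop("unknown labels in manifest: ", paste(bad, collapse = ", "))
  if (any(abs(m$duration_s - m$n_frames / m$fps) > 1 / m$fps))
    stop("manifest durations inconsistent with n_frames/fps")
  invisible(m)
}

#' @rdname manifest
#' @param path CSV file path.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

#' @rdname manifest
#' @param m A manifest data.frame.
#' @export
write_manifest <- function(m, path) {
  validate_manifest(m)
  write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' Dataset statistics of a manifest
#'
#' Per-class clip counts (over the full class vocabulary, zero-filled),
#' a per-class histogram of clip durations in 1-second bins, and the total
#' duration.
#'
#' @param m A manifest data.frame.
#' @return A list of class `dataset_stats` with `class_counts`,
#'   `duration_hist` (classes x bins matrix) and `total_duration_s`.
#' @export
summarize_manifest <- function(m) {
  validate_manifest(m)
  if (nrow(m) == 0L) stop("empty manifest")
  cls <- behavior_classes()
  counts <- vapply(cls, function(k) sum(m$label == k), integer(1))
  ub <- max(ceiling(max(m$duration_s)), 1)
  breaks <- 0:ub
  hist_m <- matrix(0L, length(cls), ub, dimnames = list(cls, NULL))
  for (k in cls) {
    d <- m$duration_s[m$label == k]
    if (length(d))
      hist_m[k, ] <- as.integer(table(cut(d, breaks, right = TRUE,
                                          include.lowest = TRUE)))
  }
  colnames(hist_m) <- paste0("(", breaks[-length(breaks)], ",", breaks[-1], "]")
  structure(list(class_counts = counts, duration_hist = hist_m,
                 total_duration_s = sum(m$duration_s)),
            class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat("Clips per class:\n")
  print(x$class_counts)
  cat(sprintf("Total duration: %.2f s\n", x$total_duration_s))
  invisible(x)
}

#' Stratified split of a manifest
#'
#' Partitions a manifest into subsets whose per-class proportions honor
#' `fractions` up to integer rounding: per class, each subset first receives
#' `floor(fraction * n)` rows and leftover rows are then assigned to subsets
#' in declaration order. The partition is exact (disjoint, union equals the
#' input) and deterministic given `seed`.
#'
#' @param m A manifest data.frame.
#' @param fractions Positive proportions; normalized to sum to 1, so `c(4, 1, 1)`
#'   means 4:1:1.
#' @param seed Integer seed controlling the within-class shuffling.
#' @return A list of manifest data.frames, one per fraction.
#' @export
stratified_split <- function(m, fractions, seed = 1L) {
  validate_manifest(m)
  stopifnot(all(fractions > 0))
  fractions <- fractions / sum(fractions)
  ns <- length(fractions)
  tab <- table(m$label)
  if (any(tab < ns))
    stop("every class needs at least as many rows as there are subsets")
  assign_subset <- integer(nrow(m))
  with_seed(seed, {
    for (k in unique(m$label)) {
      idx <- which(m$label == k)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      base <- floor(fractions * n)
      rem <- n - sum(base)
      if (rem > 0L) base[seq_len(rem)] <- base[seq_len(rem)] + 1L
      assign_subset[idx] <- rep(seq_len(ns), times = base)
    }
  })
  lapply(seq_len(ns), function(s) {
    out <- m[assign_subset == s, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Random split into arbitrary-size subsets
#'
#' Plain (non-stratified) random partition of a manifest into subsets of the
#' given sizes, for splits specified by counts rather than proportions.
#'
#' @param m A manifest data.frame.
#' @param sizes Integer subset sizes summing to `nrow(m)`.
#' @param seed Integer seed.
#' @return A list of manifest data.frames.
#' @export
split_manifest <- function(m, sizes, seed = 1L) {
  validate_manifest(m)
  stopifnot(sum(sizes) == nrow(m))
  perm <- with_seed(seed, sample.int(nrow(m)))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(sizes), function(i) {
    out <- m[sort(perm[starts[i]:ends[i]]), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
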