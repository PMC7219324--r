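# Shared fixtures, built in code.

# A micro architecture small enough for numerical gradient checks and
# memorization runs: every structural rule of the family is kept.
micro_spec <- function(n_classes = 3L) {
  make_arch_spec("pmb-scn-34", n_classes = n_classes, width_divisor = 16L,
                 block_counts = c(1L, 1L, 1L, 1L), slow_len = 2L,
                 fast_len = 8L)
}

# Reduced configuration used for CPU-scale training experiments.
reduced_spec <- function() {
  make_arch_spec("pmb-scn-34", width_divisor = 8L,
                 block_counts = c(1L, 1L, 1L, 1L), slow_len = 2L,
                 fast_len = 8L)
}

reduced_train_config <- function(epochs, seed = 1L, ...) {
  train_config(epochs = epochs, warmup_epochs = max(1L, epochs %/% 10L),
               window_len = 16L, train_scale = 64L, crop_size = 64L,
               seed = seed, ...)
}

small_scene <- function(n_frames = 32L, seed = 1L) {
  scene_spec(width = 64L, height = 64L, n_frames = n_frames, seed = seed)
}

# Balanced toy manifest without any clips on disk (for manifest-only tests).
toy_manifest <- function(n_per_class, n_frames = 64L, fps = 25) {
  cls <- rep(behavior_classes(), each = n_per_class)
  manifest(clip_path = sprintf("%s_%03d", cls, sequence(rep(n_per_class, 5))),
           label = cls, n_frames = n_frames, fps = fps)
}

# The two printed 3-row confusion matrices from the cross-pigsty test set
# (rows/columns in that table's own order: motoring, scratching, lying,
# mounting, feeding; mounting/feeding rows empty because the new pigsty had
# no such samples).
table6_order <- c("motoring", "scratching", "lying", "mounting", "feeding")

table6_pmbscn <- function() {
  m <- rbind(c(39, 0, 0, 2, 0),
             c(1, 36, 2, 1, 0),
             c(4, 0, 38, 0, 0),
             c(0, 0, 0, 0, 0),
             c(0, 0, 0, 0, 0))
  dimnames(m) <- list(truth = table6_order, predicted = table6_order)
  m
}

table6_slowfast <- function() {
  m <- rbind(c(34, 1, 0, 6, 0),
             c(1, 38, 0, 1, 0),
             c(3, 3, 30, 4, 2),
             c(0, 0, 0, 0, 0),
             c(0, 0, 0, 0, 0))
  dimnames(m) <- list(truth = table6_order, predicted = table6_order)
  m
}

# A scripted stub model: emits pre-set logit columns in call order, so the
# view-aggregation pipeline can be checked against hand tallies.
make_stub <- function(logit_list) {
  env <- new.env()
  env$queue <- logit_list
  structure(list(env = env), class = "stub_net")
}

local_stub_method <- local({
  registered <- FALSE
  function() {
    if (!registered) {
      registerS3method("predict_logits", "stub_net",
                       function(net, xs, xf, ...) {
                         n <- dim(xs)[5]
                         out <- net$env$queue[[1]][, seq_len(n), drop = FALSE]
                         net$env$queue[[1]] <-
                           net$env$queue[[1]][, -seq_len(n), drop = FALSE]
                         if (ncol(net$env$queue[[1]]) == 0)
                           net$env$queue <- net$env$queue[-1]
                         out
                       },
                       envir = asNamespace("pmbscn"))
      registered <<- TRUE
    }
  }
})

tiny_clip <- function(seed) {
  generate_clip(default_class_specs()$lying,
                scene_spec(width = 48, height = 48, n_frames = 16, seed = seed))
}
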