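test_that("the cosine schedule hits its closed-form anchors", {
  n_max <- 1000
  expect_equal(lr_at(0, n_max), 0.0125)
  expect_equal(lr_at(n_max, n_max), 0)
  expect_equal(lr_at(n_max / 2, n_max), 0.00625)
  expect_error(lr_at(-1, n_max), "out of")
  expect_error(lr_at(n_max + 1, n_max), "out of")
})

test_that("warm-up ramps linearly, joins continuously, then never increases", {
  n_max <- 500; wu <- 50
  lr <- lr_at(0:n_max, n_max, warmup_iters = wu)
  expect_equal(lr[1], 0.1 * 0.0125)
  # continuity at the join
  expect_equal(lr[wu + 1], 0.0125 * 0.5 * (cos(pi * wu / n_max) + 1))
  # linear on the ramp
  expect_equal(diff(lr[1:wu]), rep(diff(lr[1:2]), wu - 1), tolerance = 1e-12)
  # non-increasing after warm-up, bounded by the base rate
  expect_true(all(diff(lr[(wu + 1):(n_max + 1)]) <= 1e-15))
  expect_true(all(lr <= 0.0125 + 1e-15))
})

test_that("He initialization: variance 2/n_l, zero biases, seed-determinism", {
  net <- build_network(make_arch_spec("pmb-scn-34half", width_divisor = 2,
                                      block_counts = c(1, 1, 1, 1)))
  net <- init_weights(net, 11)
  # closed form: 3x3x3 kernel over 64 input channels -> sd = sqrt(2/1728)
  expect_equal(sqrt(2 / (27 * 64)), 0.034, tolerance = 1e-2)
  checked <- 0L
  for (nm in names(net$fan_in)) {
    w <- net$params[[nm]]
    if (length(w) < 1e4) next
    expect_lt(abs(mean(w)), 3 * sqrt(2 / net$fan_in[[nm]]) / sqrt(length(w)) * 2)
    expect_equal(var(as.vector(w)), 2 / net$fan_in[[nm]], tolerance = 0.05)
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
  for (nm in grep("\\.bn\\.beta$|fc\\.b", names(net$params), value = TRUE))
    expect_true(all(net$params[[nm]] == 0))
  for (nm in grep("\\.bn\\.gamma$", names(net$params), value = TRUE))
    expect_true(all(net$params[[nm]] == 1))
  net2 <- init_weights(build_network(net$spec), 11)
  expect_identical(net$params, net2$params)
})

test_that("an SGD step with zero gradients and no decay is a no-op", {
  ns <- asNamespace("pmbscn")
  net <- init_weights(build_network(micro_spec()), 3)
  zero_grads <- lapply(net$params, function(p) p * 0)
  upd <- ns$sgd_step(net, zero_grads, state = list(), lr = 0.1,
                     momentum = 0.9, weight_decay = 0)
  expect_identical(upd$net$params, net$params)
  # with weight decay the weights (and only the weights) shrink
  upd2 <- ns$sgd_step(net, zero_grads, state = list(), lr = 0.1,
                      momentum = 0.9, weight_decay = 1e-2)
  expect_false(identical(upd2$net$params$fc.w, net$params$fc.w))
  expect_identical(upd2$net$params$fc.b, net$params$fc.b)
})

test_that("one epoch produces a consistent history and lr trace", {
  ds <- generate_dataset(scene = small_scene(n_frames = 16L), n_per_class = 2,
                         seed = 31)
  net <- build_network(micro_spec(n_classes = 5L))
  cfg <- train_config(epochs = 1, warmup_epochs = 0, window_len = 16,
                      train_scale = 64, crop_size = 16, batch_size = 5,
                      seed = 2)
  res <- train(net, ds, ds, cfg)
  expect_equal(nrow(res$history), 1L)
  expect_named(res$history, c("epoch", "loss", "val_top1", "lr"))
  steps <- 10 %/% 5
  expect_equal(res$history$lr,
               lr_at(steps - 1, steps * 1, cfg$base_lr, 0))
})

test_that("training is reproducible and memorizes a two-clip dataset", {
  specs <- default_class_specs()[c("lying", "motoring")]
  ds <- generate_dataset(specs, scene = small_scene(n_frames = 16L),
                         n_per_class = 1, seed = 12)
  cfg <- train_config(epochs = 100, warmup_epochs = 2, window_len = 16,
                      train_scale = 64, crop_size = 32, batch_size = 2,
                      dropout = 0, seed = 5)
  net <- build_network(micro_spec(n_classes = 5L))
  r1 <- suppressWarnings(train(net, ds, ds, cfg))
  # 100 epochs x 1 step = 100 iterations < the 200-iteration budget
  expect_lt(min(r1$history$loss), 0.01)
  expect_equal(max(r1$history$val_top1), 1)
  r2 <- suppressWarnings(train(net, ds, ds, cfg))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$net$params$fc.w, r2$net$params$fc.w)
})

test_that("degenerate inputs are reported", {
  ds <- generate_dataset(default_class_specs()["lying"],
                         scene = small_scene(n_frames = 16L),
                         n_per_class = 2, seed = 4)
  net <- build_network(micro_spec(n_classes = 5L))
  cfg <- train_config(epochs = 1, window_len = 16, train_scale = 64,
                      crop_size = 16, batch_size = 2, seed = 1)
  expect_warning(train(net, ds, ds, cfg), "empty classes")
  bad <- ds
  bad$labels[1] <- "waltzing"
  expect_error(suppressWarnings(train(net, bad, ds, cfg)), "vocabulary")
})

test_that("checkpoints rebuild the exact network", {
  net <- init_weights(build_network(micro_spec()), 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, net$params)
  xs <- array(rnorm(3 * 2 * 16 * 16), c(3, 2, 16, 16, 1))
  xf <- array(rnorm(3 * 8 * 16 * 16), c(3, 8, 16, 16, 1))
  expect_identical(predict_logits(back, xs, xf), predict_logits(net, xs, xf))
})
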