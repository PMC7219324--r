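test_that("view-averaged prediction equals the brute-force mean-argmax oracle", {
  local_stub_method()
  set.seed(42)
  logits <- matrix(rnorm(5 * 30), 5, 30)
  stub <- make_stub(list(logits))
  vs <- test_views(tiny_clip(1), scale = 48, crop_size = 48, window_len = 16)
  pred <- predict_sample(stub, vs)
  # oracle: softmax each column, average, argmax
  sm <- apply(logits, 2, function(z) exp(z - max(z)) / sum(exp(z - max(z))))
  oracle_mean <- rowMeans(sm)
  expect_equal(unname(pred$mean_softmax), unname(oracle_mean), tolerance = 1e-12)
  expect_equal(pred$label_index, which.max(oracle_mean))
  expect_true(all(abs(rowSums(pred$view_softmax) - 1) < 1e-6))
})

test_that("the mean softmax is invariant to view order; ties break low", {
  local_stub_method()
  set.seed(9)
  logits <- matrix(rnorm(5 * 30), 5, 30)
  perm <- sample(30)
  vs <- test_views(tiny_clip(2), scale = 48, crop_size = 48, window_len = 16)
  p1 <- predict_sample(make_stub(list(logits)), vs)
  p2 <- predict_sample(make_stub(list(logits[, perm])), vs)
  expect_equal(sort(p1$mean_softmax), sort(p2$mean_softmax), tolerance = 1e-12)
  expect_equal(unname(p1$mean_softmax), unname(p2$mean_softmax), tolerance = 1e-12)
  expect_equal(p1$label_index, p2$label_index)
  # all-identical views collapse to the single-view softmax; exact ties take
  # the lowest class index
  same <- matrix(0, 5, 30)
  p3 <- predict_sample(make_stub(list(same)), vs)
  expect_equal(unname(p3$mean_softmax), rep(0.2, 5))
  expect_equal(p3$label_index, 1L)
})

test_that("a non-30-view set is a protocol error", {
  vs <- test_views(tiny_clip(3), scale = 48, crop_size = 48, window_len = 16,
                   n_temporal = 5L)
  expect_equal(vs$n_views, 15L)
  expect_error(predict_sample(make_stub(list(matrix(0, 5, 15))), vs),
               "30 views")
})

test_that("evaluate matches a hand tally on scripted view outputs", {
  local_stub_method()
  # 6 clips: feeding, lying, motoring, scratching, mounting, feeding.
  # Scripted so that samples 1-4 are classified correctly, 5 and 6 not;
  # within each sample k of 30 views vote for the scripted label.
  labels <- c("feeding", "lying", "motoring", "scratching", "mounting",
              "feeding")
  pred_class <- c(1L, 2L, 3L, 4L, 1L, 3L)   # sample-level scripted argmax
  views_for <- c(30L, 25L, 20L, 30L, 18L, 16L)  # views voting for pred_class
  truth_idx <- match(labels, behavior_classes())
  queue <- list()
  for (s in seq_len(6)) {
    m <- matrix(0, 5, 30)
    # runner-up class distinct from both prediction and truth, so only the
    # scripted votes can be correct
    other <- setdiff(1:5, c(pred_class[s], truth_idx[s]))[1]
    m[other, ] <- 2
    m[pred_class[s], seq_len(views_for[s])] <- 6
    queue[[s]] <- m
  }
  stub <- make_stub(queue)
  clips <- lapply(1:6, tiny_clip)
  rep <- evaluate(stub, list(clips = clips, labels = labels),
                  scale = 48, crop_size = 48, window_len = 16)
  # hand tally: 4 of 6 samples correct
  expect_equal(rep$top1_accuracy, 4 / 6, tolerance = 1e-12)
  # views: only views voting for the true class are correct
  correct_views <- sum(ifelse(pred_class == truth_idx, views_for, 0))
  expect_equal(rep$views_accuracy, correct_views / 180, tolerance = 1e-12)
  expect_equal(sum(rep$confusion), 6)
  expect_equal(unname(diag(rep$confusion)), c(1L, 1L, 1L, 1L, 0L))
  # report metrics agree with metrics_from_confusion exactly
  m2 <- metrics_from_confusion(rep$confusion)
  expect_identical(m2$top1, rep$top1_accuracy)
  expect_identical(m2$per_class_rate, rep$per_class_rate)
})

test_that("confusion metrics: identity, balance and validation guards", {
  id <- diag(5)
  m <- metrics_from_confusion(id)
  expect_equal(m$top1, 1)
  expect_equal(unname(m$per_class_rate), rep(1, 5))
  # constant single-class predictor on a balanced set
  cm <- matrix(0, 5, 5)
  cm[, 1] <- 10
  expect_equal(metrics_from_confusion(cm)$top1, 0.2)
  # zero rows are undefined, not zero
  z <- rbind(c(3, 1), c(0, 0))
  expect_true(is.na(metrics_from_confusion(z)$per_class_rate[2]))
  expect_error(metrics_from_confusion(matrix(-1, 2, 2)), "non-negative")
  expect_error(metrics_from_confusion(matrix(0, 2, 3)), "square")
})

test_that("evaluation reports serialize to JSON and CSV", {
  local_stub_method()
  stub <- make_stub(list(matrix(rep(c(5, 0, 0, 0, 0), 30), 5, 30)))
  rep <- evaluate(stub, list(clips = list(tiny_clip(4)), labels = "feeding"),
                  scale = 48, crop_size = 48, window_len = 16)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(rep, jp, cp)
  j <- jsonlite::read_json(jp)
  expect_equal(j$top1_accuracy, 1)
  expect_equal(unlist(j$confusion[[1]]), c(1L, rep(0L, 4)), ignore_attr = TRUE)
  expect_equal(nrow(read.csv(cp, row.names = 1)), 5L)
})
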