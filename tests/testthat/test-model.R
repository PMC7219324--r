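test_that("published variant specs carry the printed widths and depths", {
  s34 <- make_arch_spec("pmb-scn-34")
  expect_equal(vapply(s34$slow$stages, `[[`, integer(1), "channels"),
               c(128L, 256L, 512L, 1024L))
  expect_equal(vapply(s34$slow$stages, `[[`, integer(1), "n_blocks"),
               c(3L, 4L, 6L, 3L))
  expect_equal(vapply(s34$fast$stages, `[[`, integer(1), "channels"),
               c(16L, 32L, 64L, 128L))  # beta = 1/8 at every stage
  # temporal kernel rules: slow res2/res3 spatial-only, res4/res5 temporal
  expect_equal(vapply(s34$slow$stages, function(s) s$k1[1], integer(1)),
               c(1L, 1L, 3L, 3L))
  expect_true(all(vapply(s34$fast$stages, function(s) s$k1[1], integer(1)) == 3L))
  expect_true(all(vapply(c(s34$slow$stages, s34$fast$stages),
                         function(s) s$k2[1], integer(1)) == 1L))

  s18 <- make_arch_spec("pmb-scn-18")
  expect_equal(vapply(s18$slow$stages, `[[`, integer(1), "n_blocks"),
               rep(2L, 4))

  sh <- make_arch_spec("pmb-scn-34half")
  expect_equal(vapply(sh$slow$stages, `[[`, integer(1), "channels"),
               c(64L, 128L, 256L, 512L))
  expect_equal(sh$fast$stages[[1]]$channels, 8L)  # 64/8

  expect_error(make_arch_spec("pmb-scn-50"))
})

test_that("stage shapes agree with an independent stride-arithmetic oracle", {
  # oracle: walk the halving pyramid with plain floor arithmetic
  oracle <- function(hw) {
    out_len <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1
    v <- c(conv1 = out_len(hw, 7, 2, 3))
    v["pool1"] <- out_len(v["conv1"], 3, 2, 1)
    v["res2"] <- v[["pool1"]]
    v["res3"] <- out_len(v[["res2"]], 3, 2, 1)
    v["res4"] <- out_len(v[["res3"]], 3, 2, 1)
    v["res5"] <- out_len(v[["res4"]], 3, 2, 1)
    v
  }
  spec <- make_arch_spec("pmb-scn-34")
  for (hw in c(224L, 112L)) {
    tab <- stage_output_shapes(spec, hw)
    slow <- tab[tab$pathway == "slow" & tab$stage != "data", ]
    expect_equal(slow$h, unname(oracle(hw)[slow$stage]))
    expect_equal(slow$w, slow$h)
  }
  expect_equal(subset(stage_output_shapes(spec, 112),
                      pathway == "slow" & stage == "res5")$h, 4L)
  expect_error(stage_output_shapes(spec, 16L), "too small")
})

test_that("temporal lengths never change across stages", {
  tab <- stage_output_shapes(make_arch_spec("pmb-scn-18"), 224)
  expect_true(all(tab$t[tab$pathway == "slow"] == 8L))
  expect_true(all(tab$t[tab$pathway == "fast"] == 32L))
})

test_that("parameter accounting follows receptive-field arithmetic", {
  spec <- micro_spec()
  net <- build_network(spec)
  # fast res5 entry block holds a single 3x3x3 convolution mapping 4 -> 8
  # channels with no bias: 8 * 4 * 27 = 864 weights
  w <- net$params[["fast.res5.b1.conv1.w"]]
  expect_equal(dim(w), c(8L, 4L, 3L, 3L, 3L))
  expect_length(w, 864L)
  expect_equal(net$fan_in[["fast.res5.b1.conv1.w"]], 4 * 27)
  # classifier width = slow res5 + fast res5 channels
  expect_equal(dim(net$params$fc.w),
               c(spec$n_classes,
                 spec$slow$stages[[4]]$channels + spec$fast$stages[[4]]$channels))
})

test_that("halving channel widths quarters the parameter count", {
  c34 <- count_parameters(make_arch_spec("pmb-scn-34"))
  ch <- count_parameters(make_arch_spec("pmb-scn-34half"))
  c18 <- count_parameters(make_arch_spec("pmb-scn-18"))
  expect_gte(ch / c34, 0.24)
  expect_lte(ch / c34, 0.26)
  expect_lt(c18, c34)
  # count from a built network agrees with the spec-level count
  expect_equal(count_parameters(build_network(micro_spec())),
               count_parameters(micro_spec()))
})

test_that("evaluation-mode forward is deterministic and batch-independent", {
  spec <- micro_spec()
  net <- init_weights(build_network(spec), 42)
  set.seed(1)
  xs <- array(rnorm(3 * 2 * 16 * 16 * 4), c(3, 2, 16, 16, 4))
  xf <- array(rnorm(3 * 8 * 16 * 16 * 4), c(3, 8, 16, 16, 4))
  l4 <- predict_logits(net, xs, xf)
  expect_identical(l4, predict_logits(net, xs, xf))
  l1 <- predict_logits(net, xs[, , , , 2, drop = FALSE],
                       xf[, , , , 2, drop = FALSE])
  expect_equal(unname(l1[, 1]), unname(l4[, 2]), tolerance = 1e-12)
})

test_that("a zeroed classifier forces the uniform softmax", {
  net <- init_weights(build_network(micro_spec(n_classes = 5L)), 1)
  net$params$fc.w[] <- 0
  net$params$fc.b[] <- 0
  xs <- array(rnorm(3 * 2 * 16 * 16), c(3, 2, 16, 16, 1))
  xf <- array(rnorm(3 * 8 * 16 * 16), c(3, 8, 16, 16, 1))
  p <- pmbscn:::softmax_cols(predict_logits(net, xs, xf))
  expect_equal(unname(p[, 1]), rep(0.2, 5), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a micro network", {
  ns <- asNamespace("pmbscn")
  net <- init_weights(build_network(micro_spec()), 42)
  set.seed(7)
  xs <- array(rnorm(3 * 2 * 16 * 16 * 2), c(3, 2, 16, 16, 2))
  xf <- array(rnorm(3 * 8 * 16 * 16 * 2), c(3, 8, 16, 16, 2))
  labels <- c(1L, 3L)
  loss_fn <- function(nn) {
    fw <- ns$net_forward(nn, xs, xf, training = TRUE, dropout = 0)
    ns$softmax_ce(fw$logits, labels)$loss
  }
  fw <- ns$net_forward(net, xs, xf, training = TRUE, dropout = 0)
  ce <- ns$softmax_ce(fw$logits, labels)
  grads <- ns$net_backward(net, fw$cache, ce$dlogits)

  eps <- 1e-5
  set.seed(31)
  for (nm in sample(names(net$params), 8)) {
    for (j in sample(length(net$params[[nm]]), min(2L, length(net$params[[nm]])))) {
      np <- net
      np$params[[nm]][j] <- net$params[[nm]][j] + eps
      lp <- loss_fn(np)
      np$params[[nm]][j] <- net$params[[nm]][j] - eps
      lm <- loss_fn(np)
      num <- (lp - lm) / (2 * eps)
      expect_equal(grads[[nm]][j], num, tolerance = 1e-4,
                   label = paste("grad", nm, j))
    }
  }
})

test_that("every trainable parameter receives gradient (no dead branches)", {
  ns <- asNamespace("pmbscn")
  net <- init_weights(build_network(micro_spec()), 42)
  set.seed(8)
  xs <- array(rnorm(3 * 2 * 16 * 16 * 3), c(3, 2, 16, 16, 3))
  xf <- array(rnorm(3 * 8 * 16 * 16 * 3), c(3, 8, 16, 16, 3))
  fw <- ns$net_forward(net, xs, xf, training = TRUE, dropout = 0)
  ce <- ns$softmax_ce(fw$logits, c(1L, 2L, 3L))
  grads <- ns$net_backward(net, fw$cache, ce$dlogits)
  expect_setequal(names(grads), names(net$params))
  nz <- vapply(names(net$params), function(nm) any(grads[[nm]] != 0),
               logical(1))
  expect_true(all(nz), label = "all parameters reached by gradient")
})

test_that("architecture specs survive a YAML round trip", {
  spec <- make_arch_spec("pmb-scn-18", fusion = "project_sum")
  path <- withr::local_tempfile(fileext = ".yaml")
  arch_to_yaml(spec, path)
  back <- arch_from_yaml(path)
  expect_equal(back, spec)
  expect_equal(count_parameters(back), count_parameters(spec))
})

test_that("project_sum fusion preserves the slow tensor shape and runs", {
  spec <- make_arch_spec("pmb-scn-34", fusion = "project_sum",
                         width_divisor = 16, block_counts = c(1, 1, 1, 1),
                         slow_len = 2, fast_len = 8)
  net <- init_weights(build_network(spec), 4)
  xs <- array(rnorm(3 * 2 * 16 * 16), c(3, 2, 16, 16, 1))
  xf <- array(rnorm(3 * 8 * 16 * 16), c(3, 8, 16, 16, 1))
  logits <- predict_logits(net, xs, xf)
  expect_equal(dim(logits), c(5L, 1L))
})
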