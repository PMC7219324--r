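test_that("AVI round-trip is lossless and preserves fps and duration", {
  clip <- generate_clip(default_class_specs()$motoring, small_scene(seed = 5))
  expect_equal(n_frames(clip), 32L)
  path <- withr::local_tempfile(fileext = ".avi")
  write_clip(clip, path)
  back <- read_clip(path)
  expect_identical(back$frames, clip$frames)
  expect_equal(back$fps, 25)
  # container duration within one frame of n/fps
  expect_lt(abs(n_frames(back) / back$fps - 32 / 25), 1 / 25)

  one <- frame_sequence(array(7L, c(40, 48, 3, 1)), 25)
  p1 <- withr::local_tempfile(fileext = ".avi")
  write_clip(one, p1)
  expect_equal(n_frames(read_clip(p1)), 1L)
})

test_that("64-frame clip at 25 fps has 2.56 s container duration", {
  clip <- generate_clip(default_class_specs()$lying,
                        small_scene(n_frames = 64L, seed = 2))
  path <- withr::local_tempfile(fileext = ".avi")
  write_clip(clip, path)
  back <- read_clip(path)
  expect_equal(n_frames(back) / back$fps, 2.56, tolerance = 1e-12)
})

test_that("PNG frame directories round-trip with count and pixels preserved", {
  clip <- generate_clip(default_class_specs()$feeding,
                        small_scene(n_frames = 50L, seed = 9))
  d <- withr::local_tempdir()
  write_clip(clip, d)
  expect_length(list.files(d, pattern = "\\.png$"), 50L)
  back <- read_clip(d, fps = 25)
  expect_equal(n_frames(back), 50L)
  expect_identical(back$frames, clip$frames)
  expect_equal(back$fps, 25)
  expect_error(read_clip(withr::local_tempdir()), "empty")
})

test_that("manifest summary counts classes and durations", {
  m <- toy_manifest(2)  # 10 clips, 64 frames @ 25 fps
  s <- summarize_manifest(m)
  expect_equal(unname(s$class_counts), rep(2L, 5))
  expect_equal(s$total_duration_s, 10 * 64 / 25, tolerance = 1e-9)
  expect_equal(s$total_duration_s, sum(m$duration_s), tolerance = 1e-9)

  m1 <- m[m$label == "lying", ]
  s1 <- summarize_manifest(m1)
  expect_equal(unname(s1$class_counts),
               ifelse(behavior_classes() == "lying", 2L, 0L))

  big <- toy_manifest(200)
  expect_equal(unname(summarize_manifest(big)$class_counts), rep(200L, 5))

  bad <- m
  bad$label[1] <- "sleeping"
  expect_error(summarize_manifest(bad), "unknown label")
})

test_that("stratified 4:1:1 split reproduces the printed subset sizes", {
  # per-class counts 158/157/158/158/158 (789 rows total)
  per <- c(feeding = 158, lying = 157, motoring = 158, scratching = 158,
           mounting = 158)
  cls <- rep(names(per), times = per)
  m <- manifest(sprintf("clip_%04d", seq_along(cls)), cls, 64L, 25)
  parts <- stratified_split(m, c(4, 1, 1), seed = 3)
  expect_equal(vapply(parts, nrow, integer(1)), c(529L, 130L, 130L))
})

test_that("stratified split is an exact, seed-deterministic partition", {
  m <- toy_manifest(13)
  single <- stratified_split(m, 1, seed = 1)
  expect_equal(sort(single[[1]]$clip_path), sort(m$clip_path))

  a <- stratified_split(m, c(4, 1, 1), seed = 11)
  b <- stratified_split(m, c(4, 1, 1), seed = 11)
  c_ <- stratified_split(m, c(4, 1, 1), seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c_))
  expect_equal(vapply(c_, nrow, integer(1)), vapply(a, nrow, integer(1)))

  all_paths <- unlist(lapply(a, `[[`, "clip_path"))
  expect_equal(sort(all_paths), sort(m$clip_path))     # union = input
  expect_equal(anyDuplicated(all_paths), 0L)           # disjoint
  # per-class proportions honored up to rounding
  for (p in a) expect_true(all(abs(table(p$label) / 13 -
                                     nrow(p) / nrow(m)) < 0.1))

  expect_error(stratified_split(toy_manifest(2), c(4, 1, 1)), "at least")
})

test_that("arbitrary-size random split partitions exactly", {
  m <- toy_manifest(40)  # 200 rows
  parts <- split_manifest(m, c(42, 158), seed = 7)
  expect_equal(vapply(parts, nrow, integer(1)), c(42L, 158L))
  all_paths <- unlist(lapply(parts, `[[`, "clip_path"))
  expect_equal(sort(all_paths), sort(m$clip_path))
  expect_identical(split_manifest(m, c(42, 158), seed = 7), parts)
})

test_that("manifests survive a CSV round trip", {
  m <- toy_manifest(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(m, path)
  expect_equal(read_manifest(path), m)
})
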