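# luminance-threshold centroid of the body in a rendered frame
body_centroid <- function(frame) {
  mask <- frame[, , 1] > 0.62
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2]), y = mean(idx[, 1]))
}

test_that("uniform frame sampling follows floor(k*T/L)", {
  expect_identical(sample_frames(100, 20, "uniform"),
                   as.integer(seq(0, 95, by = 5)))
  expect_identical(sample_frames(7, 3, "uniform"), c(0L, 2L, 4L))
  expect_identical(sample_frames(5, 5, "uniform"), 0:4)
})

test_that("random frame sampling is sorted, in range, seeded", {
  expect_identical(sample_frames(10, 10, "random", seed = 1), 0:9)  # exhaustive
  a <- sample_frames(50, 8, "random", seed = 42)
  b <- sample_frames(50, 8, "random", seed = 42)
  expect_identical(a, b)
  expect_false(is.unsorted(a))
  expect_true(all(a >= 0 & a < 50))
  expect_identical(anyDuplicated(a), 0L)
  # with replacement only when too few frames
  cc <- sample_frames(3, 5, "random", seed = 7)
  expect_length(cc, 5)
  expect_true(all(cc >= 0 & cc < 3))
  expect_error(sample_frames(0, 5), "non-positive")
  expect_error(sample_frames(5, 0), "non-positive")
})

test_that("synthetic videos are bitwise deterministic in their seed", {
  cfg <- synthetic_config(image_size = 24L, frames_per_video = 6L)
  for (cl in BEHAVIOR_CLASSES) {
    v1 <- generate_synthetic_video(cl, cfg, seed = 5)
    v2 <- generate_synthetic_video(cl, cfg, seed = 5)
    expect_identical(v1$frames, v2$frames)
    expect_identical(v1$label, cl)
    expect_equal(v1$fps, 25)
    expect_length(v1$frames, 6L)
    expect_true(all(vapply(v1$frames, function(f)
      all(f >= 0 & f <= 1 & is.finite(f)), logical(1))))
  }
  expect_error(generate_synthetic_video("Grazing", cfg, 1), "unknown label")
})

test_that("walking translates while standing stays put", {
  cfg <- synthetic_config(image_size = 32L, frames_per_video = 20L,
                          noise_sd = 0, motion_amplitude = 0.35)
  w <- generate_synthetic_video("Walking", cfg, seed = 9)
  s <- generate_synthetic_video("Standing", cfg, seed = 9)
  cw <- sapply(w$frames, body_centroid)
  cs <- sapply(s$frames, body_centroid)
  disp_w <- sqrt(sum((cw[, 20] - cw[, 1])^2))
  disp_s <- sqrt(sum((cs[, 20] - cs[, 1])^2))
  expect_gte(disp_w, 0.35 * 19 * 0.9)   # straight-line travel
  expect_equal(disp_s, 0)
  # the body never leaves the frame
  expect_true(all(cw >= 1 & cw <= 32))
})

test_that("walking and standing differ only temporally", {
  # amplitude 0, no noise: frame-wise identical videos
  cfg0 <- synthetic_config(image_size = 24L, frames_per_video = 8L,
                           noise_sd = 0, motion_amplitude = 0)
  w <- generate_synthetic_video("Walking", cfg0, seed = 3)
  s <- generate_synthetic_video("Standing", cfg0, seed = 3)
  expect_identical(w$frames, s$frames)
  # with noise the equality still holds (same noise stream)
  cfgn <- synthetic_config(image_size = 24L, frames_per_video = 4L,
                           noise_sd = 0.05, motion_amplitude = 0)
  wn <- generate_synthetic_video("Walking", cfgn, seed = 3)
  sn <- generate_synthetic_video("Standing", cfgn, seed = 3)
  expect_identical(wn$frames[[1]], sn$frames[[1]])
})

test_that("datasets split 8:2, stratified, without leakage", {
  cfg <- synthetic_config(image_size = 16L, videos_per_class = 10L,
                          frames_per_video = 4L, seed = 77)
  ds <- make_dataset(cfg)
  expect_length(ds$train, 40L)
  expect_length(ds$test, 10L)
  tr_labs <- table(vapply(ds$train, function(v) v$label, character(1)))
  te_labs <- table(vapply(ds$test, function(v) v$label, character(1)))
  expect_true(all(tr_labs == 8L))
  expect_true(all(te_labs == 2L))
  ids <- c(vapply(ds$train, function(v) v$source_id, character(1)),
           vapply(ds$test, function(v) v$source_id, character(1)))
  expect_identical(anyDuplicated(ids), 0L)          # partition, no leakage
  ds2 <- make_dataset(cfg)
  expect_identical(vapply(ds2$train, function(v) v$source_id, character(1)),
                   vapply(ds$train, function(v) v$source_id, character(1)))
  expect_error(make_dataset(synthetic_config(videos_per_class = 4L)), ">= 5")
})

test_that("frame directories round-trip through export and load", {
  cfg <- synthetic_config(image_size = 16L, videos_per_class = 5L,
                          frames_per_video = 3L, seed = 5)
  vids <- list(generate_synthetic_video("Lying", cfg, 1),
               generate_synthetic_video("Eating", cfg, 2))
  dir <- withr::local_tempdir()
  mp <- export_dataset(vids, dir)
  man <- read_manifest(mp)
  expect_identical(man$label, c("Lying", "Eating"))
  vs <- load_video_frames(man$path[1], man$label[1], input_size = 16L)
  expect_length(vs$frames, 3L)
  expect_identical(dim(vs$frames[[1]]), c(16L, 16L, 3L))
  # PNG stores 8-bit values; round-trip is exact to 1/255
  expect_equal(vs$frames[[2]], vids[[1]]$frames[[2]], tolerance = 1 / 254)
  # resizing to another square size
  vs2 <- load_video_frames(man$path[1], man$label[1], input_size = 8L)
  expect_identical(dim(vs2$frames[[1]]), c(8L, 8L, 3L))
  # empty/missing directories error with the path in the message
  empty <- file.path(dir, "empty"); dir.create(empty)
  expect_error(load_video_frames(empty, "Lying"), "no readable frames")
  expect_error(load_video_frames(file.path(dir, "nope"), "Lying"), "nope")
})
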