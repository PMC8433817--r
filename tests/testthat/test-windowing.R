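# brute-force slicer used as oracle for window construction
brute_force_windows <- function(Fm, L) {
  N <- nrow(Fm) - L + 1
  lapply(seq_len(N), function(i) Fm[i:(i + L - 1), , drop = FALSE])
}

test_that("window slicing matches a brute-force slicer and centers targets", {
  sim <- synth_walk(tiny_synth_config(seed = 4, n_steps = 3))
  fs <- build_feature_set(clean_recording(sim$paired), "left")
  labels <- truth_labels(sim, "left")
  L <- 251
  wt <- make_windows(fs, labels, "MidS", L)
  n <- fs$n_frames
  expect_equal(nrow(wt$windows), n - L + 1)
  expect_equal(wt$center_offset, 125L)
  expect_equal(wt$source_frames, 125L + 0:(n - L))

  Fm <- feature_matrix(fs)
  oracle <- brute_force_windows(Fm, L)
  for (i in c(1, 57, length(oracle))) {
    expect_equal(wt$windows[i, , ], unname(oracle[[i]]))
  }
  # targets equal the label channel at each window's center frame
  expect_equal(wt$targets, labels$mids[wt$source_frames + 1L])
  # positive conservation: number of in-range truth events
  truth_mids <- sim$steps$mids[sim$steps$side == "left" & sim$steps$valid]
  in_range <- sum(truth_mids >= 125 & truth_mids <= n - 126)
  expect_equal(sum(wt$targets), in_range)
})

test_that("a 251-frame series yields exactly one window centered at frame 125", {
  fs <- manual_feature_set(seq_len(251) / 251)
  labels <- manual_labels(fo = 10, mids = 125, fc = 240, n = 251)
  wt <- make_windows(fs, labels, "MidS")
  expect_equal(nrow(wt$windows), 1)
  expect_equal(wt$source_frames, 125L)
  expect_equal(wt$targets, 1L)
  # 300 frames -> 50 windows
  fs300 <- manual_feature_set(stats::runif(300))
  expect_equal(nrow(make_windows(fs300, NULL, "FO")$windows), 50)
  expect_error(make_windows(manual_feature_set(stats::runif(250)), NULL, "FO"),
               "too short")
})

test_that("events near the series edges can never be positive targets", {
  n <- 300
  fs <- manual_feature_set(stats::runif(n))
  labels <- manual_labels(fo = 50, mids = 150, fc = 280, n = n)  # 50/280 out of range
  expect_equal(sum(make_windows(fs, labels, "FO")$targets), 0)
  expect_equal(sum(make_windows(fs, labels, "FC")$targets), 0)
  expect_equal(sum(make_windows(fs, labels, "MidS")$targets), 1)
})

test_that("balancing strategies keep positives and are deterministic", {
  n <- 2000
  fs <- manual_feature_set(stats::runif(n))
  mids <- as.integer(seq(200, 1700, length.out = 10))
  labels <- manual_labels(fo = mids - 30, mids = mids, fc = mids + 35, n = n)
  wt <- make_windows(fs, labels, "MidS")
  expect_identical(balance_windows(wt, "none"), wt)

  b <- balance_windows(wt, "undersample", ratio = 5, seed = 3)
  expect_equal(sum(b$targets == 1), 10)
  expect_equal(sum(b$targets == 0), 50)
  b2 <- balance_windows(wt, "undersample", ratio = 5, seed = 3)
  expect_identical(b$source_frames, b2$source_frames)
  expect_false(identical(
    balance_windows(wt, "undersample", ratio = 5, seed = 4)$source_frames,
    b$source_frames))

  d <- balance_windows(wt, "target_dilation", ratio = 5, dilation_frames = 2,
                       seed = 3)
  expect_equal(sum(d$targets == 1), 50)  # each event widened to 5 positives
  expect_error(balance_windows(wt, "bogus"), "arg")
})

test_that("recording-level splits are disjoint, conserving and seeded", {
  tensors <- lapply(1:4, function(s) {
    fs <- manual_feature_set(stats::runif(300))
    make_windows(fs, manual_labels(130, 150, 170, 300), "MidS")
  })
  names(tensors) <- paste0("rec", 1:4)
  sp <- split_by_recording(tensors, val_fraction = 0.25, seed = 2)
  expect_length(sp$validation_keys, 1)
  expect_length(intersect(sp$train_keys, sp$validation_keys), 0)
  expect_equal(nrow(sp$train$windows) + nrow(sp$validation$windows), 4 * 50)
  sp2 <- split_by_recording(tensors, val_fraction = 0.25, seed = 2)
  expect_identical(sp$validation_keys, sp2$validation_keys)
  expect_error(split_by_recording(tensors[1]), "at least 2")
})

test_that("window tensors survive a save/load round trip with metadata", {
  fs <- manual_feature_set(stats::runif(300))
  wt <- make_windows(fs, manual_labels(130, 150, 170, 300), "FO")
  dir <- withr::local_tempdir()
  write_window_tensor(wt, dir, extra = list(strategy = "none", seed = 1))
  back <- read_window_tensor(dir)
  expect_equal(back$windows, wt$windows)
  expect_identical(back$targets, wt$targets)
  expect_identical(back$source_frames, wt$source_frames)
  expect_equal(back$phase, "FO")
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$strategy, "none")
  expect_equal(meta$L, 251)
})
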