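test_that("a single-bout simulation emits the configured step counts", {
  sim <- synth_walk(tiny_synth_config(seed = 2, n_steps = 6))
  for (side in c("left", "right")) {
    st <- sim$steps[sim$steps$side == side, ]
    expect_equal(nrow(st), 6)
    expect_equal(st$step_type, c("initial", rep("steady", 4), "terminal"))
    expect_true(all(st$valid))
  }
  expect_equal(nrow(sim$turning_truth), 0)
  ev <- sim$truth
  expect_equal(sum(ev$phase == "FO"), 12)
  expect_equal(sum(ev$phase == "MidS"), 12)
  expect_equal(sum(ev$phase == "FC"), 12)
})

test_that("the same seed reproduces the recording bit for bit", {
  cfg <- tiny_synth_config(seed = 77, n_steps = 4)
  a <- synth_walk(cfg)
  b <- synth_walk(cfg)
  expect_identical(a$paired$left$gyr, b$paired$left$gyr)
  expect_identical(a$paired$right$free_acc, b$paired$right$free_acc)
  expect_identical(a$paired$left$rot_mat_11, b$paired$left$rot_mat_11)
  expect_identical(a$truth, b$truth)
  c2 <- synth_walk(tiny_synth_config(seed = 78, n_steps = 4))
  expect_false(identical(a$paired$left$gyr, c2$paired$left$gyr))
})

test_that("noise-free output is recovered by the labeler within 2 frames", {
  sim <- synth_walk(synth_config(seed = 1,
                                 noise_sd = list(gyr = 0, acc = 0, rot = 0)))
  res <- suppressMessages(run_label(sim$paired))
  for (side in c("left", "right")) {
    truth <- sim$steps[sim$steps$side == side & sim$steps$valid, ]
    lab <- res[[side]]$steps
    lab <- lab[lab$valid, ]
    for (ph in c("fo", "mids", "fc"))
      expect_true(all(nearest_dist(truth[[ph]], lab[[ph]]) <= 2))
  }
})

test_that("each noise-free steady step shows exactly 3 prominent peaks", {
  sim <- synth_walk(tiny_synth_config(seed = 3, n_steps = 5,
                                      noise_sd = list(gyr = 0, acc = 0, rot = 0)))
  rec <- sim$paired$left
  avm <- ang_vel_mag(rec$gyr[, 1], rec$gyr[, 2], rec$gyr[, 3])
  lm <- gaitphase:::local_maxima(avm) - 1L
  steady <- sim$steps[sim$steps$side == "left" &
                        sim$steps$step_type == "steady", ]
  half_amp <- sim$config$step_templates$steady[["mids"]] / 2
  for (i in seq_len(nrow(steady))) {
    inside <- lm[lm >= steady$fo[i] - 10 & lm <= steady$fc[i] + 10]
    expect_equal(sum(avm[inside + 1L] > half_amp), 3)
  }
})

test_that("turning steps exist, are invalid, and stay inside truth intervals", {
  sim <- synth_walk(synth_config(seed = 5))
  turn_steps <- sim$steps[!sim$steps$valid, ]
  expect_gt(nrow(turn_steps), 0)
  tt <- sim$turning_truth
  expect_equal(nrow(tt), 2)
  for (i in seq_len(nrow(turn_steps))) {
    expect_true(any(turn_steps$fo[i] >= tt$start & turn_steps$fc[i] <= tt$end))
  }
  # straight-bout steps never overlap turning truth
  straight <- sim$steps[sim$steps$valid, ]
  for (i in seq_len(nrow(tt)))
    expect_false(any(straight$fo <= tt$end[i] & straight$fc >= tt$start[i]))
})

test_that("in-place stepping is generated and marked invalid", {
  cfg <- tiny_synth_config(seed = 9, n_steps = 4,
                           in_place_segments = list(list(after_bout = 1,
                                                         n_steps = 3)))
  sim <- synth_walk(cfg)
  ip <- sim$steps[!sim$steps$valid, ]
  expect_equal(nrow(ip), 6)  # 3 steps per leg
  expect_equal(nrow(sim$turning_truth), 0)
})

test_that("infeasible cadences are rejected", {
  expect_error(synth_config(cadence_steps_per_s = 1.6), "overlap")
  expect_error(synth_config(step_templates = list(
    initial = c(fo = 175, mids = 400, fc = 230),
    steady = c(fo = 450, mids = 400, fc = 230),
    terminal = c(fo = 250, mids = 400, fc = 69))), "exceed")
})

test_that("training sets conserve window and positive counts", {
  cfgs <- list(tiny_synth_config(seed = 21, n_steps = 3),
               tiny_synth_config(seed = 22, n_steps = 3))
  ts <- synth_training_set(cfgs, "MidS", strategy = "none")
  expect_length(ts$per_recording, 4)  # 2 simulations x 2 legs
  for (key in names(ts$per_recording)) {
    wt <- ts$per_recording[[key]]
    ci <- as.integer(sub("sim(\\d+)_.*", "\\1", key))
    side <- sub(".*_", "", key)
    sim <- synth_walk(cfgs[[ci]])
    n <- sim$paired$left$n_frames
    expect_equal(nrow(wt$windows), n - 250)
    truth <- sim$steps[sim$steps$side == side & sim$steps$valid, ]
    in_range <- sum(truth$mids >= 125 & truth$mids <= n - 126)
    expect_equal(sum(wt$targets), in_range)
  }
  expect_equal(nrow(ts$combined$windows),
               sum(vapply(ts$per_recording,
                          function(w) nrow(w$windows), numeric(1))))

  # balanced at 5:1 without dilation: negatives = 5 x positives
  tsb <- synth_training_set(cfgs, "MidS", strategy = "undersample", ratio = 5)
  expect_equal(sum(tsb$combined$targets == 0), 5 * sum(tsb$combined$targets == 1))
})
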