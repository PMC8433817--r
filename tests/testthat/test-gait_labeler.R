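test_that("mid-swing detection ignores flat signals and is amplitude-relative", {
  expect_length(detect_mids(rep(3, 500)), 0)
  sim <- synth_walk(tiny_synth_config(seed = 1, n_steps = 2,
                                      noise_sd = list(gyr = 0, acc = 0, rot = 0)))
  fs <- build_feature_set(clean_recording(sim$paired), "left")
  truth <- sim$steps[sim$steps$side == "left", ]
  m <- detect_mids(fs$ang_vel_mag)
  expect_length(m, 2)
  expect_true(all(nearest_dist(truth$mids, m) <= 2))
  # doubling the amplitude must not change the detected frames
  expect_identical(detect_mids(2 * fs$ang_vel_mag), m)
})

test_that("flank detection recovers foot-off and foot-contact from truth", {
  for (noise in list(list(gyr = 0, acc = 0, rot = 0),
                     list(gyr = 10, acc = 0.3, rot = 0.005))) {
    sim <- synth_walk(tiny_synth_config(seed = 5, n_steps = 6,
                                        noise_sd = noise))
    fs <- build_feature_set(clean_recording(sim$paired), "left")
    truth <- sim$steps[sim$steps$side == "left", ]
    steps <- detect_fo_fc(fs$ang_vel_mag, detect_mids(fs$ang_vel_mag))
    expect_equal(nrow(steps), 6)
    tol <- if (noise$gyr == 0) 2 else 3
    expect_true(all(nearest_dist(truth$fo, steps$fo) <= tol))
    expect_true(all(nearest_dist(truth$fc, steps$fc) <= tol))
    expect_true(all(steps$fo < steps$mids & steps$mids < steps$fc))
  }
})

test_that("an initial step's reduced foot-off flank is still found", {
  sim <- synth_walk(tiny_synth_config(seed = 2, n_steps = 5,
                                      noise_sd = list(gyr = 0, acc = 0, rot = 0)))
  fs <- build_feature_set(clean_recording(sim$paired), "left")
  truth <- sim$steps[sim$steps$side == "left", ]
  steps <- detect_fo_fc(fs$ang_vel_mag, detect_mids(fs$ang_vel_mag))
  first <- truth[truth$step_type == "initial", ]
  expect_true(min(abs(steps$fo - first$fo)) <= 2)
})

test_that("a mid-swing peak with no flank inside the window is dropped", {
  # single swing bump at the very start: no left flank exists
  x <- smooth_gaussian(add <- replace(numeric(400), 11, 1), 9) * 400
  expect_message(steps <- detect_fo_fc(x, detect_mids(x)), "dropping")
  expect_equal(nrow(steps), 0)
})

test_that("turning detection flags heading sweeps and not constants", {
  expect_equal(nrow(detect_turning(rep(sqrt(2), 1000))), 0)

  # r11 sweeping 0.9 -> -0.9 over 2 s on both legs
  fs_hz <- 100
  r11 <- c(rep(0.9, 800), seq(0.9, -0.9, length.out = 200), rep(-0.9, 800))
  sig <- smooth_gaussian(rot_mat_mag(r11, r11), 9)
  iv <- detect_turning(sig)
  expect_equal(nrow(iv), 1)
  covered <- max(0, min(iv$end[1], 999) - max(iv$start[1], 800) + 1)
  expect_gte(covered / 200, 0.8)

  # a three-bout protocol has two separated turns -> two disjoint intervals
  sim <- synth_walk(synth_config(seed = 6))
  fs <- build_feature_set(clean_recording(sim$paired), "left")
  iv2 <- detect_turning(fs$rot_mat_mag)
  expect_equal(nrow(iv2), 2)
  expect_true(iv2$end[1] < iv2$start[2])
  # each detected interval overlaps its truth interval
  tt <- sim$turning_truth
  for (i in 1:2)
    expect_true(iv2$start[i] <= tt$end[i] && iv2$end[i] >= tt$start[i])
})

test_that("step types follow the rest-gap definition", {
  mk <- function(fo) data.frame(fo = fo, mids = fo + 30, fc = fo + 65)
  # one 6-step bout at 1 step/s
  bout <- mk(seq(0, 500, by = 100))
  types <- classify_step_type(bout)$step_type
  expect_equal(types, c("initial", rep("steady", 4), "terminal"))
  # two bouts separated by 3 s of rest
  two <- mk(c(0, 100, 200, 600, 700, 800))
  types2 <- classify_step_type(two)$step_type
  expect_equal(types2, c("initial", "steady", "terminal",
                         "initial", "steady", "terminal"))
  # a lone step is both initial and terminal -> terminal
  expect_equal(classify_step_type(mk(0))$step_type, "terminal")
})

test_that("steps touching a turning interval become invalid", {
  steps <- data.frame(fo = c(100, 300, 500), mids = c(130, 330, 530),
                      fc = c(165, 365, 565))
  turning <- data.frame(start = 320, end = 340)  # hits the 2nd step's mid-swing
  v <- validate_steps(steps, turning)$valid
  expect_equal(v, c(TRUE, FALSE, TRUE))
  expect_true(all(validate_steps(steps,
                                 data.frame(start = integer(0),
                                            end = integer(0)))$valid))
})

test_that("label channels are binary, balanced across phases, and bounded", {
  steps <- data.frame(fo = c(100, 300), mids = c(130, 330),
                      fc = c(165, 365), valid = c(TRUE, TRUE))
  ch <- make_label_channels(steps, 400)
  expect_equal(sum(ch$fo), 2)
  expect_equal(sum(ch$mids), 2)
  expect_equal(sum(ch$fc), 2)
  expect_true(all(unlist(ch[c("fo", "mids", "fc")]) %in% 0:1))
  steps$valid <- FALSE
  expect_equal(sum(unlist(make_label_channels(steps, 400)[1:3])), 0)
  expect_error(make_label_channels(data.frame(fo = 1, mids = 2, fc = 500,
                                              valid = TRUE), 400),
               "outside")
})

test_that("the full labeler recovers simulated ground truth at default noise", {
  hits3 <- hits5 <- tot_m <- tot_f <- 0
  for (seed in 1:3) {
    sim <- synth_walk(synth_config(seed = seed))
    res <- suppressMessages(run_label(sim$paired))
    for (side in c("left", "right")) {
      truth <- sim$steps[sim$steps$side == side & sim$steps$valid, ]
      lab <- res[[side]]$steps
      lab <- lab[lab$valid, ]
      hits3 <- hits3 + sum(nearest_dist(truth$mids, lab$mids) <= 3)
      hits5 <- hits5 + sum(nearest_dist(truth$fo, lab$fo) <= 5) +
        sum(nearest_dist(truth$fc, lab$fc) <= 5)
      tot_m <- tot_m + nrow(truth)
      tot_f <- tot_f + 2 * nrow(truth)
      # every labeled event ordering holds
      expect_true(all(lab$fo < lab$mids & lab$mids < lab$fc))
      # no valid labeled event inside a truth turning interval
      ev <- res[[side]]$events
      ev <- ev[ev$valid, ]
      tt <- sim$turning_truth
      inside <- vapply(ev$frame, function(f)
        any(f >= tt$start & f <= tt$end), logical(1))
      expect_equal(sum(inside), 0)
    }
  }
  expect_gte(hits3 / tot_m, 0.95)
  expect_gte(hits5 / tot_f, 0.90)
})
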