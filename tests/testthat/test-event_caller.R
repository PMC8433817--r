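test_that("event calling finds peak frames and respects the threshold", {
  n <- 900
  p <- rep(0.01, n)
  expect_equal(nrow(call_events(manual_trace(p))), 0)

  # one pulse with interior maximum at (0-based) frame 400
  p[200:350] <- 0.2 + 0.5 * exp(-((200:350) - 276)^2 / 200)
  tr <- manual_trace(p, first_center = 125)
  ev <- call_events(tr, caller_config(probability_threshold = 0.5))
  expect_equal(ev$frame, 400L)  # 276th value -> frame 125 + 275
  expect_true(all(ev$prob >= 0.5))
})

test_that("peaks closer than the separation merge to the higher one", {
  p <- rep(0.05, 500)
  p[200] <- 0.8
  p[210] <- 0.9  # 10 frames apart, min separation 40
  ev <- call_events(manual_trace(p), caller_config())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$frame, 125L + 209L)
  expect_equal(ev$prob, 0.9)
})

test_that("raising the threshold never increases the number of events", {
  with_seed <- getFromNamespace("with_seed", "gaitphase")
  p <- with_seed(8, {
    base <- rep(0.02, 2000)
    for (c0 in seq(150, 1850, by = 120))
      base <- base + stats::runif(1, 0.3, 0.95) * exp(-(seq_len(2000) - c0)^2 / 60)
    pmin(base + stats::runif(2000, 0, 0.03), 0.999)
  })
  tr <- manual_trace(p)
  counts <- vapply(seq(0.05, 0.95, by = 0.05), function(th)
    nrow(call_events(tr, caller_config(probability_threshold = th))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("refinement snaps to the nearby raw peak and is bounded", {
  raw <- rep(5, 600)
  raw[401] <- 80; raw[400] <- 60; raw[402] <- 60  # peak at frame 400
  ev <- gait_events(392L, "FO", "left", TRUE)     # 8 frames left of the peak
  cfg <- caller_config(refine_window_s = 0.3)
  ref <- refine_on_signal(ev, raw, cfg)
  expect_equal(ref$frame, 400L)
  # an event already on the peak stays put
  expect_equal(refine_on_signal(gait_events(400L, "FO", "left", TRUE),
                                raw, cfg)$frame, 400L)
  # never moves farther than the window
  with_seed <- getFromNamespace("with_seed", "gaitphase")
  noisy <- with_seed(2, stats::runif(600, 0, 100))
  ev2 <- gait_events(c(100L, 300L, 500L), rep("FO", 3), "left", TRUE)
  moved <- refine_on_signal(ev2, noisy, cfg)
  expect_true(all(abs(sort(moved$frame) - sort(ev2$frame)) <= 30))
})

test_that("event evaluation scores identity and disjoint cases exactly", {
  ev <- data.frame(frame = c(100L, 200L, 300L))
  r <- evaluate_events(ev, ev, 5)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 1)
  expect_equal(r$mean_abs_timing_error_frames, 0)

  shifted <- data.frame(frame = ev$frame + 6L)  # tolerance + 1
  r2 <- evaluate_events(shifted, ev, 5)
  expect_equal(r2$precision, 0)
  expect_equal(r2$recall, 0)
})

test_that("matches are one-to-one", {
  truth <- data.frame(frame = c(100L, 130L))
  pred <- data.frame(frame = c(101L, 102L, 131L))
  r <- evaluate_events(pred, truth, 5)
  expect_equal(r$n_matched, 2)
  expect_equal(anyDuplicated(r$matches$truth_frame), 0)
  expect_equal(anyDuplicated(r$matches$predicted_frame), 0)
  expect_equal(r$matches$predicted_frame[r$matches$truth_frame == 100], 101)
})

test_that("greedy matching equals the exhaustive optimal matcher", {
  # all sizes up to 6 x 6; truth events separated by more than twice the
  # tolerance, as the caller's separation merge guarantees in practice
  tol <- 5
  with_seed <- getFromNamespace("with_seed", "gaitphase")
  with_seed(31, {
    for (rep in 1:200) {
      nt <- sample(0:6, 1); np <- sample(0:6, 1)
      truth <- sort(sample(seq(0, 3000, by = 2 * tol + 1), nt))
      pred <- sort(unique(c(
        truth[seq_len(min(nt, np))] + sample(-7:7, min(nt, np), replace = TRUE),
        sample(0:3000, max(0, np - nt)))))
      r <- evaluate_events(data.frame(frame = pred),
                           data.frame(frame = truth), tol)
      expect_equal(r$n_matched, optimal_match_count(truth, pred, tol))
    }
  })
})
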