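# small architecture + short windows keep these tests fast; the full-size
# profile differs only in layer widths and sequence length
tiny_spec <- function(seq_len = 31)
  model_spec(input_units = 3, hidden_units = c(4, 4, 4),
             final_recurrent_units = 3, seq_len = seq_len)

# hand-built separable window set: positives carry a bump at the center
separable_windows <- function(n_pos = 12, n_neg = 24, L = 31, seed = 5) {
  with_seed <- getFromNamespace("with_seed", "gaitphase")
  with_seed(seed, {
    arr <- array(stats::runif((n_pos + n_neg) * L * 3, 0, 0.05),
                 dim = c(n_pos + n_neg, L, 3))
    bump <- 0.9 * exp(-((1:L) - (L + 1) / 2)^2 / 18)
    for (i in seq_len(n_pos)) arr[i, , 1] <- arr[i, , 1] + bump
    structure(list(windows = arr,
                   targets = c(rep(1L, n_pos), rep(0L, n_neg)),
                   source_frames = seq_len(n_pos + n_neg),
                   phase = "MidS", L = as.integer(L), center_offset = 15L),
              class = "window_tensor")
  })
}

test_that("model specs validate their fields and expose both profiles", {
  s <- model_spec()
  expect_equal(gaitphase:::spec_units(s), c(30L, 60L, 60L, 60L, 30L))
  expect_equal(s$dropout_rate, 0.2)
  d <- model_spec(profile = "desk_scale")
  expect_equal(gaitphase:::spec_units(d), c(8L, 16L, 16L, 16L, 8L))
  expect_error(model_spec(dropout_rate = 1.0), "dropout")
  expect_error(model_spec(seq_len = 250), "odd")
  expect_error(model_spec(input_units = 0), "positive")
})

test_that("the forward pass emits one probability per window, in [0, 1]", {
  spec <- model_spec(input_units = 4, hidden_units = c(8), seq_len = 251,
                     final_recurrent_units = 4)
  m <- build_model(spec, seed = 1)
  x <- array(stats::runif(2 * 251 * 3), dim = c(2, 251, 3))
  p <- gaitphase:::predict_window_probs(m, x)
  expect_length(p, 2)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("analytic gradients match central finite differences", {
  spec <- model_spec(input_units = 2, hidden_units = c(3, 3, 3),
                     final_recurrent_units = 2, seq_len = 9, dropout_rate = 0)
  m <- build_model(spec, seed = 7)
  units <- gaitphase:::spec_units(spec)
  with_seed <- getFromNamespace("with_seed", "gaitphase")
  dat <- with_seed(42, list(X = array(stats::rnorm(3 * 4 * 9), dim = c(3, 4, 9)),
                            y = c(1, 0, 1, 0)))
  run <- function(params)
    gaitphase:::lstm_stack_run(params, dat$X, dat$y, units, 0,
                               spec$batch_norm_momentum,
                               spec$batch_norm_epsilon, m$state, TRUE, TRUE)
  r0 <- run(m$params)
  idx <- with_seed(1, sample(length(m$params), 50))
  eps <- 1e-6
  fd <- vapply(idx, function(i) {
    up <- m$params; up[i] <- up[i] + eps
    dn <- m$params; dn[i] <- dn[i] - eps
    (run(up)$loss - run(dn)$loss) / (2 * eps)
  }, numeric(1))
  rel <- abs(fd - r0$grad[idx]) / pmax(1e-6, abs(fd) + abs(r0$grad[idx]))
  expect_lt(max(rel), 1e-5)
})

test_that("training reduces loss on separable data and logs a full history", {
  wt <- separable_windows()
  m <- build_model(tiny_spec(), seed = 2)
  cfg <- train_config(learning_rate = 5e-3, epochs = 5, batch_size = 12,
                      seed = 3)
  tm <- train_phase_model(m, wt, cfg = cfg)
  expect_equal(nrow(tm$history), 5)
  expect_lt(tm$history$loss[5], tm$history$loss[1])
  expect_equal(tm$phase, "MidS")
})

test_that("zero epochs returns the initialized model unchanged", {
  wt <- separable_windows()
  m <- build_model(tiny_spec(), seed = 2)
  tm <- train_phase_model(m, wt, cfg = train_config(epochs = 0))
  expect_identical(tm$params, m$params)
  expect_equal(nrow(tm$history), 0)
})

test_that("training is bit-reproducible for a fixed seed", {
  wt <- separable_windows()
  cfg <- train_config(learning_rate = 1e-3, epochs = 2, batch_size = 12,
                      seed = 9)
  t1 <- train_phase_model(build_model(tiny_spec(), seed = 4), wt, cfg = cfg)
  t2 <- train_phase_model(build_model(tiny_spec(), seed = 4), wt, cfg = cfg)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$history, t2$history)
})

test_that("shape mismatches between windows and spec are rejected", {
  wt <- separable_windows(L = 31)
  m <- build_model(tiny_spec(seq_len = 33), seed = 1)
  expect_error(train_phase_model(m, wt, cfg = train_config(epochs = 1)),
               "does not match")
})

test_that("inference is deterministic and trace length is n - L + 1", {
  spec <- tiny_spec(seq_len = 31)
  m <- build_model(spec, seed = 3)
  m$phase <- "FO"
  fs <- manual_feature_set(stats::runif(80))
  tr1 <- predict_trace(m, fs)
  tr2 <- predict_trace(m, fs)
  expect_identical(tr1$probabilities, tr2$probabilities)
  expect_length(tr1$probabilities, 80 - 31 + 1)
  expect_equal(tr1$frames[1], 15)
  expect_true(all(tr1$probabilities >= 0 & tr1$probabilities <= 1))
  expect_error(predict_trace(m, manual_feature_set(stats::runif(30))),
               "too short")
})

test_that("frame metrics reproduce closed forms and a hand-computed loss", {
  n <- 400
  labels <- manual_labels(fo = 200, mids = 220, fc = 240, n = n)
  zero_tr <- manual_trace(rep(0, n - 250), phase = "FO")
  m0 <- frame_metrics(zero_tr, labels, "FO")
  expect_equal(m0$accuracy, 1 - 1 / (n - 250))  # one positive frame missed
  half_tr <- manual_trace(rep(0.5, n - 250), phase = "FO")
  mh <- frame_metrics(half_tr, labels, "FO")
  expect_equal(mh$bce_loss, log(2), tolerance = 1e-12)
  expect_equal(mh$accuracy, mh$baseline_accuracy)

  # 10-frame toy trace against an explicitly summed cross-entropy
  p <- c(0.9, 0.1, 0.8, 0.3, 0.5, 0.6, 0.2, 0.7, 0.05, 0.95)
  y <- c(1, 0, 1, 0, 0, 1, 0, 1, 0, 1)
  toy_labels <- manual_labels(fo = (125:134)[y == 1], mids = 1, fc = 2, n = 500)
  toy_tr <- manual_trace(p, phase = "FO")
  expected <- -sum(y * log(p) + (1 - y) * log(1 - p)) / 10
  expect_equal(frame_metrics(toy_tr, toy_labels, "FO")$bce_loss, expected,
               tolerance = 1e-12)

  # all-zero trace against all-zero labels: perfect accuracy, ~0 loss
  empty_labels <- manual_labels(fo = 1, mids = 2, fc = 3, n = 400)
  tr <- manual_trace(rep(0, 150), phase = "MidS")
  mm <- frame_metrics(tr, empty_labels, "MidS")
  expect_equal(mm$accuracy, 1)
  expect_lt(mm$bce_loss, 1e-6)
})

test_that("model artifacts survive a save/load round trip", {
  wt <- separable_windows()
  m <- train_phase_model(build_model(tiny_spec(), seed = 2), wt,
                         cfg = train_config(epochs = 1, seed = 1))
  dir <- withr::local_tempdir()
  save_phase_model(m, dir)
  back <- load_phase_model(dir)
  expect_identical(back$params, m$params)
  expect_identical(back$state, m$state)
  expect_equal(back$phase, "MidS")
  fs <- manual_feature_set(stats::runif(60))
  expect_identical(predict_trace(back, fs)$probabilities,
                   predict_trace(m, fs)$probabilities)
})
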