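test_that("frame labels follow the half-overlap rule", {
  hop <- 0.032
  flen <- 0.064
  starts <- seq(0, 10 - flen, by = hop)
  expect_identical(frame_labels_from_events(NULL, starts, hop, flen),
                   integer(length(starts)))

  ev <- data.frame(onset_s = 1.0, offset_s = 1.5)
  y <- frame_labels_from_events(ev, starts, hop, flen)
  # independent enumeration of overlapping frame intervals
  expected <- as.integer(pmax(0, pmin(starts + flen, 1.5) -
                                pmax(starts, 1.0)) >= flen / 2)
  expect_identical(y, expected)
  expect_gt(sum(y), 0)

  # event shorter than half a frame centered between frame starts
  tiny <- data.frame(onset_s = 1.006, offset_s = 1.022)  # 16 ms < 32 ms
  expect_identical(sum(frame_labels_from_events(tiny, starts, hop, flen)), 0L)

  expect_error(frame_labels_from_events(
    data.frame(onset_s = 2, offset_s = 1), starts, hop, flen), "malformed")
})

test_that("decode_events applies threshold, gap merge and duration filter", {
  cfg <- detector_config()
  hop <- 0.01
  starts <- seq(0, 4.99, by = hop)

  empty <- frame_posterior(numeric(500), starts, hop)
  expect_equal(nrow(decode_events(empty, cfg)), 0)

  # one 0.3-s supra-threshold run
  p <- numeric(500)
  p[101:130] <- 0.9
  one <- decode_events(frame_posterior(p, starts, hop), cfg)
  expect_equal(nrow(one), 1)
  expect_lt(abs(one$onset_s - 1.0), hop + 1e-9)
  expect_lt(abs(one$offset_s - 1.3), hop + 1e-9)

  # two runs with a 0.03-s gap merge under merge_gap 0.05
  p2 <- numeric(500)
  p2[101:130] <- 0.9
  p2[134:163] <- 0.9
  merged <- decode_events(frame_posterior(p2, starts, hop), cfg)
  expect_equal(nrow(merged), 1)

  # the same runs 0.2 s apart stay separate
  p3 <- numeric(500)
  p3[101:130] <- 0.9
  p3[151:180] <- 0.9
  two <- decode_events(frame_posterior(p3, starts, hop), cfg)
  expect_equal(nrow(two), 2)
})

test_that("decode_events matches the brute-force oracle on random posteriors", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(50:400, 1)
    hop <- sample(c(0.01, 0.032, 0.05), 1)
    probs <- pmin(pmax(stats::filter(runif(n), rep(1 / 3, 3),
                                     circular = TRUE), 0), 1)
    probs <- as.numeric(probs)
    cfg <- detector_config(decode_threshold = runif(1, 0.2, 0.8),
                           min_event_s = runif(1, 0.02, 0.3),
                           merge_gap_s = runif(1, 0, 0.12))
    starts <- (seq_len(n) - 1) * hop
    got <- decode_events(frame_posterior(probs, starts, hop), cfg)
    want <- oracle_decode(probs, starts, hop, cfg$decode_threshold,
                          cfg$merge_gap_s, cfg$min_event_s)
    expect_equal(got, want)
  }
})

test_that("lowering the threshold never shrinks event coverage", {
  set.seed(32)
  hop <- 0.032
  n <- 300
  starts <- (seq_len(n) - 1) * hop
  probs <- runif(n)
  cover <- function(thr) {
    ev <- decode_events(frame_posterior(probs, starts, hop),
                        detector_config(decode_threshold = thr,
                                        min_event_s = 0.01, merge_gap_s = 0))
    if (nrow(ev) == 0) 0 else sum(ev$offset_s - ev$onset_s)
  }
  cv <- vapply(seq(0.9, 0.1, by = -0.1), cover, 1)
  expect_true(all(diff(cv) >= -1e-12))
})

test_that("label/decode round trip recovers event boundaries within one hop", {
  set.seed(33)
  hop <- 0.032
  flen <- 0.064
  starts <- seq(0, 10 - flen, by = hop)
  cfg <- detector_config()
  for (i in 1:30) {
    k <- sample(1:3, 1)
    onsets <- sort(runif(k, 0.5, 8.5))
    durs <- runif(k, 0.15, 1.2)
    ev <- data.frame(onset_s = onsets, offset_s = onsets + durs)
    # keep events separated by > merge gap + one frame
    if (k > 1 && any(ev$onset_s[-1] - ev$offset_s[-k] < 0.2)) next
    y <- frame_labels_from_events(ev, starts, hop, flen)
    dec <- decode_events(frame_posterior(y, starts, hop), cfg)
    expect_equal(nrow(dec), k)
    expect_true(all(abs(dec$onset_s - ev$onset_s) <= hop + 1e-9))
    expect_true(all(abs(dec$offset_s - ev$offset_s) <= hop + 1e-9))
  }
})

test_that("initialization is seeded and zero-epoch fits return it unchanged", {
  toy <- make_toy_window_set(n = 8, seed = 51)
  cfg0 <- detector_config(epochs = 0, seed = 7)
  f1 <- wheeze_detector(toy$windows, config = cfg0)
  f2 <- wheeze_detector(toy$windows, config = cfg0)
  expect_identical(coef(f1), coef(f2))
  expect_equal(nrow(f1$history), 0)
  expect_gt(f1$n_parameters, 1000)

  f3 <- wheeze_detector(toy$windows, config = detector_config(epochs = 0,
                                                              seed = 8))
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("training rejects invalid splits", {
  toy <- make_toy_window_set(n = 8, seed = 52)
  expect_error(
    wheeze_detector(toy$windows, val = toy$windows,
                    config = detector_config(epochs = 1)),
    "patient")

  # a split with no positive frames is a data error
  neg <- toy$windows[vapply(toy$windows, function(w) sum(w$y) == 0, TRUE)]
  expect_error(wheeze_detector(neg, config = detector_config(epochs = 1)),
               "positive")
})

test_that("a separable toy problem reaches validation frame-F1 >= 0.9", {
  toy <- make_toy_window_set(n = 60, seed = 42)
  fit <- wheeze_detector(toy$windows,
                         config = detector_config(epochs = 20, seed = 3))
  expect_gte(fit$best_val_f1, 0.9)
  expect_lte(nrow(fit$history), 20)
})

test_that("prediction is deterministic, bounded, and pad-robust", {
  toy <- make_toy_window_set(n = 8, seed = 53)
  fit <- wheeze_detector(toy$windows, config = detector_config(epochs = 1,
                                                               seed = 2))
  set.seed(1)
  rec <- simulate_breath_cycle_track(6.5, 20)   # 2-s windows => padded tail
  w <- segment_windows(rec, 2)
  fb <- feature_bundle(w[[length(w)]], fit$feature_cfg)
  p1 <- predict_frames(fit, fb)
  p2 <- predict_frames(fit, fb)
  expect_identical(p1$probs, p2$probs)
  expect_true(all(p1$probs >= 0 & p1$probs <= 1))
  expect_true(all(is.finite(p1$probs)))
  expect_length(p1$probs, nrow(fb$mel$values))
})

test_that("checkpoints round-trip through JSON", {
  toy <- make_toy_window_set(n = 8, seed = 54)
  fit <- wheeze_detector(toy$windows, config = detector_config(epochs = 1,
                                                               seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_equal(back$params, fit$params, ignore_attr = TRUE)
  expect_equal(back$hc_stats, fit$hc_stats, ignore_attr = TRUE)
  fb <- toy$windows[[1]]$bundle
  expect_equal(predict_frames(back, fb)$probs, predict_frames(fit, fb)$probs)
})
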