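test_that("breath-cycle envelope repeats at the respiratory period", {
  set.seed(5)
  rec <- simulate_breath_cycle_track(10, 20)   # 3-s cycle
  env <- rec$envelope
  fs <- rec$sample_rate_hz
  # autocorrelation of the demeaned envelope peaks at one cycle period
  e <- env - mean(env)
  ac <- stats::acf(e, lag.max = 4 * fs, plot = FALSE)$acf[-1]
  lags_s <- seq_along(ac) / fs
  search <- lags_s > 1.5                        # skip the zero-lag shoulder
  peak_lag <- lags_s[search][which.max(ac[search])]
  expect_lt(abs(peak_lag - 3), 0.2)
  expect_false(rec$incomplete_cycle)

  short <- simulate_breath_cycle_track(2, 12)   # one cycle = 5 s > duration
  expect_true(short$incomplete_cycle)
  expect_s3_class(short, "audio_recording")
})

test_that("generation is bit-identical under a fixed seed", {
  mk <- function() {
    set.seed(99)
    simulate_breath_cycle_track(4, 22)$samples
  }
  expect_identical(mk(), mk())

  cfgA <- cohort_config(n_patients = 3, seed = 123)
  a <- simulate_cohort(cfgA)
  b <- simulate_cohort(cfgA)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$annotations, b$annotations)
  expect_identical(lapply(a$recordings, `[[`, "samples"),
                   lapply(b$recordings, `[[`, "samples"))
})

test_that("inject_wheeze adds tonal energy at the event with exact truth", {
  set.seed(11)
  base <- simulate_breath_cycle_track(10, 20)

  none <- inject_wheeze(base, 0)
  expect_identical(none$recording$samples, base$samples)
  expect_equal(nrow(none$events), 0)

  # one strong 400 Hz event: mel energy near 400 Hz rises >= 10 dB during
  # the event relative to outside it
  iw <- inject_wheeze(base, 1, wheeze_event_config(
    snr_db = c(15, 15), f0_range_hz = c(400, 400),
    duration_range_s = c(1.0, 1.0), max_harmonics = 1))
  ev <- iw$events
  expect_equal(ev$offset_s - ev$onset_s, 1.0, tolerance = 1e-9)
  mel <- mel_spectrogram(iw$recording$samples, sample_rate_hz = 4000,
                         cfg = feature_config(db_reference = "unit"))
  band <- which.min(abs(mel$mel_center_freqs_hz - 400))
  inside <- mel$frame_times_s >= ev$onset_s & mel$frame_times_s <= ev$offset_s
  expect_gt(mean(mel$values[inside, band]) - mean(mel$values[!inside, band]), 10)

  # infeasible packing errors out
  expect_error(
    inject_wheeze(simulate_breath_cycle_track(2, 20), 5,
                  wheeze_event_config(duration_range_s = c(1, 1.5))),
    "infeasible")
})

test_that("ground-truth events never overlap and stay within the recording", {
  set.seed(21)
  for (i in 1:15) {
    rec <- simulate_breath_cycle_track(runif(1, 5, 10), 20)
    iw <- inject_wheeze(rec, sample(1:3, 1))
    ev <- iw$events[order(iw$events$onset_s), ]
    expect_true(all(ev$onset_s >= 0))
    expect_true(all(ev$offset_s <= rec$duration_s + 1e-9))
    expect_true(all(ev$offset_s - ev$onset_s >= 0.1 - 1e-9))
    if (nrow(ev) > 1)
      expect_true(all(ev$onset_s[-1] >= ev$offset_s[-nrow(ev)]))
  }
})

test_that("artifacts behave per kind and drive the quality flag", {
  set.seed(13)
  rec <- simulate_breath_cycle_track(5, 20)

  cl <- inject_artifact(rec, "clipping", gain = 8)
  expect_gte(mean(abs(cl$samples) >= 1 - 1e-12), 0.01)

  same <- inject_artifact(rec, "speech_like", gain = 0)
  expect_identical(same$samples, rec$samples)

  loud <- inject_artifact(rec, "speech_like", gain = 5)
  expect_false(loud$quality)

  bump <- inject_artifact(rec, "bump", gain = 2)
  expect_true(all(is.finite(bump$samples)))
})

test_that("cohort marginals are calibrated to the configured probabilities", {
  # 500 patients x 4 locations = 2000 recordings, metadata only
  cfg <- cohort_config(n_patients = 500, seed = 2024)
  co <- simulate_cohort(cfg, render_audio = FALSE)
  n <- nrow(co$metadata)
  expect_equal(n, 2000L)

  binom99 <- function(p) stats::qbinom(c(0.005, 0.995), n, p) / n
  wz <- mean(co$metadata$wheeze_truth)
  expect_gte(wz, binom99(0.18)[1]); expect_lte(wz, binom99(0.18)[2])
  q <- mean(co$metadata$quality)
  expect_gte(q, binom99(0.743)[1]); expect_lte(q, binom99(0.743)[2])

  # age mix converges too (99% binomial band per group, patient level)
  mix <- table(factor(co$metadata$age_group,
                      c("preschool", "school", "adolescent"))) / n
  for (g in names(mix)) {
    b <- stats::qbinom(c(0.005, 0.995), 500, cfg$age_group_mix[[g]]) / 500
    expect_gte(mix[[g]], b[1]); expect_lte(mix[[g]], b[2])
  }

  # degenerate prevalence: no events anywhere
  co0 <- simulate_cohort(cohort_config(n_patients = 20, seed = 3,
                                       wheeze_prevalence = 0),
                         render_audio = FALSE)
  expect_equal(nrow(co0$annotations), 0)
  expect_true(all(!co0$metadata$wheeze_truth))
})

test_that("annotation TSVs round-trip through the ICBHI-style reader", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(cohort_config(n_patients = 2, seed = 8,
                                      wheeze_prevalence = 0.9), dir = dir)
  pos <- unique(co$annotations$recording_id)[1]
  ev <- read_event_annotations(file.path(dir, paste0(pos, "_events.tsv")))
  truth <- co$annotations[co$annotations$recording_id == pos, ]
  expect_equal(ev$begin_s, truth$onset_s)
  expect_equal(ev$end_s, truth$offset_s)
  expect_true(all(ev$label == "wheeze"))

  # headerless ICBHI cycle dialect: begin end crackles wheezes
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0.1\t1.2\t0\t1", "1.5\t2.0\t1\t0"), f)
  d <- read_event_annotations(f)
  expect_equal(d$label, c("wheeze", "crackle"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("begin_s\tend_s\tlabel\n2.0\t1.0\twheeze", f2)
  expect_error(read_event_annotations(f2), "malformed")
})
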