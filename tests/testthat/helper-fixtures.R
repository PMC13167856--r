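# shared fixtures and independent oracles used across the suite

# brute-force event decoder: explicit scan for maximal supra-threshold runs,
# then merge, then length filter; independent of the rle-based implementation
oracle_decode <- function(probs, starts, hop, threshold, merge_gap_s,
                          min_event_s) {
  n <- length(probs)
  mask <- probs >= threshold
  runs <- list()
  i <- 1
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) == 0)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if ((r[1] - last[2] - 1) * hop < merge_gap_s)
      merged[[length(merged)]][2] <- r[2]
    else merged[[length(merged) + 1]] <- r
  }
  keep <- Filter(function(r) (r[2] - r[1] + 1) * hop >= min_event_s - hop - 1e-9,
                 merged)
  if (length(keep) == 0)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  data.frame(onset_s = starts[vapply(keep, `[`, 1, 1)],
             offset_s = starts[vapply(keep, `[`, 1, 2)] + hop)
}

# small separable window set: 2-s breath-noise windows, half with one
# strong injected tonal event; per-window patient ids
make_toy_window_set <- function(n = 60, seed = 42, window_s = 2,
                                snr_db = c(10, 15)) {
  set.seed(seed)
  recs <- list()
  anns <- list()
  for (i in seq_len(n)) {
    id <- sprintf("w%03d", i)
    b <- simulate_breath_cycle_track(window_s, 30)
    b$recording_id <- id
    b$patient_id <- id
    if (i %% 2 == 0) {
      iw <- inject_wheeze(b, 1, wheeze_event_config(
        snr_db = snr_db, duration_range_s = c(0.4, 1.2)))
      b <- iw$recording
      ev <- iw$events
      ev$recording_id <- id
      anns[[length(anns) + 1]] <- ev
    }
    recs[[i]] <- b
  }
  ann <- do.call(rbind, anns)
  list(recordings = recs, annotations = ann,
       windows = prepare_training_windows(recs, ann, window_s = window_s))
}

# seeded end-to-end cohort at the scale used for the recovery check:
# 10-s recordings (one analysis window each), high-SNR wheezes, balanced
# prevalence
make_recovery_cohort <- function(n_patients, seed) {
  simulate_cohort(cohort_config(
    n_patients = n_patients, seed = seed,
    wheeze_prevalence = 0.5, quality_proportion = 1,
    duration_range_s = c(10, 10),
    event_cfg = wheeze_event_config(snr_db = c(6, 15))))
}
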