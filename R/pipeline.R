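#' Load a simulated or on-disk cohort
#'
#' Reads `metadata.csv`, the per-recording WAV files, and the
#' ICBHI-style event TSVs written by [simulate_cohort()] (or arranged in
#' the same layout for real data), and attaches the metadata fields to
#' each recording.
#'
#' @param dir Cohort directory.
#' @param load_audio Read the waveforms (set `FALSE` for metadata-only
#'   operations).
#' @return List with `recordings`, `annotations`, `metadata`, matching
#'   the in-memory layout of [simulate_cohort()].
#' @export
load_cohort <- function(dir, load_audio = TRUE) {
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  recordings <- vector("list", nrow(meta))
  anns <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    if (load_audio) {
      rec <- read_wav(file.path(dir, paste0(meta$recording_id[i], ".wav")))
      rec$recording_id <- meta$recording_id[i]
      rec$patient_id <- meta$patient_id[i]
      rec$age_group <- meta$age_group[i]
      rec$location <- meta$location[i]
      rec$collector <- meta$collector[i]
      rec$quality <- meta$quality[i]
      recordings[[i]] <- rec
    }
    tsv <- file.path(dir, paste0(meta$recording_id[i], "_events.tsv"))
    if (file.exists(tsv)) {
      ev <- read_event_annotations(tsv)
      if (nrow(ev) > 0)
        anns[[i]] <- data.frame(recording_id = meta$recording_id[i],
                                onset_s = ev$begin_s, offset_s = ev$end_s,
                                f0_hz = NA_real_, label = ev$label)
    }
  }
  ann <- do.call(rbind, anns)
  if (is.null(ann))
    ann <- data.frame(recording_id = character(0), onset_s = numeric(0),
                      offset_s = numeric(0), f0_hz = numeric(0),
                      label = character(0))
  list(recordings = recordings, annotations = ann, metadata = meta)
}

#' Pipeline subcommands
#'
#' Thin orchestration wrappers used by the `wheezr` command-line script
#' (`inst/exec/wheezr`): simulate a cohort to disk, train a detector
#' from a cohort directory, run detection to a predictions CSV, evaluate
#' predictions against the metadata truth (quality recordings only, as
#' in the study design), and re-derive the published numbers.
#'
#' @param out_dir,cohort_dir Cohort directory.
#' @param n_patients,seed Cohort size and seed for `run_simulate`.
#' @param ... Extra arguments passed to [cohort_config()].
#' @return `run_simulate`: the cohort metadata (invisibly);
#'   `run_train`: the fitted detector (checkpoint written);
#'   `run_detect`: the predictions data.frame (CSV written);
#'   `run_evaluate`: a list with the overall `metric_report` and the
#'   per-stratum tables; `run_reproduce`: a `reproduction_report`.
#' @name pipeline
#' @export
run_simulate <- function(out_dir, n_patients = 50, seed = 1L, ...) {
  cohort <- simulate_cohort(cohort_config(n_patients = n_patients,
                                          seed = seed, ...), dir = out_dir)
  invisible(cohort$metadata)
}

#' @rdname pipeline
#' @param checkpoint Checkpoint path.
#' @param config [detector_config()].
#' @param feature_cfg [feature_config()].
#' @export
run_train <- function(cohort_dir, checkpoint, config = detector_config(),
                      feature_cfg = feature_config()) {
  cohort <- load_cohort(cohort_dir)
  fit <- wheeze_detector(cohort, config = config, feature_cfg = feature_cfg)
  save_checkpoint(fit, checkpoint)
  fit
}

#' @rdname pipeline
#' @param out_csv Predictions CSV path.
#' @export
run_detect <- function(cohort_dir, checkpoint, out_csv) {
  cohort <- load_cohort(cohort_dir)
  fit <- load_checkpoint(checkpoint)
  res <- predict(fit, cohort)
  tab <- predictions_table(res)
  write.csv(tab, out_csv, row.names = FALSE)
  invisible(tab)
}

#' @rdname pipeline
#' @param predictions_csv Predictions CSV from `run_detect`.
#' @param metadata_csv Cohort metadata CSV holding the reference
#'   `wheeze_truth` and `quality` columns.
#' @export
run_evaluate <- function(predictions_csv, metadata_csv) {
  pred <- read.csv(predictions_csv, stringsAsFactors = FALSE)
  meta <- read.csv(metadata_csv, stringsAsFactors = FALSE)
  d <- merge(meta, pred, by = "recording_id")
  d <- d[d$quality, ]   # only quality recordings are scored
  overall <- metrics(confusion(d$label_pred, d$wheeze_truth))
  list(overall = overall,
       by_age_group = evaluate_by_stratum(d$label_pred, d$wheeze_truth,
                                          d$age_group),
       by_location = evaluate_by_stratum(d$label_pred, d$wheeze_truth,
                                         d$location),
       n_scored = nrow(d))
}

#' @rdname pipeline
#' @export
run_reproduce <- function() {
  rep <- reproduce_reported()
  print(rep)
  invisible(rep)
}
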