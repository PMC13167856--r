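# run code under a local seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# pink (1/f) noise via FFT spectral shaping; deterministic given the RNG state
pink_noise <- function(n) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))         # avoid division by zero at DC
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE)) / n
  x / max(abs(x), 1e-12)
}

#' Simulate one breath-cycle noise track
#'
#' Generates band-limited pink noise amplitude-modulated by alternating
#' inspiratory/expiratory envelopes at the given respiratory rate. This
#' emulates a normal (vesicular or tracheal) respiratory sound with
#' clearly distinguishable phases; inspiration is louder than expiration
#' at chest locations and the asymmetry is reversed over the trachea.
#'
#' Uses the current RNG state; call `set.seed()` (or use
#' [simulate_cohort()], which seeds itself) for reproducibility.
#'
#' @param duration_s Duration in seconds (> 0).
#' @param resp_rate_bpm Respiratory rate, breaths per minute.
#' @param sample_rate_hz Sampling rate (default 4000).
#' @param location Auscultation site; controls phase asymmetry.
#' @param insp_frac Fraction of the cycle spent in inspiration.
#' @return [audio_recording]; when the duration is shorter than one full
#'   respiratory cycle the recording carries `incomplete_cycle = TRUE`.
#' @export
simulate_breath_cycle_track <- function(duration_s, resp_rate_bpm,
                                        sample_rate_hz = 4000,
                                        location = "right_posterior_inferior",
                                        insp_frac = 0.4) {
  stopifnot(duration_s > 0, resp_rate_bpm > 0)
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  cycle_s <- 60 / resp_rate_bpm
  t <- (seq_len(n) - 1) / fs
  phase <- (t %% cycle_s) / cycle_s                 # position within the cycle

  # raised-cosine hump per phase; expiration quieter at chest, louder at trachea
  gains <- if (identical(location, "trachea")) c(insp = 0.6, exp = 1.0)
           else c(insp = 1.0, exp = 0.55)
  env <- ifelse(phase < insp_frac,
                gains["insp"] * sin(pi * phase / insp_frac)^2,
                gains["exp"]  * sin(pi * (phase - insp_frac) / (1 - insp_frac))^2)
  env <- env + 0.05                                  # breath sounds never fully gate

  x <- pink_noise(n) * env
  x <- x / max(abs(x), 1e-12) * 0.5
  rec <- audio_recording(x, fs, location = location)
  rec$incomplete_cycle <- duration_s < cycle_s
  rec$envelope <- env
  rec
}

#' Wheeze event configuration
#'
#' Acoustic model of a wheeze: a stack of 1-3 harmonics on a fundamental
#' drawn from 100-1000 Hz, with slow frequency drift (up to +/-10%) and
#' raised-cosine onset/offset ramps, mixed at a signal-to-noise ratio
#' drawn from `snr_db`. Durations are drawn from `duration_range_s`
#' (tonal events of at least 0.1 s, the conventional minimum).
#'
#' @param snr_db Length-2 range of event SNR in dB relative to the local
#'   breath-noise RMS.
#' @param f0_range_hz Fundamental frequency range.
#' @param duration_range_s Event duration range in seconds.
#' @param min_event_s Minimum admissible event duration.
#' @param max_harmonics Maximum number of harmonics (drawn 1..max).
#' @param drift_frac Maximum relative frequency drift over the event.
#' @param ramp_s Raised-cosine ramp length.
#' @param min_gap_s Minimum silence between consecutive events.
#' @return List of class `wheeze_event_config`.
#' @export
wheeze_event_config <- function(snr_db = c(3, 12), f0_range_hz = c(100, 1000),
                                duration_range_s = c(0.1, 1.5),
                                min_event_s = 0.1, max_harmonics = 3,
                                drift_frac = 0.1, ramp_s = 0.025,
                                min_gap_s = 0.05) {
  structure(as.list(environment()), class = "wheeze_event_config")
}

#' Inject wheeze events into a recording
#'
#' Adds amplitude-modulated harmonic tones at non-overlapping random
#' positions and returns the exact ground-truth intervals. Placement uses
#' stick-breaking over the free time, so any feasible request succeeds.
#'
#' @param rec [audio_recording] host.
#' @param n_events Number of events to inject.
#' @param event_cfg [wheeze_event_config()].
#' @return List with `recording` (audio with events mixed in) and
#'   `events`, a data.frame with columns `onset_s`, `offset_s`, `f0_hz`,
#'   `label` (= `"wheeze"`).
#' @export
inject_wheeze <- function(rec, n_events, event_cfg = wheeze_event_config()) {
  stopifnot(inherits(rec, "audio_recording"), n_events >= 0)
  if (n_events == 0)
    return(list(recording = rec,
                events = data.frame(onset_s = numeric(0), offset_s = numeric(0),
                                    f0_hz = numeric(0), label = character(0))))
  fs <- rec$sample_rate_hz
  dur <- rec$duration_s
  cfg <- event_cfg

  durs <- runif(n_events, cfg$duration_range_s[1], cfg$duration_range_s[2])
  slack <- dur - sum(durs) - (n_events - 1) * cfg$min_gap_s
  if (slack < 0)
    stop("infeasible packing: ", n_events, " events of total ",
         round(sum(durs), 2), " s do not fit in ", round(dur, 2), " s")
  # distribute free time over the n_events + 1 gaps (stick breaking)
  cuts <- sort(runif(n_events))
  gaps <- diff(c(0, cuts, 1)) * slack
  onsets <- numeric(n_events)
  pos <- 0
  for (i in seq_len(n_events)) {
    pos <- pos + gaps[i]
    onsets[i] <- pos
    pos <- pos + durs[i] + cfg$min_gap_s
  }

  x <- rec$samples
  noise_rms <- sqrt(mean(x^2))
  f0s <- runif(n_events, cfg$f0_range_hz[1], cfg$f0_range_hz[2])
  for (i in seq_len(n_events)) {
    a <- round(onsets[i] * fs) + 1L
    b <- min(round((onsets[i] + durs[i]) * fs), length(x))
    m <- b - a + 1L
    tt <- (seq_len(m) - 1) / fs
    nh <- sample.int(cfg$max_harmonics, 1)
    drift <- runif(1, -cfg$drift_frac, cfg$drift_frac)
    f_inst <- f0s[i] * (1 + drift * tt / max(tt[m], 1e-9))
    ph <- 2 * pi * cumsum(f_inst) / fs
    tone <- rowSums(sapply(seq_len(nh), function(h) sin(h * ph) / h))
    ramp_n <- min(round(cfg$ramp_s * fs), m %/% 2)
    env <- rep(1, m)
    if (ramp_n > 0) {
      r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
      env[seq_len(ramp_n)] <- r
      env[m - ramp_n + seq_len(ramp_n)] <- rev(r)
    }
    snr <- runif(1, cfg$snr_db[1], cfg$snr_db[2])
    target_rms <- noise_rms * 10^(snr / 20)
    tone <- tone * env
    tone <- tone / max(sqrt(mean(tone^2)), 1e-12) * target_rms
    x[a:b] <- x[a:b] + tone
  }
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  out <- rec
  out$samples <- x
  list(recording = out,
       events = data.frame(onset_s = onsets, offset_s = onsets + durs,
                           f0_hz = f0s, label = "wheeze"))
}

#' Inject a recording artifact
#'
#' Superimposes one of three artifact types seen in real-world smartphone
#' auscultation: `speech_like` (syllabic low-frequency harmonic bursts),
#' `bump` (decaying handling thumps), or `clipping` (gain into hard
#' limiting). The quality flag is set `FALSE` when the artifact energy
#' fraction of the output exceeds `quality_threshold`.
#'
#' @param rec [audio_recording].
#' @param kind `"speech_like"`, `"bump"`, or `"clipping"`.
#' @param gain Artifact amplitude relative to the signal RMS (for
#'   `clipping`, the pre-limiter gain applied to the whole signal).
#' @param quality_threshold Energy-fraction cutoff above which the
#'   recording is flagged as non-quality.
#' @return [audio_recording] with the artifact mixed in and an updated
#'   `quality` flag.
#' @export
inject_artifact <- function(rec, kind = c("speech_like", "bump", "clipping"),
                            gain = 3, quality_threshold = 0.2) {
  kind <- match.arg(kind)
  fs <- rec$sample_rate_hz
  n <- length(rec$samples)
  x <- rec$samples
  rms <- sqrt(mean(x^2))

  if (kind == "clipping") {
    y <- pmax(-1, pmin(1, x * max(gain, 1)))
    art_energy <- sum((y - x)^2)
  } else if (kind == "bump") {
    a <- numeric(n)
    n_bumps <- sample(1:3, 1)
    for (i in seq_len(n_bumps)) {
      at <- sample.int(max(n - fs %/% 2, 1), 1)
      len <- min(round(0.3 * fs), n - at + 1)
      tt <- (seq_len(len) - 1) / fs
      a[at:(at + len - 1)] <- a[at:(at + len - 1)] +
        sin(2 * pi * 40 * tt) * exp(-tt / 0.05)
    }
    a <- a * gain * rms
    y <- x + a
    art_energy <- sum(a^2)
  } else {  # speech_like
    tt <- (seq_len(n) - 1) / fs
    f0 <- runif(1, 120, 250)
    syl <- pmax(0, sin(2 * pi * runif(1, 3, 5) * tt))^2
    a <- (sin(2 * pi * f0 * tt) + 0.5 * sin(2 * pi * 2 * f0 * tt) +
          0.3 * sin(2 * pi * 3 * f0 * tt)) * syl
    a <- a * gain * rms
    y <- x + a
    art_energy <- sum(a^2)
  }
  if (gain <= 0) { y <- x; art_energy <- 0 }
  peak <- max(abs(y))
  if (kind != "clipping" && peak > 1) y <- y / peak
  frac <- art_energy / max(sum(y^2), 1e-12)
  out <- rec
  out$samples <- y
  out$quality <- if (frac > quality_threshold) FALSE
                 else if (is.na(rec$quality)) NA else rec$quality
  out$artifact <- kind
  out$artifact_energy_fraction <- frac
  out
}

#' Cohort simulation configuration
#'
#' Defaults emulate the study population: three pediatric age groups,
#' four auscultation locations (one recording per location per patient),
#' 5-10 s recordings, roughly 18% wheeze-positive recordings and a 74.3%
#' quality proportion, with about 17% of recordings collected by parents.
#' Respiratory rates are age-typical resting values.
#'
#' @param n_patients Number of patients.
#' @param wheeze_prevalence Per-recording probability of containing
#'   wheezes.
#' @param quality_proportion Per-recording probability of passing quality
#'   assessment.
#' @param age_group_mix Probabilities for preschool/school/adolescent
#'   (must sum to 1).
#' @param parent_fraction Probability a recording is parent-collected.
#' @param duration_range_s Recording duration range, seconds.
#' @param respiratory_rate_by_age Named breaths/min per age group.
#' @param events_per_positive Range of wheeze events per positive
#'   recording.
#' @param event_cfg [wheeze_event_config()].
#' @param sample_rate_hz Sampling rate of generated audio.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 50,
                          wheeze_prevalence = 0.18,
                          quality_proportion = 0.743,
                          age_group_mix = c(preschool = 0.29, school = 0.20,
                                            adolescent = 0.51),
                          parent_fraction = 0.17,
                          duration_range_s = c(5, 10),
                          respiratory_rate_by_age = c(preschool = 26,
                                                      school = 20,
                                                      adolescent = 15),
                          events_per_positive = c(1, 3),
                          event_cfg = wheeze_event_config(),
                          sample_rate_hz = 4000,
                          seed = 1L) {
  stopifnot(abs(sum(age_group_mix) - 1) < 1e-8,
            all(c(wheeze_prevalence, quality_proportion, parent_fraction) >= 0),
            all(c(wheeze_prevalence, quality_proportion, parent_fraction) <= 1))
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate an annotated cohort of lung-sound recordings
#'
#' Draws patients (age group, pseudo-ID), one recording per auscultation
#' location per patient, per-recording wheeze status
#' Bernoulli(`wheeze_prevalence`) and quality Bernoulli
#' (`quality_proportion`), then synthesizes the audio: a breath-cycle
#' noise track, injected wheeze events for positives, and a high-gain
#' artifact for non-quality recordings. Fully deterministic under
#' `cfg$seed`.
#'
#' @param cfg [cohort_config()].
#' @param dir Optional output directory; when given, WAV files, one
#'   ICBHI-style annotation TSV per recording (`begin_s`, `end_s`,
#'   `label`), and `metadata.csv` are written there.
#' @param render_audio If `FALSE`, only metadata and ground-truth event
#'   tables are generated (fast; for calibration checks at large n).
#' @return List with `recordings` (list of [audio_recording], or `NULL`s
#'   when `render_audio = FALSE`), `annotations` (one data.frame of all
#'   ground-truth events), and `metadata` (one row per recording).
#' @export
simulate_cohort <- function(cfg = cohort_config(), dir = NULL,
                            render_audio = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    n_rec <- cfg$n_patients * length(LOCATIONS)
    age <- if (cfg$n_patients > 0)
      sample(AGE_GROUPS, cfg$n_patients, replace = TRUE, prob = cfg$age_group_mix)
      else character(0)
    meta <- if (n_rec > 0) data.frame(
      recording_id = sprintf("rec%04d", seq_len(n_rec)),
      patient_id = rep(sprintf("pt%03d", seq_len(cfg$n_patients)),
                       each = length(LOCATIONS)),
      age_group = rep(age, each = length(LOCATIONS)),
      location = rep(LOCATIONS, times = cfg$n_patients),
      collector = ifelse(runif(n_rec) < cfg$parent_fraction,
                         "parent", "physician"),
      quality = runif(n_rec) < cfg$quality_proportion,
      wheeze_truth = runif(n_rec) < cfg$wheeze_prevalence,
      duration_s = runif(n_rec, cfg$duration_range_s[1],
                         cfg$duration_range_s[2]),
      stringsAsFactors = FALSE
    ) else data.frame(recording_id = character(0), patient_id = character(0),
                      age_group = character(0), location = character(0),
                      collector = character(0), quality = logical(0),
                      wheeze_truth = logical(0), duration_s = numeric(0))
    meta$n_events <- ifelse(meta$wheeze_truth,
                            if (n_rec > 0) sample(seq(cfg$events_per_positive[1],
                                                      cfg$events_per_positive[2]),
                                                  n_rec, replace = TRUE) else integer(0),
                            0L)

    recordings <- vector("list", n_rec)
    ann_list <- vector("list", n_rec)
    for (i in seq_len(n_rec)) {
      events <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                           f0_hz = numeric(0), label = character(0))
      if (render_audio) {
        rr <- cfg$respiratory_rate_by_age[[meta$age_group[i]]]
        rec <- simulate_breath_cycle_track(meta$duration_s[i], rr,
                                           sample_rate_hz = cfg$sample_rate_hz,
                                           location = meta$location[i])
        rec$recording_id <- meta$recording_id[i]
        rec$patient_id <- meta$patient_id[i]
        rec$age_group <- meta$age_group[i]
        rec$collector <- meta$collector[i]
        rec$quality <- meta$quality[i]
        if (meta$n_events[i] > 0) {
          iw <- inject_wheeze(rec, meta$n_events[i], cfg$event_cfg)
          rec <- iw$recording
          events <- iw$events
        }
        if (!meta$quality[i])
          rec <- inject_artifact(rec, "speech_like", gain = 4)
        rec$quality <- meta$quality[i]  # flag stays the drawn ground truth
        recordings[[i]] <- rec
      } else if (meta$n_events[i] > 0) {
        # ground-truth intervals only (no waveform): reuse the packer
        host <- audio_recording(numeric(round(meta$duration_s[i] *
                                                cfg$sample_rate_hz)) + 0.01,
                                cfg$sample_rate_hz)
        events <- inject_wheeze(host, meta$n_events[i], cfg$event_cfg)$events
      }
      if (nrow(events) > 0) events$recording_id <- meta$recording_id[i]
      ann_list[[i]] <- events
    }
    ann <- do.call(rbind, ann_list)
    if (is.null(ann) || nrow(ann) == 0)
      ann <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                        f0_hz = numeric(0), label = character(0),
                        recording_id = character(0))
    ann <- ann[, c("recording_id", "onset_s", "offset_s", "f0_hz", "label")]

    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      # paths are stored relative to the cohort directory so manifests are
      # location-independent (and comparable across runs)
      meta$path <- if (n_rec > 0) paste0(meta$recording_id, ".wav")
                   else character(0)
      for (i in seq_len(n_rec)) {
        if (render_audio) write_wav(recordings[[i]], file.path(dir, meta$path[i]))
        ev <- ann[ann$recording_id == meta$recording_id[i],
                  c("onset_s", "offset_s", "label")]
        names(ev) <- c("begin_s", "end_s", "label")
        write.table(ev, file.path(dir, paste0(meta$recording_id[i], "_events.tsv")),
                    sep = "\t", row.names = FALSE, quote = FALSE)
      }
      write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
    }
    list(recordings = recordings, annotations = ann, metadata = meta)
  })
}

#' Read an ICBHI-style event annotation table
#'
#' Parses a tab-separated event table with begin/end timestamps and a
#' label column, the dialect used by the public respiratory-sound
#' databases and by [simulate_cohort()]'s output. Files without a header
#' row (plain `begin end label` or `begin end crackle wheeze` columns)
#' are handled.
#'
#' @param path TSV path.
#' @return data.frame with columns `begin_s`, `end_s`, `label`.
#' @export
read_event_annotations <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("begin", first, ignore.case = TRUE)
  d <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (has_header) {
    names(d)[1:2] <- c("begin_s", "end_s")
    if (!"label" %in% names(d)) d$label <- "event"
  } else if (ncol(d) >= 4 && all(vapply(d[, 3:4], is.numeric, TRUE))) {
    # ICBHI respiratory-cycle dialect: begin end crackles wheezes
    d <- data.frame(begin_s = d[[1]], end_s = d[[2]],
                    label = ifelse(d[[4]] > 0, "wheeze",
                                   ifelse(d[[3]] > 0, "crackle", "normal")))
  } else {
    d <- data.frame(begin_s = d[[1]], end_s = d[[2]],
                    label = if (ncol(d) >= 3) as.character(d[[3]]) else "event")
  }
  bad <- d$end_s <= d$begin_s
  if (any(bad)) stop("malformed events: end <= begin at row(s) ",
                     paste(which(bad), collapse = ", "))
  d[, c("begin_s", "end_s", "label")]
}
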