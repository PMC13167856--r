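#' Map window-level events onto the recording timeline
#'
#' Shifts each decoded event by its window offset, truncates events that
#' extend into the zero-padded tail at the recording duration, discards
#' events lying entirely inside the pad (the pad is appended silence, so
#' any detection there is a model artifact), and removes events that fall
#' below the minimum duration after truncation.
#'
#' @param window_events List of per-window event data.frames
#'   (`onset_s`, `offset_s` on the window timeline), one per window.
#' @param windows The `analysis_window` list from [segment_windows()]
#'   for the same recording.
#' @param duration_s True (unpadded) recording duration, seconds.
#' @param min_event_s Minimum surviving event duration.
#' @return data.frame with `onset_s`, `offset_s` on the recording
#'   timeline, sorted by onset.
#' @export
map_events_to_recording <- function(window_events, windows, duration_s,
                                    min_event_s = 0.1) {
  stopifnot(length(window_events) == length(windows))
  if (length(windows) > 1) {
    ids <- vapply(windows, `[[`, "", "parent_id")
    if (length(unique(ids)) != 1)
      stop("windows belong to different recordings: ",
           paste(unique(ids), collapse = ", "))
  }
  pieces <- lapply(seq_along(windows), function(i) {
    ev <- window_events[[i]]
    if (is.null(ev) || nrow(ev) == 0) return(NULL)
    off <- windows[[i]]$offset_s
    data.frame(onset_s = ev$onset_s + off, offset_s = ev$offset_s + off)
  })
  ev <- do.call(rbind, pieces)
  if (is.null(ev) || nrow(ev) == 0)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  ev <- ev[ev$onset_s < duration_s, , drop = FALSE]   # drop pad-only events
  ev$offset_s <- pmin(ev$offset_s, duration_s)        # truncate into the pad
  ev <- ev[ev$offset_s - ev$onset_s >= min_event_s - 1e-9, , drop = FALSE]
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Recording-level classification by the any-window rule
#'
#' A recording is classified as containing wheezes iff at least one
#' decoded event survives mapping onto the recording timeline in any of
#' its windows.
#'
#' @inheritParams map_events_to_recording
#' @return Object of class `detection_result`: `recording_id`,
#'   `window_flags` (one logical per window), `events` (recording
#'   timeline), `label` (logical).
#' @export
classify_recording <- function(window_events, windows, duration_s,
                               min_event_s = 0.1) {
  events <- map_events_to_recording(window_events, windows, duration_s,
                                    min_event_s)
  flags <- vapply(seq_along(windows), function(i) {
    off <- windows[[i]]$offset_s
    w_end <- off + windows[[i]]$window_s
    any(events$onset_s < w_end & events$offset_s > off)
  }, logical(1))
  structure(list(recording_id = windows[[1]]$parent_id,
                 window_flags = flags,
                 events = events,
                 label = any(flags)),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s: %s (%d event%s in %d window%s)\n",
              x$recording_id,
              if (x$label) "wheeze present" else "no wheeze",
              nrow(x$events), if (nrow(x$events) == 1) "" else "s",
              length(x$window_flags),
              if (length(x$window_flags) == 1) "" else "s"))
  if (nrow(x$events) > 0) print(x$events, row.names = FALSE)
  invisible(x)
}

#' Serialize detection results to a predictions table
#'
#' @param results List of `detection_result` objects (e.g. from
#'   [predict.wheeze_detector()]).
#' @return data.frame with `recording_id`, `label_pred`, `n_events`, and
#'   events serialized as `"onset-offset;..."`.
#' @export
predictions_table <- function(results) {
  data.frame(
    recording_id = vapply(results, `[[`, "", "recording_id"),
    label_pred = vapply(results, `[[`, logical(1), "label"),
    n_events = vapply(results, function(d) nrow(d$events), integer(1)),
    events = vapply(results, function(d) {
      if (nrow(d$events) == 0) return("")
      paste(sprintf("%.3f-%.3f", d$events$onset_s, d$events$offset_s),
            collapse = ";")
    }, ""),
    stringsAsFactors = FALSE
  )
}
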