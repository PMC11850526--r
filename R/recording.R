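#' Multi-channel ECoG recording container
#'
#' The central data structure of the package: a continuous multi-channel
#' voltage trace with its sampling rate, channel labels, named session
#' segments (baselines, trials, rests) and any spans excluded by artifact
#' rejection. Time is stored in seconds, 0-based from recording start.
#'
#' @param samples numeric matrix, time points in rows, channels in columns
#'   (voltages in microvolt).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per column.
#' @param segments data frame with columns `name`, `start_s`, `end_s`;
#'   the six canonical names are `baseline1`, `titration`, `baseline2`,
#'   `trial1`, `rest`, `trial2`, `trial3` (titration/rest are idle spans).
#' @param rejected_spans data frame with columns `start_s`, `end_s` of
#'   globally excluded time (may be `NULL`).
#' @param id subject identifier (mouse label), optional.
#' @param cohort cohort label, optional.
#' @return an object of class `ecog_recording`.
#' @export
recording <- function(samples, fs, channel_labels,
                      segments = NULL, rejected_spans = NULL,
                      id = NA_character_, cohort = NA_character_) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stopf("samples must be numeric")
  if (length(channel_labels) != ncol(samples))
    stopf("channel count (%d) != label count (%d)",
          ncol(samples), length(channel_labels))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stopf("fs must be a single positive number")
  colnames(samples) <- channel_labels
  dur <- nrow(samples) / fs
  if (!is.null(segments)) {
    stopifnot(all(c("name", "start_s", "end_s") %in% names(segments)))
    if (any(segments$start_s < 0) || any(segments$end_s > dur + 1 / fs))
      stopf("segment spans must lie within [0, %.3f] s", dur)
    if (any(segments$end_s <= segments$start_s))
      stopf("segment spans must have positive length")
    seg <- segments[order(segments$start_s), ]
    if (nrow(seg) > 1 && any(seg$start_s[-1] < seg$end_s[-nrow(seg)] - 1e-9))
      stopf("named segments must not overlap")
  }
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 segments = segments,
                 rejected_spans = rejected_spans,
                 id = id, cohort = cohort),
            class = "ecog_recording")
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %s%s: %d ch x %.1f s @ %g Hz\n",
              ifelse(is.na(x$id), "", paste0(x$id, " ")),
              ifelse(is.na(x$cohort), "", sprintf("(%s)", x$cohort)),
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs))
  if (!is.null(x$segments))
    cat("  segments:", paste(x$segments$name, collapse = ", "), "\n")
  nrej <- if (is.null(x$rejected_spans)) 0 else nrow(x$rejected_spans)
  if (nrej) cat(sprintf("  rejected spans: %d (%.1f s)\n", nrej,
                        sum(x$rejected_spans$end_s - x$rejected_spans$start_s)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `ecog_recording`.
#' @export
recording_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Restrict a recording to a subset of channels
#'
#' @param rec an `ecog_recording`.
#' @param channels character vector of labels to keep.
#' @export
subset_channels <- function(rec, channels) {
  missing <- setdiff(channels, rec$channel_labels)
  if (length(missing))
    stopf("channel(s) not in recording: %s", paste(missing, collapse = ", "))
  rec$samples <- rec$samples[, channels, drop = FALSE]
  rec$channel_labels <- channels
  rec
}

#' Look up a named segment span
#' @param rec an `ecog_recording`.
#' @param name segment name, e.g. `"trial1"`.
#' @return list with `start_s` and `end_s`.
#' @export
segment_span <- function(rec, name) {
  if (is.null(rec$segments)) stopf("recording has no segment map")
  i <- match(name, rec$segments$name)
  if (is.na(i)) stopf("no segment named '%s'", name)
  list(start_s = rec$segments$start_s[i], end_s = rec$segments$end_s[i])
}

#' Stimulus marker list
#'
#' @param onsets_s strictly ascending event onset times (seconds from
#'   recording start).
#' @param labels per-marker descriptor, `"light_on"` for real light pulses
#'   or `"virtual"` for segmentation-only markers (US-only cohort).
#' @return data frame of class `ecog_markers` with columns `onset_s`, `label`.
#' @export
marker_list <- function(onsets_s, labels = rep("light_on", length(onsets_s))) {
  if (length(onsets_s) != length(labels))
    stopf("onsets and labels differ in length")
  if (length(onsets_s) > 1 && any(diff(onsets_s) <= 0))
    stopf("marker onsets must be strictly ascending")
  structure(data.frame(onset_s = as.numeric(onsets_s),
                       label = as.character(labels),
                       stringsAsFactors = FALSE),
            class = c("ecog_markers", "data.frame"))
}

#' Convert a marker onset in seconds to a 1-based sample index
#'
#' BrainVision marker files store positions as 1-based sample indices;
#' this pair of helpers is the single place where that convention meets
#' the package's 0-based seconds.
#'
#' @param onset_s onset in seconds from recording start.
#' @param fs sampling rate in Hz.
#' @export
onset_to_sample <- function(onset_s, fs) as.integer(round(onset_s * fs)) + 1L

#' @rdname onset_to_sample
#' @param sample 1-based sample index.
#' @export
sample_to_onset <- function(sample, fs) (as.numeric(sample) - 1) / fs
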