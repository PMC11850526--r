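#' Running-RMS envelope of a signal
#'
#' `envelope[t] = sqrt(mean(x[w]^2))` over a moving window of `window_s`
#' seconds. The default alignment is centered, with the window truncated
#' at the edges so the envelope has the same length as the input; a
#' trailing alignment is available for sensitivity checks.
#'
#' @param x numeric signal.
#' @param window_s window length in seconds (0.25 by default).
#' @param fs sampling rate (Hz); `window_s * fs` must be at least 1 sample.
#' @param align `"centered"` (default) or `"trailing"`.
#' @return non-negative numeric vector, `length(x)`.
#' @export
running_rms <- function(x, window_s = 0.25, fs, align = c("centered", "trailing")) {
  align <- match.arg(align)
  w <- as.integer(round(window_s * fs))
  if (w < 1) stopf("window_s * fs must be >= 1 sample")
  n <- length(x)
  if (w > n) stopf("window (%d samples) longer than signal (%d)", w, n)
  cs <- c(0, cumsum(x^2))
  i <- seq_len(n)
  if (align == "centered") {
    lo <- pmax(1L, i - ((w - 1L) %/% 2L))
    hi <- pmin(n, i + (w %/% 2L))
  } else {
    lo <- pmax(1L, i - w + 1L)
    hi <- i
  }
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Cut a trial into stimulus-locked events
#'
#' One epoch per marker, starting at the marker onset and lasting
#' `event_period_s`; the running-RMS envelope is computed per epoch.
#' Epochs that intersect a rejected span are kept but flagged invalid
#' (`valid_mask = FALSE`) so every retained scalar averages over identical
#' support; markers too close to the end of the recording are dropped with
#' a warning count.
#'
#' @param rec a filtered [recording()] (single channel selected via
#'   `channel`).
#' @param markers an [marker_list()]; only markers inside the named trial
#'   segment are used.
#' @param trial trial number 1-3.
#' @param channel label of the analyzed channel (default the first).
#' @param event_period_s epoch duration (s).
#' @param window_s running-RMS window (s).
#' @param align envelope window alignment, see [running_rms()].
#' @return an `event_set`: list with `mouse_id`, `cohort`, `trial`,
#'   `channel`, `onsets_s`, `epochs` (events x samples), `envelopes`,
#'   `valid_mask`, `n_dropped_boundary`, `fs`.
#' @export
segment_events <- function(rec, markers, trial, channel = rec$channel_labels[1],
                           event_period_s = 10, window_s = 0.25,
                           align = "centered") {
  stopifnot(inherits(rec, "ecog_recording"), trial %in% 1:3)
  span <- segment_span(rec, paste0("trial", trial))
  x <- rec$samples[, channel]
  fs <- rec$fs
  on <- markers$onset_s[markers$onset_s >= span$start_s - 1e-9 &
                        markers$onset_s < span$end_s - 1e-9]
  n <- length(x)
  len <- as.integer(round(event_period_s * fs))
  fits <- as.integer(round(on * fs)) + len <= n
  n_drop <- sum(!fits)
  if (n_drop > 0)
    warning(sprintf("%d marker(s) within %g s of recording end dropped", n_drop,
                    event_period_s), call. = FALSE)
  on <- on[fits]
  nev <- length(on)
  epochs <- matrix(0, nev, len)
  envelopes <- matrix(0, nev, len)
  valid <- logical(nev)
  for (e in seq_len(nev)) {
    i0 <- as.integer(round(on[e] * fs)) + 1L
    seg <- x[i0:(i0 + len - 1L)]
    epochs[e, ] <- seg
    envelopes[e, ] <- running_rms(seg, window_s, fs, align = align)
    valid[e] <- span_overlap(on[e], on[e] + event_period_s,
                             rec$rejected_spans) <= 1e-9
  }
  structure(list(mouse_id = rec$id, cohort = rec$cohort, trial = trial,
                 channel = channel, onsets_s = on, epochs = epochs,
                 envelopes = envelopes, valid_mask = valid,
                 n_dropped_boundary = n_drop, fs = fs,
                 event_period_s = event_period_s),
            class = "event_set")
}

#' Reduce events to scalars over subsets of event length
#'
#' For each valid event and each subset length `k` (seconds), the scalar
#' is the mean of the running-RMS envelope over the first `k` seconds of
#' the event. These per-event scalars are the unit of all downstream
#' statistics.
#'
#' @param es an `event_set` from [segment_events()].
#' @param k_values integer subset lengths in seconds (default 1-10).
#' @return data frame with columns `mouse_id`, `cohort`, `trial`,
#'   `event_index`, `k`, `value`, `normalization_stage` (= `"raw"`).
#' @export
event_scalars <- function(es, k_values = 1:10) {
  stopifnot(inherits(es, "event_set"))
  if (any(k_values > es$event_period_s))
    stopf("k = %g exceeds event duration %g s", max(k_values),
          es$event_period_s)
  valid_idx <- which(es$valid_mask)
  rows <- lapply(k_values, function(k) {
    nk <- as.integer(round(k * es$fs))
    vals <- if (length(valid_idx))
      rowMeans(es$envelopes[valid_idx, seq_len(nk), drop = FALSE]) else numeric(0)
    data.frame(mouse_id = rep(es$mouse_id, length(valid_idx)),
               cohort = rep(es$cohort, length(valid_idx)),
               trial = rep(es$trial, length(valid_idx)),
               event_index = valid_idx, k = rep(k, length(valid_idx)),
               value = vals,
               normalization_stage = rep("raw", length(valid_idx)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-mouse median event value
#'
#' The median across valid events of the per-event scalar at one
#' `(mouse, trial, k)` cell — the per-mouse summary used for cohort
#' activity curves and as the Trial-1 normalization reference.
#'
#' @param table an event-scalar table.
#' @param mouse_id,trial,k cell selectors.
#' @return scalar median.
#' @export
median_event_value <- function(table, mouse_id, trial, k) {
  v <- table$value[table$mouse_id == mouse_id & table$trial == trial &
                   table$k == k]
  if (length(v) == 0)
    stopf("no valid events for mouse '%s', trial %d, k = %g", mouse_id,
          trial, k)
  median(v)
}

#' Write an event-scalar table as TSV
#' @param table event-scalar table.
#' @param path output file.
#' @export
write_event_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
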