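#' Band-pass filter specification
#'
#' Zero-phase Butterworth band-pass, 5-55 Hz by default, applied forward
#' and backward so the net phase response is zero. `order` is the
#' lowpass-prototype order per pass (4 by default, a common
#' electrophysiology choice; the band-pass transfer function is order
#' `2 * order`, and the forward-backward pass doubles the effective
#' magnitude roll-off again).
#'
#' @param low_hz,high_hz band edges (Hz), `0 < low < high < fs/2`.
#' @param order prototype filter order per pass.
#' @export
filter_spec <- function(low_hz = 5, high_hz = 55, order = 4) {
  if (low_hz <= 0 || high_hz <= low_hz) stopf("need 0 < low_hz < high_hz")
  if (order < 1) stopf("order must be >= 1")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order),
            class = "filter_spec")
}

# Butterworth band-pass designed as second-order sections: analog
# prototype poles -> lowpass-to-bandpass transform -> bilinear transform,
# conjugate pole pairs assembled into biquads with zeros at z = +/-1.
# Direct-form coefficients of the full-order filter are numerically
# unstable for narrow relative bands (e.g. 5-55 Hz at 20 kHz); the
# cascade is not.
butter_bandpass_sos <- function(order, low_hz, high_hz, fs) {
  if (high_hz >= fs / 2) stopf("high_hz (%g) must be < fs/2 (%g)", high_hz, fs / 2)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP unit circle
  wl <- 2 * fs * tan(pi * low_hz / fs)                       # prewarped edges
  wh <- 2 * fs * tan(pi * high_hz / fs)
  w0sq <- wl * wh
  B <- wh - wl
  poles <- unlist(lapply(proto, function(p) {
    d <- sqrt((p * B)^2 / 4 - w0sq)
    c(p * B / 2 + d, p * B / 2 - d)
  }))
  z <- (2 * fs + poles) / (2 * fs - poles)                   # bilinear
  pos <- z[Im(z) > 0]
  stopifnot(length(pos) == order)
  sos <- lapply(pos, function(p)
    list(b = c(1, 0, -1), a = c(1, -2 * Re(p), Mod(p)^2)))
  # unit gain at the geometric center frequency (Butterworth passband peak)
  wc <- 2 * pi * sqrt(low_hz * high_hz) / fs
  H1 <- function(ba) sum(ba$b * exp(-1i * wc * 0:2)) / sum(ba$a * exp(-1i * wc * 0:2))
  g <- prod(vapply(sos, function(s) Mod(H1(s)), 0))
  sos[[1]]$b <- sos[[1]]$b / g
  sos
}

sos_matrix <- function(sos)
  do.call(rbind, lapply(sos, function(s) c(s$b, s$a)))

# Forward-backward filtering through the SOS cascade (compiled biquad
# kernel). The signal is extended at both ends by odd reflection over
# `pad` samples so start-up transients decay outside the data; `pad`
# should cover several times the filter's impulse-response decay
# (~1/low_hz seconds).
sos_filtfilt <- function(sos, x, pad = 0L) {
  n <- length(x)
  pad <- min(as.integer(pad), n - 1L)
  m <- sos_matrix(sos)
  y <- if (pad > 0)
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  else x
  y <- .sosfilt(m, y)
  y <- rev(.sosfilt(m, rev(y)))
  if (pad > 0) y[(pad + 1):(pad + n)] else y
}

#' Zero-phase band-pass filter a recording
#'
#' Each channel is filtered forward and backward through a cascaded
#' second-order-section Butterworth band-pass, so the output has zero net
#' phase shift and the same length as the input.
#'
#' @param rec an [recording()].
#' @param spec a [filter_spec()].
#' @return the filtered recording.
#' @export
bandpass_zero_phase <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "ecog_recording"))
  if (rec$fs <= 2 * spec$high_hz)
    stopf("fs = %g Hz too low for a %g Hz band edge", rec$fs, spec$high_hz)
  sos <- butter_bandpass_sos(spec$order, spec$low_hz, spec$high_hz, rec$fs)
  pad <- as.integer(round(6 / spec$low_hz * rec$fs))
  for (ch in seq_len(ncol(rec$samples)))
    rec$samples[, ch] <- sos_filtfilt(sos, rec$samples[, ch], pad = pad)
  rec
}

#' Artifact-rejection specification
#'
#' High-amplitude data are excluded by a distribution-relative rule: the
#' recording is cut into consecutive non-overlapping windows of
#' `segment_len_s`, the RMS of each window is computed per channel, and
#' windows whose RMS exceeds `mean + k_sd x SD` of that channel's
#' window-RMS distribution are rejected. A window rejected on any analyzed
#' channel is rejected globally, so events stay aligned across channels.
#'
#' @param segment_len_s RMS evaluation window (s).
#' @param k_sd threshold in standard deviations (`Inf` disables rejection).
#' @export
rejection_spec <- function(segment_len_s = 1.0, k_sd = 4.0) {
  if (segment_len_s <= 0) stopf("segment_len_s must be > 0")
  if (!(k_sd > 0)) stopf("k_sd must be > 0")
  structure(list(segment_len_s = segment_len_s, k_sd = k_sd),
            class = "rejection_spec")
}

#' Mark high-RMS segments of a recording as rejected
#'
#' Applies the rule described in [rejection_spec()]. Rejected time is
#' marked by exclusion spans on the recording — samples are never spliced
#' out, so event timing is preserved. Because the threshold is relative to
#' the recording's own RMS distribution, rejection is invariant under
#' global amplitude rescaling.
#'
#' @param rec a (typically already filtered) [recording()].
#' @param spec a [rejection_spec()].
#' @return list with `recording` (rejected spans filled in, merged with
#'   any pre-existing ones) and `report` (one row per rejected window:
#'   channel, span_start_s, span_end_s, rms, threshold).
#' @export
reject_artifacts <- function(rec, spec = rejection_spec()) {
  stopifnot(inherits(rec, "ecog_recording"))
  L <- as.integer(round(spec$segment_len_s * rec$fs))
  n <- nrow(rec$samples)
  nseg <- n %/% L
  if (nseg < 1)
    stopf("recording (%.2f s) shorter than one %g-s rejection segment",
          n / rec$fs, spec$segment_len_s)
  report <- list()
  spans <- list()
  for (ch in seq_len(ncol(rec$samples))) {
    x <- rec$samples[seq_len(nseg * L), ch]
    seg_rms <- sqrt(colMeans(matrix(x^2, nrow = L)))
    thr <- if (is.finite(spec$k_sd))
      mean(seg_rms) + spec$k_sd * sd(seg_rms) else Inf
    bad <- which(seg_rms > thr)
    if (length(bad)) {
      df <- data.frame(channel = rec$channel_labels[ch],
                       span_start_s = (bad - 1) * spec$segment_len_s,
                       span_end_s = bad * spec$segment_len_s,
                       rms = seg_rms[bad], threshold = thr)
      report[[length(report) + 1]] <- df
      spans[[length(spans) + 1]] <- df[, c("span_start_s", "span_end_s")]
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(channel = character(0), span_start_s = numeric(0),
               span_end_s = numeric(0), rms = numeric(0),
               threshold = numeric(0))
  new_spans <- if (length(spans)) {
    sp <- do.call(rbind, spans)
    names(sp) <- c("start_s", "end_s")
    sp
  } else NULL
  all_spans <- rbind(rec$rejected_spans, new_spans)
  rec$rejected_spans <- merge_spans(all_spans)
  list(recording = rec, report = report)
}

#' Write an artifact-rejection report as TSV
#' @param report report data frame from [reject_artifacts()].
#' @param path output file.
#' @export
write_rejection_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
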