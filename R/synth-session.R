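#' Generate a pink-noise background trace
#'
#' Ongoing ECoG is emulated as 1/f-amplitude-weighted ("pink") Gaussian
#' noise, synthesized in the frequency domain (white spectrum scaled by
#' 1/sqrt(f), flat below 1 Hz to keep finite power) and normalized to unit
#' RMS before the gain is applied. An optional 60 Hz sinusoid emulates
#' line pickup.
#'
#' @param duration_s trace duration (s).
#' @param fs sampling rate (Hz).
#' @param background_gain amplitude multiplier (0 gives an all-zero trace).
#' @param line_noise_amp amplitude of an added 60 Hz sinusoid.
#' @param seed RNG seed; identical arguments give bit-identical traces.
#' @return numeric vector of `round(duration_s * fs)` samples.
#' @export
generate_background <- function(duration_s, fs, background_gain = 1,
                                line_noise_amp = 0, seed = 1L) {
  if (!is.finite(duration_s) || duration_s <= 0 || !is.finite(fs) || fs <= 0)
    stopf("duration_s and fs must be positive")
  n <- as.integer(round(duration_s * fs))
  # Long traces are synthesized in power-of-two blocks (fast FFT lengths)
  # joined by an equal-power half-cosine crossfade. Block synthesis only
  # alters spectral content below 1/block-duration Hz, far under the 1 Hz
  # flattening point, so the in-band (5-55 Hz) spectrum is unaffected.
  blk <- min(2^18, 2^ceiling(log2(max(n, 2))))
  ov <- if (n > blk) min(as.integer(fs), blk %/% 4L) else 0L
  pink_block <- function() {
    X <- fft(rnorm(blk))
    f <- seq(0, fs, length.out = blk + 1)[seq_len(blk)]
    f[f > fs / 2] <- fs - f[f > fs / 2]      # mirror to physical frequency
    amp <- 1 / sqrt(pmax(f, 1))              # pink above 1 Hz, flat below
    amp[1] <- 0                              # remove DC
    Re(fft(X * amp, inverse = TRUE)) / blk
  }
  x <- with_local_seed(seed, {
    out <- numeric(n)
    pos <- 1L
    prev_tail <- NULL
    wfade <- if (ov > 0) sin(seq(0, pi / 2, length.out = ov)) else NULL
    while (pos <= n) {
      b <- pink_block()
      if (!is.null(prev_tail)) {
        m <- length(prev_tail)
        b[seq_len(m)] <- prev_tail * sqrt(1 - wfade[seq_len(m)]^2) +
          b[seq_len(m)] * wfade[seq_len(m)]
      }
      take <- min(blk - ov, n - pos + 1L)
      out[pos:(pos + take - 1L)] <- b[seq_len(take)]
      prev_tail <- if (ov > 0 && take == blk - ov) b[(blk - ov + 1L):blk] else NULL
      pos <- pos + take
    }
    out
  })
  r <- sqrt(mean(x^2))
  if (r > 0) x <- x / r
  x <- x * background_gain
  if (line_noise_amp > 0) {
    t <- (seq_len(n) - 1) / fs
    x <- x + line_noise_amp * sin(2 * pi * 60 * t)
  }
  x
}

#' Render the evoked-response waveform
#'
#' Evaluates a [vep_kernel()] at sampling rate `fs`, normalizes its peak
#' absolute value to 1, and scales by `amplitude`. The waveform is zero
#' before the kernel's onset latency and its support never exceeds 4 s,
#' so evoked energy stays inside each 10-s event.
#'
#' @param kernel a [vep_kernel()].
#' @param amplitude peak absolute amplitude (microvolt); must be >= 0.
#' @param fs sampling rate (Hz).
#' @return numeric vector of `round(support_s * fs)` samples.
#' @export
render_vep <- function(kernel, amplitude, fs) {
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (kernel$freq_hz <= 0 || kernel$freq_hz >= fs / 2)
    stopf("kernel frequency %g Hz outside (0, fs/2)", kernel$freq_hz)
  n <- as.integer(round(kernel$support_s * fs))
  t <- (seq_len(n) - 1) / fs
  tt <- t - kernel$onset_s
  h <- ifelse(tt < 0, 0,
              sin(2 * pi * kernel$freq_hz * tt) * exp(-tt / kernel$decay_s))
  pk <- max(abs(h))
  if (pk > 0) h <- h / pk
  h * amplitude
}

#' Generate one complete synthetic session
#'
#' Builds a contiguous recording covering baseline 1, the titration gap,
#' baseline 2, Trial 1, the 4-minute rest, and Trials 2-3, with one event
#' marker per `event_period_s` in each trial (60 per trial at defaults).
#' Evoked waveforms are added at each marker with amplitude
#' `vep_amplitude_uv x trial gain x mouse scale x lognormal event jitter`
#' (full weight on visual channels, 0.4 on somatosensory channels);
#' artifact bursts arrive as a Poisson process and are recorded in the
#' ground truth. US-only sessions carry `"virtual"` markers (segmentation
#' only, no evoked response).
#'
#' @param config a [session_config()].
#' @param effect an [effect_model()]; defaults to the cohort's standard
#'   model.
#' @param seed RNG seed; defaults to the config's seed.
#' @return list with elements `recording` ([recording()]), `markers`
#'   ([marker_list()]), and `ground_truth` (per-event true amplitudes,
#'   artifact spans, mouse scale, configuration echoes).
#' @export
generate_session <- function(config,
                             effect = cohort_effect_model(config$cohort),
                             seed = config$seed) {
  stopifnot(inherits(config, "session_config"), inherits(effect, "effect_model"))
  validate_cohort_effect(config$cohort, effect)
  fs <- config$fs
  seg_durs <- c(baseline1 = config$baseline1_s,
                titration = config$titration_gap_s,
                baseline2 = config$baseline2_s,
                trial1 = config$trial_s,
                rest = config$rest_after_trial1_s,
                trial2 = config$trial_s,
                trial3 = config$trial_s)
  seg_start <- cumsum(c(0, unname(seg_durs)))[seq_along(seg_durs)]
  names(seg_start) <- names(seg_durs)
  total_s <- sum(seg_durs)
  n <- as.integer(round(total_s * fs))
  nev <- as.integer(round(config$trial_s / config$event_period_s))

  # background gain profile: trial multipliers, 1 elsewhere
  profile <- rep(1, n)
  for (tr in 1:3) {
    nm <- paste0("trial", tr)
    i0 <- as.integer(round(seg_start[nm] * fs)) + 1L
    i1 <- as.integer(round((seg_start[nm] + seg_durs[nm]) * fs))
    profile[i0:i1] <- effect$background_gain_by_trial[tr]
  }

  samples <- matrix(0, nrow = n, ncol = config$n_channels,
                    dimnames = list(NULL, config$channel_labels))
  for (ch in seq_len(config$n_channels)) {
    bg <- generate_background(total_s, fs, background_gain = 1,
                              line_noise_amp = 0,
                              seed = derive_seed(seed, "bg", ch))
    samples[, ch] <- bg * profile * effect$background_rms_uv
    if (effect$line_noise_amp > 0) {
      ph <- with_local_seed(derive_seed(seed, "line", ch), runif(1, 0, 2 * pi))
      t <- (seq_len(n) - 1) / fs
      samples[, ch] <- samples[, ch] +
        effect$line_noise_amp * sin(2 * pi * 60 * t + ph)
    }
  }

  # evoked responses
  mouse_scale <- with_local_seed(derive_seed(seed, "mouse"),
                                 exp(rnorm(1, 0, effect$mouse_scale_sd)))
  kern <- render_vep(effect$vep_kernel, 1, fs)
  ch_weight <- ifelse(startsWith(config$channel_labels, "S"), 0.4, 1)
  onsets <- numeric(0); labels <- character(0)
  amp_tab <- vector("list", 3)
  for (tr in 1:3) {
    t0 <- seg_start[paste0("trial", tr)]
    ev_on <- t0 + (seq_len(nev) - 1) * config$event_period_s
    onsets <- c(onsets, ev_on)
    labels <- c(labels,
                rep(if (config$cohort == "US-only") "virtual" else "light_on",
                    nev))
    jit <- with_local_seed(derive_seed(seed, "jitter", tr),
                           exp(rnorm(nev, 0, effect$event_jitter_sd)))
    amps <- effect$vep_amplitude_uv * effect$vep_gain_by_trial[tr] *
      mouse_scale * jit
    amp_tab[[tr]] <- data.frame(trial = tr, event_index = seq_len(nev),
                                onset_s = ev_on, amplitude = amps)
    if (any(amps > 0)) {
      for (e in seq_len(nev)) {
        i0 <- as.integer(round(ev_on[e] * fs)) + 1L
        idx <- i0:(i0 + length(kern) - 1L)
        keep <- idx <= n
        for (ch in seq_len(config$n_channels))
          samples[idx[keep], ch] <- samples[idx[keep], ch] +
            amps[e] * ch_weight[ch] * kern[keep]
      }
    }
  }

  # artifact bursts: Poisson arrivals, 0.5-s half-sine envelope on an
  # in-band 23 Hz carrier, hitting all channels simultaneously
  burst_len_s <- 0.5
  n_art <- with_local_seed(derive_seed(seed, "nart"),
                           rpois(1, effect$artifact_rate * total_s / 60))
  art_spans <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (n_art > 0 && effect$artifact_gain > 0) {
    starts <- with_local_seed(derive_seed(seed, "artpos"),
                              sort(runif(n_art, 0, total_s - burst_len_s)))
    nb <- as.integer(round(burst_len_s * fs))
    tau <- (seq_len(nb) - 1) / fs
    burst <- effect$artifact_gain * effect$background_rms_uv *
      sin(pi * tau / burst_len_s) * sin(2 * pi * 23 * tau)
    for (s0 in starts) {
      i0 <- as.integer(round(s0 * fs)) + 1L
      idx <- i0:(i0 + nb - 1L)
      keep <- idx <= n
      samples[idx[keep], ] <- samples[idx[keep], ] + burst[keep]
    }
    art_spans <- data.frame(start_s = starts, end_s = starts + burst_len_s)
  }

  segs <- data.frame(name = names(seg_durs),
                     start_s = unname(seg_start),
                     end_s = unname(seg_start + seg_durs),
                     stringsAsFactors = FALSE)
  rec <- recording(samples, fs, config$channel_labels, segments = segs,
                   id = config$mouse_id, cohort = config$cohort)
  list(recording = rec,
       markers = marker_list(onsets, labels),
       ground_truth = list(mouse_id = config$mouse_id,
                           cohort = config$cohort,
                           seed = seed,
                           mouse_scale = mouse_scale,
                           event_amplitudes = do.call(rbind, amp_tab),
                           artifact_spans = art_spans,
                           config = config, effect = effect,
                           synthetic = TRUE))
}

#' Generate a cohort of independent synthetic sessions
#'
#' Each mouse gets its own seed derived from the master seed, the cohort
#' label and the mouse index, so different cohorts under the same master
#' seed are independent. Default sizes follow the study: 7 mice in the
#' light-stimulated cohorts, 6 in the US-only cohort.
#'
#' @param cohort cohort label.
#' @param n_mice number of mice.
#' @param config_overrides named list of [session_config()] arguments
#'   applied to every mouse (e.g. `list(fs = 500, trial_s = 120)`).
#' @param effect an [effect_model()]; default the cohort's standard model.
#' @param seed master seed.
#' @return list of sessions as returned by [generate_session()].
#' @export
generate_cohort <- function(cohort = c("US+Light", "Light-only", "US-only"),
                            n_mice = NULL, config_overrides = list(),
                            effect = NULL, seed = 1L) {
  cohort <- match.arg(cohort)
  if (is.null(n_mice)) n_mice <- if (cohort == "US-only") 6L else 7L
  if (n_mice < 1) stopf("n_mice must be >= 1")
  if (is.null(effect)) effect <- cohort_effect_model(cohort)
  tag <- c("US+Light" = "usl", "Light-only" = "lo", "US-only" = "uso")[cohort]
  lapply(seq_len(n_mice), function(i) {
    cfg <- do.call(session_config, modifyList(
      list(mouse_id = sprintf("%s%02d", tag, i), cohort = cohort,
           seed = derive_seed(seed, cohort, i)),
      config_overrides))
    generate_session(cfg, effect = effect)
  })
}
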