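#' Session configuration for the synthetic experiment
#'
#' Describes the timeline of one recording session: a first dark baseline,
#' an idle titration gap, a second baseline, then three 10-minute trials
#' (Trial 1 light only, Trial 2 light and/or ultrasound, Trial 3 light only)
#' with one 0.1-s light pulse every 10 s, and a 4-minute rest between
#' Trials 1 and 2. Defaults follow the study timeline; the default sampling
#' rate is 2 kHz (the analysis band tops out at 55 Hz, so 2 kHz keeps an
#' 18x Nyquist margin), with 20 kHz supported to match the acquisition rate.
#'
#' @param mouse_id subject label.
#' @param cohort one of `"US+Light"`, `"Light-only"`, `"US-only"`.
#' @param fs sampling rate in Hz; must be at least 4x the 2 x 55 Hz band edge.
#' @param n_channels number of electrodes.
#' @param channel_labels electrode labels (visual and somatosensory pairs).
#' @param baseline1_s,baseline2_s baseline durations (s).
#' @param titration_gap_s idle gap emulating the light-titration period
#'   (default 737 s, the study's mean 12.29 min).
#' @param trial_s trial duration (s); must be an exact multiple of
#'   `event_period_s`.
#' @param rest_after_trial1_s rest between Trials 1 and 2 (s).
#' @param event_period_s inter-stimulus interval (s).
#' @param stim_duration_s light pulse duration (s).
#' @param seed per-session RNG seed.
#' @return a `session_config` list.
#' @export
session_config <- function(mouse_id = "m01",
                           cohort = c("US+Light", "Light-only", "US-only"),
                           fs = 2000, n_channels = 4,
                           channel_labels = c("V1L", "V1R", "S1L", "S1R"),
                           baseline1_s = 300, titration_gap_s = 737,
                           baseline2_s = 300, trial_s = 600,
                           rest_after_trial1_s = 240,
                           event_period_s = 10, stim_duration_s = 0.1,
                           seed = 1L) {
  cohort <- match.arg(cohort)
  durs <- c(baseline1_s, titration_gap_s, baseline2_s, trial_s,
            rest_after_trial1_s, event_period_s, stim_duration_s)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stopf("all durations must be strictly positive")
  if (fs < 2 * 55 * 4)
    stopf("fs = %g Hz too low: need >= %g Hz (4x the 55 Hz band edge Nyquist)",
          fs, 2 * 55 * 4)
  if (abs(trial_s / event_period_s - round(trial_s / event_period_s)) > 1e-9)
    stopf("trial_s (%g) must be an integer multiple of event_period_s (%g)",
          trial_s, event_period_s)
  channel_labels <- channel_labels[seq_len(n_channels)]
  if (anyNA(channel_labels))
    stopf("need %d channel labels, got %d", n_channels,
          sum(!is.na(channel_labels)))
  structure(list(mouse_id = mouse_id, cohort = cohort, fs = fs,
                 n_channels = n_channels, channel_labels = channel_labels,
                 baseline1_s = baseline1_s, titration_gap_s = titration_gap_s,
                 baseline2_s = baseline2_s, trial_s = trial_s,
                 rest_after_trial1_s = rest_after_trial1_s,
                 event_period_s = event_period_s,
                 stim_duration_s = stim_duration_s,
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Evoked-response kernel descriptor
#'
#' The visually evoked transient is modelled as a damped oscillation:
#' zero until `onset_s`, then `sin(2 pi f t) * exp(-t / decay_s)`,
#' truncated at `support_s` (at most 4 s, the longest light-induced
#' activity the analysis assumes). The oscillation frequency must sit
#' inside the 5-55 Hz analysis band so the band-pass preserves the
#' response.
#'
#' @param onset_s response latency after the light pulse (s).
#' @param freq_hz oscillation frequency (Hz), inside (5, 55).
#' @param decay_s exponential decay time constant (s).
#' @param support_s total kernel support (s), capped at 4.
#' @export
vep_kernel <- function(onset_s = 0.05, freq_hz = 15, decay_s = 0.5,
                       support_s = 4) {
  if (support_s > 4 + 1e-9) stopf("kernel support must be <= 4 s")
  if (decay_s <= 0 || onset_s < 0 || support_s <= onset_s)
    stopf("invalid kernel timing")
  structure(list(onset_s = onset_s, freq_hz = freq_hz, decay_s = decay_s,
                 support_s = support_s), class = "vep_kernel")
}

#' Effect model: what the stimulation does to the signal
#'
#' Per-trial multipliers for the evoked-response amplitude and the ongoing
#' background amplitude, plus the nuisance structure: per-mouse lognormal
#' amplitude scale (the sole downstream trace of the light titration),
#' per-event lognormal jitter (so roughly half the events are weak,
#' mirroring the ~50% response-rate titration goal), sparse high-amplitude
#' artifact bursts, and optional 60 Hz line noise. The ultrasound effect is
#' represented only through the Trial-2/3 multipliers; no acoustics are
#' modelled.
#'
#' @param vep_gain_by_trial three multipliers on evoked amplitude (Trials
#'   1-3). Must be all zero for the US-only cohort (no blinking light).
#' @param background_gain_by_trial three multipliers on ongoing activity.
#' @param vep_kernel a [vep_kernel()].
#' @param vep_amplitude_uv evoked peak amplitude (microvolt) at gain 1,
#'   mouse scale 1, jitter 1.
#' @param background_rms_uv ongoing (pink-noise) background RMS (microvolt).
#' @param mouse_scale_sd lognormal SD of per-mouse amplitude variability.
#' @param event_jitter_sd lognormal SD of per-event amplitude jitter.
#' @param artifact_rate expected artifact bursts per minute.
#' @param artifact_gain burst amplitude as a multiple of background RMS.
#' @param line_noise_amp 60 Hz line amplitude (microvolt), 0 to disable.
#' @export
effect_model <- function(vep_gain_by_trial = c(1, 1, 1),
                         background_gain_by_trial = c(1, 1, 1),
                         vep_kernel = ecogrms::vep_kernel(),
                         vep_amplitude_uv = 300,
                         background_rms_uv = 50,
                         mouse_scale_sd = 0.2,
                         event_jitter_sd = 0.3,
                         artifact_rate = 0.5,
                         artifact_gain = 20,
                         line_noise_amp = 0) {
  stopifnot(length(vep_gain_by_trial) == 3,
            length(background_gain_by_trial) == 3)
  if (any(vep_gain_by_trial < 0) || any(background_gain_by_trial < 0) ||
      artifact_gain < 0 || vep_amplitude_uv < 0 || background_rms_uv < 0)
    stopf("all gains must be >= 0")
  if (artifact_rate < 0 || line_noise_amp < 0)
    stopf("artifact_rate and line_noise_amp must be >= 0")
  structure(list(vep_gain_by_trial = vep_gain_by_trial,
                 background_gain_by_trial = background_gain_by_trial,
                 vep_kernel = vep_kernel,
                 vep_amplitude_uv = vep_amplitude_uv,
                 background_rms_uv = background_rms_uv,
                 mouse_scale_sd = mouse_scale_sd,
                 event_jitter_sd = event_jitter_sd,
                 artifact_rate = artifact_rate,
                 artifact_gain = artifact_gain,
                 line_noise_amp = line_noise_amp),
            class = "effect_model")
}

#' Default effect model for each cohort
#'
#' Encodes the qualitative pattern the experiment is designed around:
#' the US+Light cohort's evoked response is enhanced during Trial 2
#' (ultrasound on) and partially maintained in Trial 3; the Light-only
#' cohort habituates slowly across trials; the US-only cohort sees no
#' light (evoked gain identically zero) and its ongoing activity drops
#' after the exposure trial.
#'
#' @param cohort cohort label.
#' @param ... overrides passed on to [effect_model()].
#' @export
cohort_effect_model <- function(cohort = c("US+Light", "Light-only", "US-only"),
                                ...) {
  cohort <- match.arg(cohort)
  base <- switch(cohort,
    "US+Light"   = list(vep_gain_by_trial = c(1, 1.5, 1.2),
                        background_gain_by_trial = c(1, 1, 1)),
    "Light-only" = list(vep_gain_by_trial = c(1, 0.85, 0.8),
                        background_gain_by_trial = c(1, 1, 1)),
    "US-only"    = list(vep_gain_by_trial = c(0, 0, 0),
                        background_gain_by_trial = c(1, 1, 0.85)))
  do.call(effect_model, modifyList(base, list(...)))
}

validate_cohort_effect <- function(cohort, effect) {
  if (cohort == "US-only" && any(effect$vep_gain_by_trial != 0))
    stopf("US-only cohort sees no blinking light: vep_gain_by_trial must be 0")
  invisible(TRUE)
}
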