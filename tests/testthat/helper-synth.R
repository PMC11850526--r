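# Shared fixtures: small, fast synthetic sessions (fs 500 Hz, short inert
# spans) built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

small_overrides <- function(...) {
  modifyList(list(fs = 500, baseline1_s = 20, titration_gap_s = 5,
                  baseline2_s = 70, trial_s = 60, rest_after_trial1_s = 10),
             list(...))
}

small_session <- function(seed = 7, cohort = "US+Light", effect = NULL, ...) {
  key <- paste("sess", seed, cohort, deparse(substitute(effect)),
               paste(deparse(list(...)), collapse = ""), collapse = "_")
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  cfg <- do.call(session_config,
                 modifyList(small_overrides(...),
                            list(mouse_id = paste0("m", seed), cohort = cohort,
                                 seed = seed)))
  s <- if (is.null(effect)) generate_session(cfg)
       else generate_session(cfg, effect = effect)
  .fixtures[[key]] <- s
  s
}

# One small session taken through filtering + rejection, memoized.
small_conditioned <- function(seed = 7, cohort = "US+Light") {
  key <- paste("cond", seed, cohort)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  s <- small_session(seed, cohort)
  rec <- subset_channels(s$recording, "V1L")
  rec <- bandpass_zero_phase(rec)
  rj <- reject_artifacts(rec)
  out <- list(session = s, recording = rj$recording, report = rj$report)
  .fixtures[[key]] <- out
  out
}

# Scalar table for one conditioned session across all three trials.
small_table <- function(seed = 7, cohort = "US+Light", k_values = 1:10) {
  key <- paste("tab", seed, cohort, paste(k_values, collapse = ","))
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  cd <- small_conditioned(seed, cohort)
  tb <- do.call(rbind, lapply(1:3, function(tr)
    event_scalars(segment_events(cd$recording, cd$session$markers, tr),
                  k_values)))
  .fixtures[[key]] <- tb
  tb
}

# Brute-force windowed RMS: the independent oracle for running_rms.
naive_running_rms <- function(x, window_s, fs, align = "centered") {
  w <- as.integer(round(window_s * fs))
  n <- length(x)
  vapply(seq_len(n), function(i) {
    if (align == "centered") {
      lo <- max(1, i - ((w - 1) %/% 2)); hi <- min(n, i + (w %/% 2))
    } else {
      lo <- max(1, i - w + 1); hi <- i
    }
    sqrt(mean(x[lo:hi]^2))
  }, 0)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (midranks), independent of the package implementation.
enum_mwu_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- combn(m + n, m)
  U_all <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mean(abs(U_all - m * n / 2) >= abs(U_obs - m * n / 2) - 1e-9)
}

# Kruskal-Wallis H from the rank-sum definition with midranks and tie
# correction, computed directly from the formula.
hand_kw_H <- function(groups) {
  allv <- unlist(groups)
  N <- length(allv)
  r <- rank(allv)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(g)
      lengths(groups)[g] * (mean(r[idx == g]) - (N + 1) / 2)^2, 0))
  ties <- table(allv)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
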