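test_that("background generator is deterministic, unit-RMS, and zero at zero gain", {
  a <- generate_background(10, 500, seed = 3)
  b <- generate_background(10, 500, seed = 3)
  expect_identical(a, b)
  expect_length(a, 5000)
  expect_equal(sqrt(mean(a^2)), 1, tolerance = 1e-12)

  z <- generate_background(10, 500, background_gain = 0, seed = 3)
  expect_true(all(z == 0))

  long <- generate_background(60, 2000, background_gain = 1, seed = 9)
  expect_lt(abs(sqrt(mean(long^2)) - 1), 0.05)

  expect_error(generate_background(-1, 500), "positive")
  expect_error(generate_background(10, 0), "positive")
})

test_that("background spectrum is 1/f-weighted in the analysis band", {
  x <- generate_background(120, 2000, seed = 21)
  sp <- spec.pgram(ts(x, frequency = 2000), spans = 101, plot = FALSE)
  lowband <- mean(sp$spec[sp$freq > 5 & sp$freq < 10])
  highband <- mean(sp$spec[sp$freq > 40 & sp$freq < 50])
  # 1/f power: expected ratio ~ mean(1/f on 5-10)/mean(1/f on 40-50) ~ 6.2
  expect_gt(lowband / highband, 4)
  expect_lt(lowband / highband, 10)
})

test_that("rendered evoked waveform is linear in amplitude and time-bounded", {
  k <- vep_kernel()
  w0 <- render_vep(k, 0, 500)
  expect_true(all(w0 == 0))
  w1 <- render_vep(k, 1, 500)
  w2 <- render_vep(k, 2, 500)
  expect_equal(w2, 2 * w1)
  expect_lte(length(w1), 4 * 500)
  expect_equal(max(abs(w1)), 1)
  expect_error(render_vep(vep_kernel(freq_hz = 400), 1, 500), "outside")
  expect_error(render_vep(k, -1, 500), ">= 0")
  expect_error(vep_kernel(support_s = 5), "4 s")
})

test_that("kernel energy is concentrated early and inside the 5-55 Hz band", {
  fs <- 2000
  w <- render_vep(vep_kernel(decay_s = 0.5), 1, fs)
  e <- cumsum(w^2) / sum(w^2)
  expect_gte(e[2 * fs], 0.95)  # >= 95% of energy in the first 2 s

  W <- abs(fft(w))^2
  f <- seq(0, fs, length.out = length(w) + 1)[seq_along(w)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  inband <- sum(W[f >= 5 & f <= 55]) / sum(W)
  expect_gte(inband, 0.90)
})

test_that("sessions have the full timeline, exact marker arithmetic, and ground truth", {
  s <- small_session(seed = 7)
  rec <- s$recording
  expect_s3_class(rec, "ecog_recording")
  expect_identical(rec$segments$name,
                   c("baseline1", "titration", "baseline2", "trial1", "rest",
                     "trial2", "trial3"))
  nev <- 60 / 10 * (60 / 60)  # floor(trial_s / event_period_s) with trial_s = 60
  expect_identical(nrow(s$markers), 3L * 6L)
  for (tr in 1:3) {
    sp <- segment_span(rec, paste0("trial", tr))
    on <- s$markers$onset_s[s$markers$onset_s >= sp$start_s &
                            s$markers$onset_s < sp$end_s]
    expect_length(on, 6)
    expect_equal(diff(on), rep(10, 5))
  }
  gt <- s$ground_truth
  expect_equal(nrow(gt$event_amplitudes), 18)
  expect_true(all(gt$event_amplitudes$amplitude >= 0))
})

test_that("session generation is bit-deterministic given (config, seed)", {
  a <- generate_session(session_config(fs = 500, baseline1_s = 20,
                                       titration_gap_s = 5, baseline2_s = 70,
                                       trial_s = 60, rest_after_trial1_s = 10,
                                       seed = 13))
  b <- generate_session(session_config(fs = 500, baseline1_s = 20,
                                       titration_gap_s = 5, baseline2_s = 70,
                                       trial_s = 60, rest_after_trial1_s = 10,
                                       seed = 13))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$ground_truth$event_amplitudes, b$ground_truth$event_amplitudes)
})

test_that("doubling the evoked gain doubles ground-truth amplitudes exactly", {
  ov <- small_overrides()
  cfg <- do.call(session_config, c(ov, list(seed = 5)))
  e1 <- cohort_effect_model("US+Light", artifact_rate = 0)
  e2 <- cohort_effect_model("US+Light", artifact_rate = 0,
                            vep_gain_by_trial = 2 * e1$vep_gain_by_trial)
  a1 <- generate_session(cfg, effect = e1)$ground_truth$event_amplitudes
  a2 <- generate_session(cfg, effect = e2)$ground_truth$event_amplitudes
  expect_equal(a2$amplitude, 2 * a1$amplitude)
})

test_that("trial gains shape mean evoked amplitudes in proportion", {
  gains <- c(1, 1.5, 1.2)
  eff <- cohort_effect_model("US+Light", vep_gain_by_trial = gains,
                             artifact_rate = 0)
  amps <- lapply(1:20, function(i) {
    cfg <- do.call(session_config, c(small_overrides(),
                                     list(seed = 3000 + i)))
    gt <- generate_session(cfg, effect = eff)$ground_truth$event_amplitudes
    tapply(gt$amplitude, gt$trial, mean)
  })
  m <- colMeans(do.call(rbind, amps))
  expect_equal(unname(m / m[1]), gains, tolerance = 0.15)
})

test_that("US-only sessions emit virtual markers and reject nonzero light gain", {
  s <- small_session(seed = 11, cohort = "US-only")
  expect_true(all(s$markers$label == "virtual"))
  expect_true(all(s$ground_truth$event_amplitudes$amplitude == 0))
  expect_error(
    generate_session(do.call(session_config,
                             c(small_overrides(), list(cohort = "US-only"))),
                     effect = cohort_effect_model("US+Light")),
    "US-only")
})

test_that("zero evoked gain leaves event epochs indistinguishable from idle spans", {
  eff <- effect_model(vep_gain_by_trial = c(0, 0, 0), artifact_rate = 0)
  cfg <- do.call(session_config, c(small_overrides(), list(seed = 23)))
  s <- generate_session(cfg, effect = eff)
  rec <- subset_channels(s$recording, "V1L")
  sp1 <- segment_span(rec, "trial1")
  spb <- segment_span(rec, "baseline2")
  fs <- rec$fs
  rms_tr <- sqrt(mean(rec$samples[(sp1$start_s * fs + 1):(sp1$end_s * fs), 1]^2))
  rms_bl <- sqrt(mean(rec$samples[(spb$start_s * fs + 1):(spb$end_s * fs), 1]^2))
  expect_equal(rms_tr / rms_bl, 1, tolerance = 0.1)
})

test_that("cohorts derive distinct per-mouse seeds and honor default sizes", {
  co <- generate_cohort("US+Light", n_mice = 2,
                        config_overrides = small_overrides(), seed = 42)
  expect_length(co, 2)
  seeds <- vapply(co, function(s) s$ground_truth$seed, 0L)
  expect_length(unique(seeds), 2)
  # same master seed, different cohort label -> different mouse seeds
  expect_false(derive_seed(42, "US+Light", 1) == derive_seed(42, "Light-only", 1))
  # a one-mouse cohort equals generate_session at the derived seed
  one <- generate_cohort("Light-only", n_mice = 1,
                         config_overrides = small_overrides(), seed = 42)
  direct <- generate_session(
    do.call(session_config,
            modifyList(small_overrides(),
                       list(mouse_id = "lo01", cohort = "Light-only",
                            seed = derive_seed(42, "Light-only", 1)))),
    effect = cohort_effect_model("Light-only"))
  expect_identical(one[[1]]$recording$samples, direct$recording$samples)
})
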