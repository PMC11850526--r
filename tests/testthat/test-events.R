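test_that("running RMS of simple signals has closed-form values", {
  expect_equal(running_rms(rep(3, 100), 0.1, 100), rep(3, 100))
  expect_equal(running_rms(rep(-2.5, 50), 0.2, 50), rep(2.5, 50))
  # two samples, window covering both: sqrt((9 + 16) / 2)
  env <- running_rms(c(3, -4), 1, 2)
  expect_equal(env[1], sqrt(12.5))
  env_tr <- running_rms(c(3, -4), 1, 2, align = "trailing")
  expect_equal(env_tr[2], sqrt(12.5))
})

test_that("running RMS equals the brute-force windowed loop on any input", {
  set.seed(41)
  cases <- list(
    list(x = rnorm(500), w = 0.25, fs = 200),
    list(x = rnorm(1000) * 50, w = 0.25, fs = 2000),
    list(x = runif(333, -3, 3), w = 0.11, fs = 100),
    list(x = sin(2 * pi * 5 * seq(0, 2, by = 1 / 250)), w = 0.5, fs = 250))
  for (cs in cases) for (al in c("centered", "trailing")) {
    got <- running_rms(cs$x, cs$w, cs$fs, align = al)
    want <- naive_running_rms(cs$x, cs$w, cs$fs, align = al)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("running RMS rejects windows longer than the signal", {
  expect_error(running_rms(rnorm(10), 1, 100), "longer than signal")
  expect_error(running_rms(rnorm(10), 0.0001, 100), ">= 1 sample")
})

test_that("trials segment into one epoch per marker with exact duration", {
  cd <- small_conditioned(seed = 7)
  es <- segment_events(cd$recording, cd$session$markers, 1)
  expect_identical(nrow(es$epochs), 6L)
  expect_identical(ncol(es$epochs), as.integer(10 * cd$recording$fs))
  expect_true(all(es$envelopes >= 0))
  # 600-s trial at one event per 10 s gives 60 epochs
  ov <- small_overrides(trial_s = 600)
  cfg <- do.call(session_config, c(ov, list(seed = 3)))
  s <- generate_session(cfg, effect = cohort_effect_model("US+Light",
                                                          artifact_rate = 0))
  rec <- subset_channels(s$recording, "V1L")
  es60 <- segment_events(rec, s$markers, 1)
  expect_identical(nrow(es60$epochs), 60L)
})

test_that("epochs intersecting rejected spans are flagged invalid", {
  s <- small_session(seed = 7, effect = cohort_effect_model("US+Light",
                                                            artifact_rate = 0))
  rec <- subset_channels(s$recording, "V1L")
  sp <- segment_span(rec, "trial1")
  # plant a rejected span inside epoch 3 of trial 1
  rec$rejected_spans <- data.frame(start_s = sp$start_s + 24,
                                   end_s = sp$start_s + 25)
  es <- segment_events(rec, s$markers, 1)
  expect_identical(which(!es$valid_mask), 3L)
})

test_that("zero markers yield an empty event set without error", {
  cd <- small_conditioned(seed = 7)
  es <- segment_events(cd$recording, marker_list(numeric(0), character(0)), 2)
  expect_identical(nrow(es$epochs), 0L)
  expect_identical(nrow(event_scalars(es, 1:3)), 0L)
})

test_that("markers too close to the recording end are dropped with a warning", {
  fs <- 500
  n <- 30 * fs
  rec <- recording(cbind(rnorm(n)), fs, "V1L",
                   segments = data.frame(name = "trial1", start_s = 0,
                                         end_s = 30))
  mk <- marker_list(c(0, 10, 25))
  expect_warning(es <- segment_events(rec, mk, 1), "dropped")
  expect_identical(nrow(es$epochs), 2L)
  expect_identical(es$n_dropped_boundary, 1L)
})

test_that("event scalars average the envelope over the first k seconds", {
  fs <- 100
  env <- c(rep(4, 2 * fs), rep(1, 8 * fs))
  es <- structure(list(mouse_id = "m", cohort = "US+Light", trial = 1,
                       channel = "V1L", envelopes = matrix(env, nrow = 1),
                       valid_mask = TRUE, fs = fs, event_period_s = 10),
                  class = "event_set")
  tb <- event_scalars(es, c(2, 10))
  expect_equal(tb$value[tb$k == 2], 4)
  expect_equal(tb$value[tb$k == 10], (4 * 2 + 1 * 8) / 10)
  expect_true(all(tb$normalization_stage == "raw"))
  # a constant envelope gives the constant at every k
  es$envelopes <- matrix(2, nrow = 1, ncol = 10 * fs)
  tbc <- event_scalars(es, 1:10)
  expect_true(all(tbc$value == 2))
  expect_error(event_scalars(es, 11), "exceeds event duration")
})

test_that("dominating events dominate scalars at every subset length", {
  cd <- small_conditioned(seed = 7)
  es <- segment_events(cd$recording, cd$session$markers, 1)
  es$epochs <- es$epochs[1:2, , drop = FALSE]
  big <- abs(es$epochs[1, ]) + 1
  fs <- es$fs
  es$envelopes <- rbind(running_rms(big, 0.25, fs),
                        running_rms(es$epochs[1, ], 0.25, fs))
  es$valid_mask <- c(TRUE, TRUE)
  tb <- event_scalars(es, 1:10)
  for (k in 1:10)
    expect_gte(tb$value[tb$k == k & tb$event_index == 1],
               tb$value[tb$k == k & tb$event_index == 2])
})

test_that("event counting is conserved across validity and boundary drops", {
  cd <- small_conditioned(seed = 7)
  for (tr in 1:3) {
    es <- segment_events(cd$recording, cd$session$markers, tr)
    n_markers <- sum(cd$session$markers$onset_s >=
                       segment_span(cd$recording, paste0("trial", tr))$start_s &
                     cd$session$markers$onset_s <
                       segment_span(cd$recording, paste0("trial", tr))$end_s)
    expect_identical(sum(es$valid_mask) + sum(!es$valid_mask) +
                       es$n_dropped_boundary, n_markers)
  }
})

test_that("median event value follows the mean-of-middle-two convention", {
  tb <- data.frame(mouse_id = "m", cohort = "c", trial = 1,
                   event_index = 1:4, k = 2, value = c(1, 2, 3, 4),
                   normalization_stage = "raw")
  expect_equal(median_event_value(tb, "m", 1, 2), 2.5)
  expect_equal(median_event_value(tb[1:3, ], "m", 1, 2), 2)
  expect_error(median_event_value(tb, "m", 2, 2), "no valid events")
  # matches an explicit sort-based oracle on lognormal draws
  set.seed(43)
  v <- exp(rnorm(60, 0, 0.3))
  tb2 <- data.frame(mouse_id = "m", cohort = "c", trial = 1,
                    event_index = 1:60, k = 1, value = v,
                    normalization_stage = "raw")
  sv <- sort(v)
  expect_equal(median_event_value(tb2, "m", 1, 1), (sv[30] + sv[31]) / 2)
})
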