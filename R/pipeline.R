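#' End-to-end analysis configuration
#'
#' Collects every tunable of the pipeline: band-pass and rejection specs,
#' the 0.25-s envelope window, the 10-s event period, the 1-10 s subset
#' grid, the analyzed channel (default left visual cortex, contralateral
#' to the stimulated eye and under the transducer center), the family-wise
#' error rate and the master seed. Input is either `"synthetic"` (three
#' cohorts generated on the fly) or a BIDS directory.
#'
#' @param input `"synthetic"` or `"bids"`.
#' @param bids_dir dataset root when `input = "bids"`.
#' @param out_dir output directory for report tables (`NULL` for none).
#' @param channel analyzed channel label.
#' @param filter a [filter_spec()].
#' @param rejection a [rejection_spec()].
#' @param window_s running-RMS window (s).
#' @param event_period_s event duration (s).
#' @param k_grid subset lengths (s).
#' @param fwer family-wise error rate.
#' @param seed master seed (synthetic mode).
#' @param n_mice named vector of cohort sizes (synthetic mode).
#' @param config_overrides [session_config()] overrides applied to every
#'   synthetic mouse.
#' @param effects named list of per-cohort [effect_model()]s (default the
#'   standard [cohort_effect_model()]s).
#' @export
analysis_config <- function(input = c("synthetic", "bids"), bids_dir = NULL,
                            out_dir = NULL, channel = "V1L",
                            filter = filter_spec(),
                            rejection = rejection_spec(),
                            window_s = 0.25, event_period_s = 10,
                            k_grid = 1:10, fwer = 0.05, seed = 42L,
                            n_mice = c("US+Light" = 7, "Light-only" = 7,
                                       "US-only" = 6),
                            config_overrides = list(), effects = NULL) {
  input <- match.arg(input)
  if (input == "bids" && is.null(bids_dir)) stopf("bids input needs bids_dir")
  stopifnot(inherits(filter, "filter_spec"),
            inherits(rejection, "rejection_spec"),
            window_s > 0, event_period_s > 0, all(k_grid > 0),
            all(k_grid <= event_period_s), fwer > 0, fwer < 1)
  structure(list(input = input, bids_dir = bids_dir, out_dir = out_dir,
                 channel = channel, filter = filter, rejection = rejection,
                 window_s = window_s, event_period_s = event_period_s,
                 k_grid = k_grid, fwer = fwer, seed = as.integer(seed),
                 n_mice = n_mice, config_overrides = config_overrides,
                 effects = effects),
            class = "analysis_config")
}

# Condition one session and reduce it to scalars: select the analysis
# channel, band-pass, reject artifacts, compute the baseline reference and
# the per-trial event scalars plus envelopes on a 0.25-s grid.
analyze_session <- function(session, config) {
  rec <- session$recording
  if (!(config$channel %in% rec$channel_labels))
    stopf("mouse '%s': channel '%s' not present", rec$id, config$channel)
  rec <- subset_channels(rec, config$channel)
  rec <- bandpass_zero_phase(rec, config$filter)
  rj <- reject_artifacts(rec, config$rejection)
  rec <- rj$recording
  bref <- baseline_reference(rec, channel = config$channel,
                             window_s = config$window_s)
  tabs <- list(); curves <- list()
  step <- max(1L, as.integer(round(config$window_s * rec$fs)))
  for (tr in 1:3) {
    es <- segment_events(rec, session$markers, tr, channel = config$channel,
                         event_period_s = config$event_period_s,
                         window_s = config$window_s)
    tabs[[tr]] <- event_scalars(es, config$k_grid)
    grid_idx <- seq(1L, ncol(es$envelopes), by = step)
    curves[[tr]] <- es$envelopes[es$valid_mask, grid_idx, drop = FALSE] / bref
  }
  list(table = do.call(rbind, tabs), baseline_ref = bref,
       rejection_report = rj$report, curves = curves,
       mouse_id = rec$id, cohort = rec$cohort)
}

#' Run the full analysis pipeline
#'
#' Executes generate/read, filter, artifact rejection, event segmentation,
#' envelope computation, scalar reduction, both normalization stages, and
#' the registered statistical comparisons; optionally writes all report
#' tables plus a provenance record to `out_dir`. The Trial-1
#' self-normalization identity (each mouse's Trial-1 median = 1 at every
#' k) is asserted on every run.
#'
#' @param config an [analysis_config()].
#' @return a `pipeline_report` list: `tables` (baseline- and
#'   trial1-normalized event-scalar tables), `baseline_refs`, `context`,
#'   `profiles` (significance-vs-k profiles for every registered
#'   comparison), `boxplots` (quartile summaries at short and full subset
#'   lengths), `intra_cohort_tests` / `inter_cohort_tests` (pairwise
#'   Mann-Whitney grids under the n = 90 and n = 60 families),
#'   `median_curves` (per cohort x trial pooled median envelopes),
#'   `rejection_report`, `families`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  sessions <- if (config$input == "synthetic") {
    unlist(lapply(names(config$n_mice), function(co)
      generate_cohort(co, n_mice = config$n_mice[[co]],
                      config_overrides = config$config_overrides,
                      effect = config$effects[[co]],
                      seed = config$seed)),
      recursive = FALSE)
  } else read_bids_dataset(config$bids_dir)

  per <- lapply(sessions, function(s)
    tryCatch(analyze_session(s, config),
             error = function(e) stopf("stage: per-session analysis, mouse '%s': %s",
                                       s$recording$id, conditionMessage(e))))
  raw <- do.call(rbind, lapply(per, `[[`, "table"))
  brefs <- vapply(per, `[[`, 0, "baseline_ref")
  names(brefs) <- vapply(per, `[[`, "", "mouse_id")

  tb_base <- apply_baseline_norm(raw, brefs)
  ctx <- normalization_context(tb_base, brefs, k_grid = config$k_grid)
  tb_t1 <- apply_trial1_norm(tb_base, ctx)

  # self-normalization identity: every mouse's Trial-1 median is 1
  for (m in names(ctx)) for (k in config$k_grid) {
    dev <- abs(median_event_value(tb_t1, m, 1, k) - 1)
    if (dev > 1e-12)
      stopf("stage: normalization audit, mouse '%s': Trial-1 median deviates from 1 by %g at k = %g",
            m, dev, k)
  }

  fam <- standard_families(config$fwer)
  cohorts <- intersect(c("US+Light", "Light-only", "US-only"),
                       unique(tb_t1$cohort))
  profiles <- list()
  # Trial-1 cohort comparisons on baseline-normalized data
  if (all(c("US+Light", "Light-only") %in% cohorts))
    profiles$trial1_uslight_vs_lightonly <- significance_profile(
      tb_base, list(list(cohort = "US+Light", trial = 1),
                    list(cohort = "Light-only", trial = 1)),
      fam$trial1_profiles, config$k_grid, "trial1 US+Light vs Light-only")
  if (length(cohorts) >= 3)
    profiles$trial1_three_cohorts <- significance_profile(
      tb_base, lapply(cohorts, function(co) list(cohort = co, trial = 1)),
      fam$trial1_profiles, config$k_grid, "trial1 three cohorts")
  # intra-cohort trial-pair profiles on trial1-normalized data
  for (co in cohorts) {
    for (pr in list(c(1, 2), c(2, 3))) {
      nm <- sprintf("%s_t%d_vs_t%d", gsub("[^A-Za-z]", "", co), pr[1], pr[2])
      profiles[[nm]] <- significance_profile(
        tb_t1, list(list(cohort = co, trial = pr[1]),
                    list(cohort = co, trial = pr[2])),
        fam$trial_pair_mwu, config$k_grid,
        sprintf("%s trial %d vs %d", co, pr[1], pr[2]))
    }
  }
  # across-trials / within-trial Kruskal-Wallis profiles
  for (co in cohorts)
    profiles[[sprintf("kw_%s_across_trials", gsub("[^A-Za-z]", "", co))]] <-
      significance_profile(
        tb_t1, lapply(1:3, function(tr) list(cohort = co, trial = tr)),
        fam$kw_across_trials, config$k_grid,
        sprintf("%s across trials", co))
  if (length(cohorts) >= 3)
    for (tr in 2:3)
      profiles[[sprintf("kw_trial%d_across_cohorts", tr)]] <-
        significance_profile(
          tb_t1, lapply(cohorts, function(co) list(cohort = co, trial = tr)),
          fam$kw_within_trials, config$k_grid,
          sprintf("trial %d across cohorts", tr))

  k_rep <- intersect(c(3, max(config$k_grid)), config$k_grid)
  box <- summarize_boxplots(tb_t1[tb_t1$k %in% k_rep, ],
                            c("cohort", "trial", "k"))

  # pairwise Mann-Whitney grids accompanying the boxplot summaries:
  # all trial pairs within each cohort, and all cohort pairs within
  # Trials 2-3, at every subset length, under their registered families
  grid_row <- function(g1, g2, labels, k, fam) {
    res <- mann_whitney_u(g1, g2, mode = "approx")
    data.frame(a = labels[1], b = labels[2], k = k,
               statistic = res$statistic, p_value = res$p_value,
               alpha = fam$alpha, significant = res$p_value < fam$alpha)
  }
  intra <- list()
  for (co in cohorts) for (pr in list(c(1, 2), c(2, 3), c(1, 3)))
    for (k in config$k_grid)
      intra[[length(intra) + 1]] <- cbind(
        data.frame(cohort = co),
        grid_row(pool_cell(tb_t1, co, pr[1], k),
                 pool_cell(tb_t1, co, pr[2], k),
                 paste0("trial", pr), k, fam$intra_cohort_grid))
  intra <- do.call(rbind, intra)
  names(intra)[names(intra) %in% c("a", "b")] <- c("trial_a", "trial_b")
  inter <- NULL
  if (length(cohorts) >= 2) {
    pairs <- combn(cohorts, 2, simplify = FALSE)
    inter <- list()
    for (tr in intersect(2:3, 1:3)) for (pp in pairs)
      for (k in config$k_grid)
        inter[[length(inter) + 1]] <- cbind(
          data.frame(trial = tr),
          grid_row(pool_cell(tb_t1, pp[1], tr, k),
                   pool_cell(tb_t1, pp[2], tr, k),
                   pp, k, fam$inter_cohort_grid))
    inter <- do.call(rbind, inter)
    names(inter)[names(inter) %in% c("a", "b")] <- c("cohort_a", "cohort_b")
  }

  curves <- pooled_median_curves(per, config)
  rej <- do.call(rbind, lapply(per, `[[`, "rejection_report"))

  report <- list(tables = list(baseline = tb_base, trial1 = tb_t1),
                 baseline_refs = brefs, context = ctx, profiles = profiles,
                 boxplots = box, intra_cohort_tests = intra,
                 inter_cohort_tests = inter, median_curves = curves,
                 rejection_report = rej, families = fam,
                 provenance = list(
                   package = "ecogrms",
                   version = as.character(utils::packageVersion("ecogrms")),
                   r_version = R.version.string,
                   seed = config$seed, input = config$input,
                   channel = config$channel,
                   filter = unclass(config$filter),
                   rejection = unclass(config$rejection),
                   window_s = config$window_s, fwer = config$fwer,
                   n_sessions = length(sessions)))
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Pooled (over all valid events of all mice) pointwise median envelope per
# cohort x trial, on the 0.25-s grid, baseline-normalized.
pooled_median_curves <- function(per, config) {
  cohorts <- unique(vapply(per, `[[`, "", "cohort"))
  rows <- list()
  for (co in cohorts) for (tr in 1:3) {
    mats <- lapply(per[vapply(per, `[[`, "", "cohort") == co],
                   function(p) p$curves[[tr]])
    m <- do.call(rbind, mats)
    if (is.null(m) || nrow(m) == 0) next
    med <- apply(m, 2, median)
    rows[[length(rows) + 1]] <- data.frame(
      cohort = co, trial = tr,
      time_s = (seq_along(med) - 1) * config$window_s,
      median_envelope = med, n_events = nrow(m))
  }
  do.call(rbind, rows)
}

#' Estimate an effect-gain ratio between two trials
#'
#' Recovers the evoked-amplitude ratio between `trial` and Trial 1 from a
#' baseline-normalized event-scalar table. Because baseline normalization
#' fixes the ongoing-background envelope median at 1, the evoked excess of
#' a trial's pooled median above 1 tracks the evoked amplitude; the ratio
#' of excesses therefore estimates the between-trial gain with the
#' background floor removed:
#' `(median(trial) - 1) / (median(trial 1) - 1)`.
#'
#' @param table event-scalar table at stage `"baseline"`.
#' @param trial numerator trial (default 2).
#' @param k subset length at which medians are pooled (default 2 s, where
#'   evoked activity dominates the envelope).
#' @return scalar gain estimate.
#' @export
estimate_trial_gain <- function(table, trial = 2, k = 2) {
  if (any(table$normalization_stage != "baseline"))
    stopf("gain estimation uses the baseline-normalized table")
  m1 <- median(table$value[table$trial == 1 & table$k == k])
  mt <- median(table$value[table$trial == trial & table$k == k])
  if (m1 <= 1) stopf("Trial-1 median not above baseline floor; no evoked signal to ratio")
  (mt - 1) / (m1 - 1)
}

#' Quartile summaries for boxplot-style reporting
#'
#' Per grouping cell: median, quartiles (linear interpolation between
#' order statistics) and whiskers at the 0.5th/99.5th percentiles, so the
#' whiskers enclose more than 99% of the data.
#'
#' @param table event-scalar table.
#' @param grouping character vector of grouping columns.
#' @return data frame with one row per cell: grouping columns, `n`,
#'   `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`.
#' @export
summarize_boxplots <- function(table, grouping = c("cohort", "trial", "k")) {
  if (nrow(table) == 0) stopf("empty table")
  key <- interaction(table[grouping], drop = TRUE, lex.order = TRUE)
  cells <- split(table, key)
  rows <- lapply(cells, function(cell) {
    v <- cell$value
    if (length(v) == 0) stopf("empty cell in boxplot summary")
    q <- quantile(v, c(0.005, 0.25, 0.5, 0.75, 0.995), type = 7, names = FALSE)
    cbind(cell[1, grouping, drop = FALSE],
          data.frame(n = length(v), median = q[3], q1 = q[2], q3 = q[4],
                     whisker_lo = q[1], whisker_hi = q[5]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write all pipeline report tables to a directory
#'
#' Emits the normalized event tables, every significance profile, the
#' boxplot quartile table, the pooled median envelope curves, the
#' rejection report, the per-mouse normalization audit and a provenance
#' JSON.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(report$tables$trial1, "event_scalars_trial1norm.tsv")
  tsv(report$boxplots, "boxplot_quartiles.tsv")
  tsv(report$intra_cohort_tests, "intra_cohort_tests.tsv")
  if (!is.null(report$inter_cohort_tests))
    tsv(report$inter_cohort_tests, "inter_cohort_tests.tsv")
  tsv(report$median_curves, "median_envelope_curves.tsv")
  tsv(report$rejection_report, "rejection_report.tsv")
  prof <- do.call(rbind, lapply(names(report$profiles), function(nm) {
    p <- report$profiles[[nm]]
    cbind(data.frame(comparison = attr(p, "label"), test = attr(p, "test"),
                     family = attr(p, "family")), as.data.frame(p))
  }))
  tsv(prof, "significance_profiles.tsv")
  write_context_json(report$context,
                     file.path(out_dir, "normalization_context.json"))
  jsonlite::write_json(
    lapply(report$families, function(f) f[c("name", "fwer", "n_comparisons",
                                            "alpha", "alpha_printed")]),
    file.path(out_dir, "bonferroni_families.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
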