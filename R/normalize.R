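#' Per-mouse baseline reference value
#'
#' The median of the 0.25-s running-RMS envelope over the last 60 s of the
#' second baseline (the rest period between titration and Trial 1), with
#' samples inside rejected spans excluded from the median. All trial data
#' of a mouse are divided by this reference, putting every animal on a
#' common dimensionless scale.
#'
#' @param rec a filtered [recording()] with a `baseline2` segment.
#' @param channel analyzed channel label.
#' @param window_s running-RMS window (s).
#' @param last_s length of the reference window at the end of baseline2.
#' @return positive scalar (same units as the signal).
#' @export
baseline_reference <- function(rec, channel = rec$channel_labels[1],
                               window_s = 0.25, last_s = 60) {
  span <- segment_span(rec, "baseline2")
  usable <- (span$end_s - span$start_s) -
    span_overlap(span$start_s, span$end_s, rec$rejected_spans)
  if (usable < last_s - 1e-9)
    stopf("mouse '%s': only %.1f usable s of baseline2, need %g", rec$id,
          usable, last_s)
  fs <- rec$fs
  i0 <- as.integer(round(span$start_s * fs)) + 1L
  i1 <- as.integer(round(span$end_s * fs))
  env <- running_rms(rec$samples[i0:i1, channel], window_s, fs)
  t_abs <- span$start_s + (seq_along(env) - 1) / fs
  keep <- t_abs >= span$end_s - last_s
  if (!is.null(rec$rejected_spans) && nrow(rec$rejected_spans) > 0)
    for (j in seq_len(nrow(rec$rejected_spans)))
      keep <- keep & !(t_abs >= rec$rejected_spans$start_s[j] &
                       t_abs < rec$rejected_spans$end_s[j])
  median(env[keep])
}

#' Divide all event scalars by each mouse's baseline reference
#'
#' First normalization stage: every value in the table is divided by its
#' mouse's [baseline_reference()]. The table's stage flag advances from
#' `"raw"` to `"baseline"`; re-application is an error, so values can
#' never be double-normalized.
#'
#' @param table event-scalar table at stage `"raw"`.
#' @param baseline_refs named numeric vector, mouse id -> reference.
#' @return the table at stage `"baseline"`.
#' @export
apply_baseline_norm <- function(table, baseline_refs) {
  if (any(table$normalization_stage != "raw"))
    stopf("table is at stage '%s', expected 'raw'",
          table$normalization_stage[1])
  missing <- setdiff(unique(table$mouse_id), names(baseline_refs))
  if (length(missing))
    stopf("no baseline reference for mouse: %s", paste(missing, collapse = ", "))
  if (any(baseline_refs <= 0)) stopf("baseline references must be > 0")
  table$value <- table$value / unname(baseline_refs[table$mouse_id])
  table$normalization_stage <- "baseline"
  table
}

#' Trial-1 reference for one mouse at one subset length
#'
#' The median across Trial-1 valid events of the baseline-normalized
#' event scalar at subset length `k`. Computed per `k`: the 2-s reference
#' and the 10-s reference generally differ.
#'
#' @param table event-scalar table at stage `"baseline"`.
#' @param mouse_id,k cell selectors.
#' @return positive scalar (dimensionless).
#' @export
trial1_reference <- function(table, mouse_id, k) {
  if (any(table$normalization_stage != "baseline"))
    stopf("trial-1 references are computed from baseline-normalized data")
  median_event_value(table, mouse_id, 1, k)
}

#' Build the full normalization context for a table
#'
#' @param table event-scalar table at stage `"baseline"`.
#' @param baseline_refs named vector of per-mouse baseline references
#'   (stored for audit).
#' @param k_grid subset lengths.
#' @return a `normalization_context`: per mouse, the baseline reference
#'   and the Trial-1 reference at every `k`.
#' @export
normalization_context <- function(table, baseline_refs = NULL,
                                  k_grid = sort(unique(table$k))) {
  mice <- unique(table$mouse_id)
  ctx <- lapply(mice, function(m) {
    refs <- vapply(k_grid, function(k) trial1_reference(table, m, k), 0)
    if (any(refs <= 0)) stopf("non-positive trial-1 reference for '%s'", m)
    names(refs) <- as.character(k_grid)
    list(mouse_id = m,
         baseline_ref = if (!is.null(baseline_refs))
           unname(baseline_refs[m]) else NA_real_,
         trial1_ref_by_k = refs)
  })
  names(ctx) <- mice
  structure(ctx, class = "normalization_context", k_grid = k_grid)
}

#' Divide all event scalars by each mouse's Trial-1 reference
#'
#' Second normalization stage: every `(mouse, trial, k)` value is divided
#' by that mouse's Trial-1 median at the same `k`, so each mouse's Trial-1
#' median becomes exactly 1 and between-trial changes read as ratios.
#' Requires stage `"baseline"`; advances it to `"trial1"`.
#'
#' @param table event-scalar table at stage `"baseline"`.
#' @param ctx a [normalization_context()].
#' @return the table at stage `"trial1"`.
#' @export
apply_trial1_norm <- function(table, ctx) {
  if (any(table$normalization_stage != "baseline"))
    stopf("table is at stage '%s', expected 'baseline'",
          table$normalization_stage[1])
  missing <- setdiff(unique(table$mouse_id), names(ctx))
  if (length(missing))
    stopf("no trial-1 reference for mouse: %s", paste(missing, collapse = ", "))
  ref <- vapply(seq_len(nrow(table)), function(i) {
    r <- ctx[[table$mouse_id[i]]]$trial1_ref_by_k[as.character(table$k[i])]
    if (is.na(r)) stopf("no trial-1 reference for mouse '%s' at k = %g",
                        table$mouse_id[i], table$k[i])
    r
  }, 0)
  table$value <- table$value / ref
  table$normalization_stage <- "trial1"
  table
}

#' Persist a normalization context as JSON
#' @param ctx a [normalization_context()].
#' @param path output file.
#' @export
write_context_json <- function(ctx, path) {
  jsonlite::write_json(
    lapply(ctx, function(m) list(mouse_id = m$mouse_id,
                                 baseline_ref = m$baseline_ref,
                                 trial1_ref_by_k = as.list(m$trial1_ref_by_k))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
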