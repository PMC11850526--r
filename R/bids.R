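#' Write sessions as a BIDS dataset
#'
#' Lays out one subject folder per session (`sub-01`, `sub-02`, ...), each
#' with a BrainVision triple, an `events.tsv` (onset, duration, trial_type,
#' sample), and — for synthetic sessions — a ground-truth JSON sidecar
#' clearly flagged as synthetic. A top-level `participants.tsv` carries the
#' mouse id and cohort of every subject, next to a
#' `dataset_description.json`.
#'
#' @param sessions list of sessions, each a list with at least `recording`
#'   and `markers` (as returned by [generate_session()]); an optional
#'   `ground_truth` element is serialized alongside.
#' @param out_dir output directory (created if needed).
#' @param task task label used in file names.
#' @return invisibly, `out_dir`.
#' @export
write_bids_dataset <- function(sessions, out_dir, task = "lightstim") {
  if (length(sessions) < 1) stopf("need at least one session")
  ids <- vapply(sessions, function(s) s$recording$id, "")
  if (anyDuplicated(ids))
    stopf("duplicate subject ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  jsonlite::write_json(
    list(Name = "Synthetic mouse ECoG light/ultrasound sessions",
         BIDSVersion = "1.9.0", DatasetType = "raw",
         GeneratedBy = list(list(Name = "ecogrms",
                                 Version = as.character(utils::packageVersion("ecogrms"))))),
    file.path(out_dir, "dataset_description.json"),
    auto_unbox = TRUE, pretty = TRUE)

  part <- data.frame(participant_id = sprintf("sub-%02d", seq_along(sessions)),
                     mouse_id = ids,
                     cohort = vapply(sessions, function(s) s$recording$cohort, ""))
  write.table(part, file.path(out_dir, "participants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    sub <- sprintf("sub-%02d", i)
    eegdir <- file.path(out_dir, sub, "eeg")
    dir.create(eegdir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(eegdir, sprintf("%s_task-%s_eeg", sub, task))
    write_brainvision(s$recording, s$markers, base)

    ev <- data.frame(onset = s$markers$onset_s,
                     duration = if (!is.null(s$ground_truth))
                       s$ground_truth$config$stim_duration_s else 0,
                     trial_type = s$markers$label,
                     sample = onset_to_sample(s$markers$onset_s,
                                              s$recording$fs))
    write.table(ev, file.path(eegdir, sprintf("%s_task-%s_events.tsv", sub, task)),
                sep = "\t", quote = FALSE, row.names = FALSE)

    if (!is.null(s$ground_truth)) {
      gt <- s$ground_truth
      gt$config <- unclass(gt$config)
      gt$effect <- unclass(gt$effect)
      gt$effect$vep_kernel <- unclass(gt$effect$vep_kernel)
      jsonlite::write_json(gt,
        file.path(eegdir, sprintf("%s_task-%s_groundtruth.json", sub, task)),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
    }
  }
  invisible(out_dir)
}

#' Read a BIDS dataset written by [write_bids_dataset()]
#'
#' Subjects are discovered through `participants.tsv`; each subject's
#' BrainVision triple, events and (if present) ground-truth sidecar are
#' loaded. Recordings without a segment sidecar are returned with a `NULL`
#' segment map (permissive mode).
#'
#' @param dir dataset root.
#' @return list of sessions (`recording`, `markers`, `ground_truth` or
#'   `NULL`), one per participants.tsv row.
#' @export
read_bids_dataset <- function(dir) {
  ptsv <- file.path(dir, "participants.tsv")
  if (!file.exists(ptsv)) stopf("no participants.tsv under %s", dir)
  part <- read.delim(ptsv, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(part)), function(i) {
    sub <- part$participant_id[i]
    vhdr <- list.files(file.path(dir, sub, "eeg"), pattern = "\\.vhdr$",
                       full.names = TRUE)
    if (length(vhdr) != 1)
      stopf("expected one .vhdr for %s, found %d", sub, length(vhdr))
    x <- read_brainvision(vhdr)
    if (is.na(x$recording$id)) x$recording$id <- part$mouse_id[i]
    if (is.na(x$recording$cohort)) x$recording$cohort <- part$cohort[i]
    gt_path <- sub("_eeg\\.vhdr$", "_groundtruth.json", vhdr)
    gt <- if (file.exists(gt_path))
      jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
    list(recording = x$recording, markers = x$markers, ground_truth = gt)
  })
}
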