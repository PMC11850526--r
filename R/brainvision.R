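#' Write a recording as a BrainVision file triple
#'
#' Emits the standard three-file format: a text header (`.vhdr`), a text
#' marker file (`.vmrk`) and multiplexed IEEE float32 little-endian binary
#' samples (`.eeg`), units microvolt. Marker positions are written as
#' 1-based sample indices per the BrainVision convention (see
#' [onset_to_sample()]). The recording's segment map, subject id and
#' cohort go into a `<base>_segments.json` sidecar, since the format has
#' no native notion of trial phases.
#'
#' @param rec an [recording()].
#' @param markers an [marker_list()] (may have zero rows).
#' @param path_base path without extension; the three files are written as
#'   `path_base.vhdr` / `.vmrk` / `.eeg`.
#' @return invisibly, the paths written.
#' @export
write_brainvision <- function(rec, markers, path_base) {
  stopifnot(inherits(rec, "ecog_recording"))
  base <- basename(path_base)
  dir <- dirname(path_base)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vhdr <- paste0(path_base, ".vhdr")
  vmrk <- paste0(path_base, ".vmrk")
  eeg  <- paste0(path_base, ".eeg")

  nch <- ncol(rec$samples)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           "Codepage=UTF-8",
           sprintf("DataFile=%s.eeg", base),
           sprintf("MarkerFile=%s.vmrk", base),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           sprintf("NumberOfChannels=%d", nch),
           sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec$channel_labels))
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]",
          "Codepage=UTF-8",
          sprintf("DataFile=%s.eeg", base),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (nrow(markers) > 0)
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(markers)) + 1L, markers$label,
                        onset_to_sample(markers$onset_s, rec$fs)))
  writeLines(mk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 4L, endian = "little")

  sidecar <- list(id = rec$id, cohort = rec$cohort)
  if (!is.null(rec$segments))
    sidecar$segments <- rec$segments
  jsonlite::write_json(sidecar, paste0(path_base, "_segments.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(vhdr = vhdr, vmrk = vmrk, eeg = eeg))
}

parse_vhdr_lines <- function(lines, path) {
  kv <- list()
  for (l in lines) {
    if (grepl("^\\s*[;\\[]", l) || !grepl("=", l, fixed = TRUE)) next
    eq <- regexpr("=", l, fixed = TRUE)
    kv[[substr(l, 1, eq - 1)]] <- substr(l, eq + 1, nchar(l))
  }
  kv
}

#' Read a BrainVision file triple
#'
#' Parses the header for sampling rate and channel labels, reads the
#' float32 multiplexed binary samples, converts marker positions back to
#' seconds, and restores the segment map from the `_segments.json` sidecar
#' when present (permissive mode: a triple without the sidecar is read as
#' a plain recording with no segment map). Malformed inputs are rejected,
#' never repaired: a missing member file or a binary length that is not a
#' whole number of multiplexed samples is an error naming the file.
#'
#' @param path path to the `.vhdr` file (or the base path without
#'   extension).
#' @return list with `recording` and `markers`.
#' @export
read_brainvision <- function(path) {
  path_base <- sub("\\.vhdr$", "", path)
  vhdr <- paste0(path_base, ".vhdr")
  if (!file.exists(vhdr)) stopf("header file not found: %s", vhdr)
  kv <- parse_vhdr_lines(readLines(vhdr, warn = FALSE, encoding = "UTF-8"), vhdr)
  if (is.null(kv$NumberOfChannels) || is.null(kv$SamplingInterval))
    stopf("malformed header (missing NumberOfChannels/SamplingInterval): %s",
          vhdr)
  if (!is.null(kv$BinaryFormat) && kv$BinaryFormat != "IEEE_FLOAT_32")
    stopf("unsupported BinaryFormat '%s' in %s", kv$BinaryFormat, vhdr)
  nch <- as.integer(kv$NumberOfChannels)
  fs <- 1e6 / as.numeric(kv$SamplingInterval)
  labels <- vapply(seq_len(nch), function(i) {
    v <- kv[[sprintf("Ch%d", i)]]
    if (is.null(v)) stopf("header %s missing channel %d", vhdr, i)
    strsplit(v, ",", fixed = TRUE)[[1]][1]
  }, "")

  eeg <- file.path(dirname(vhdr), kv$DataFile %||% paste0(basename(path_base), ".eeg"))
  if (!file.exists(eeg)) stopf("data file not found: %s", eeg)
  sz <- file.size(eeg)
  if (sz %% (4L * nch) != 0)
    stopf("data file %s truncated: %d bytes is not a whole number of %d-channel float32 samples",
          eeg, sz, nch)
  n <- sz / (4L * nch)
  con <- file(eeg, "rb")
  raw <- readBin(con, "numeric", n = n * nch, size = 4L, endian = "little")
  close(con)
  samples <- t(matrix(raw, nrow = nch))

  vmrk <- file.path(dirname(vhdr), kv$MarkerFile %||% paste0(basename(path_base), ".vmrk"))
  onsets <- numeric(0); mlabels <- character(0)
  if (file.exists(vmrk)) {
    for (l in readLines(vmrk, warn = FALSE, encoding = "UTF-8")) {
      if (!grepl("^Mk[0-9]+=Stimulus,", l)) next
      f <- strsplit(sub("^Mk[0-9]+=", "", l), ",", fixed = TRUE)[[1]]
      mlabels <- c(mlabels, f[2])
      onsets <- c(onsets, sample_to_onset(as.numeric(f[3]), fs))
    }
  }

  segments <- NULL; id <- NA_character_; cohort <- NA_character_
  sc_path <- paste0(path_base, "_segments.json")
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    if (!is.null(sc$segments)) segments <- as.data.frame(sc$segments)
    id <- sc$id %||% NA_character_
    cohort <- sc$cohort %||% NA_character_
  }
  list(recording = recording(samples, fs, labels, segments = segments,
                             id = id, cohort = cohort),
       markers = marker_list(onsets, mlabels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
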