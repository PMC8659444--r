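#' Continuous multichannel EEG recordings
#'
#' Container for one continuous recording: a channels-by-samples matrix in
#' microvolts, its sampling rate, the montage, and annotated seizure onset
#' times in seconds from the start of the recording.
#'
#' @param samples Numeric matrix, `n_channels x n_samples`, in microvolts.
#' @param fs Sampling rate in Hz (CHB-MIT recordings use 256).
#' @param seizure_onsets Numeric vector of onset times in seconds, strictly
#'   increasing, each inside `[0, n_samples / fs)`. May be empty.
#' @param montage A [channel_montage()] with one entry per matrix row.
#' @param patient_id Identifier carried into window provenance.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs = 256, seizure_onsets = numeric(),
                          montage = chbmit_montage(), patient_id = "unknown") {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix [n_channels x n_samples]")
  assert_scalar_num(fs, "fs", min = 1e-9)
  if (nrow(samples) != nrow(montage))
    stop(sprintf("samples has %d rows but montage has %d channels",
                 nrow(samples), nrow(montage)))
  seizure_onsets <- as.numeric(seizure_onsets)
  dur <- ncol(samples) / fs
  if (length(seizure_onsets)) {
    if (is.unsorted(seizure_onsets, strictly = TRUE))
      stop("`seizure_onsets` must be strictly increasing")
    if (any(seizure_onsets < 0 | seizure_onsets >= dur))
      stop("every seizure onset must lie in [0, duration)")
  }
  structure(list(samples = samples, fs = fs, seizure_onsets = seizure_onsets,
                 montage = montage, patient_id = as.character(patient_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording '%s': %d channels x %d samples (%.2f h at %g Hz), %d seizure(s)>\n",
    x$patient_id, nrow(x$samples), ncol(x$samples),
    ncol(x$samples) / x$fs / 3600, x$fs, length(x$seizure_onsets)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

# ---- EDF input/output ------------------------------------------------------
#
# Minimal EDF (European Data Format) support for continuous recordings:
# 256-byte fixed ASCII header, 256 ASCII bytes per signal, then data records
# of 16-bit little-endian integers, one contiguous block per signal per
# record. Physical values are recovered by the standard linear calibration
# from the (digital, physical) min/max header fields.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Read an EDF file into an [eeg_recording()]
#'
#' Channels are matched to `montage` labels case- and whitespace-insensitively
#' and returned in montage order; duplicate montage labels (e.g. the two
#' T8-P8 derivations of the CHB-MIT montage) are filled with the matching file
#' channels in file order. Annotation signals ("EDF Annotations") are ignored.
#'
#' @param path Path to an EDF/EDF+ file.
#' @param montage Target [channel_montage()]; file channels are reordered to
#'   it. `NULL` adopts the file's own channel labels in file order.
#' @param onsets Seizure onset times in seconds (EDF itself carries no seizure
#'   annotations in this layout; CHB-MIT distributes them in sidecar text).
#' @param patient_id Recording identifier; defaults to the file name.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, montage = chbmit_montage(), onsets = numeric(),
                     patient_id = NULL) {
  if (!file.exists(path)) stop(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, raw(), 256L))
  if (nchar(hdr) < 256L) stop("truncated EDF header")
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1L))
  n_records <- as.integer(fld(237L, 8L))
  record_dur <- as.numeric(fld(245L, 8L))
  n_signals <- as.integer(fld(253L, 4L))
  if (is.na(n_signals) || n_signals < 1L) stop("invalid EDF header: no signals")
  sig_hdr <- rawToChar(readBin(con, raw(), 256L * n_signals))
  # per-signal fields, laid out field-major: labels(16) transducer(80)
  # dim(8) pmin(8) pmax(8) dmin(8) dmax(8) prefilter(80) nsamples(8)
  pos <- c(label = 0L, transducer = 16L * n_signals, dim = 96L * n_signals,
           pmin = 104L * n_signals, pmax = 112L * n_signals,
           dmin = 120L * n_signals, dmax = 128L * n_signals,
           prefilter = 136L * n_signals, nsamp = 216L * n_signals)
  take <- function(start, len) {
    vapply(seq_len(n_signals), function(i)
      trimws(substr(sig_hdr, start + (i - 1L) * len + 1L, start + i * len)), "")
  }
  labels <- take(pos[["label"]], 16L)
  pmin <- as.numeric(take(pos[["pmin"]], 8L))
  pmax <- as.numeric(take(pos[["pmax"]], 8L))
  dmin <- as.numeric(take(pos[["dmin"]], 8L))
  dmax <- as.numeric(take(pos[["dmax"]], 8L))
  nsamp <- as.integer(take(pos[["nsamp"]], 8L))

  keep <- normalize_label(labels) != "EDFANNOTATIONS"
  tot <- sum(nsamp)
  raw_data <- readBin(con, integer(), n = n_records * tot, size = 2L,
                      endian = "little", signed = TRUE)
  if (length(raw_data) < n_records * tot) stop("truncated EDF data section")

  offsets <- c(0L, cumsum(nsamp))
  sig_mat <- lapply(which(keep), function(s) {
    idx <- outer(seq_len(nsamp[s]), (seq_len(n_records) - 1L) * tot, `+`) +
      offsets[s]
    d <- raw_data[as.vector(idx)]
    if (dmax[s] == dmin[s]) stop("invalid EDF calibration (digital min == max)")
    (d - dmin[s]) * (pmax[s] - pmin[s]) / (dmax[s] - dmin[s]) + pmin[s]
  })
  labels <- labels[keep]
  nsamp <- nsamp[keep]

  fs_all <- nsamp / record_dur
  if (length(unique(fs_all)) != 1L)
    stop(sprintf("non-uniform sampling rate across channels: %s",
                 paste(unique(fs_all), collapse = ", ")))
  fs <- fs_all[[1L]]

  if (is.null(montage)) montage <- channel_montage(labels)
  # match montage entries to file channels (first unused label match wins)
  norm_file <- normalize_label(labels)
  norm_want <- normalize_label(montage$label)
  used <- logical(length(labels))
  pick <- integer(nrow(montage))
  for (i in seq_len(nrow(montage))) {
    j <- which(!used & norm_file == norm_want[i])
    if (!length(j)) {
      stop(sprintf(
        "montage channel %d ('%s') not found in EDF; file labels left: %s",
        montage$index[i], montage$label[i],
        paste(labels[!used], collapse = ", ")))
    }
    pick[i] <- j[[1L]]
    used[j[[1L]]] <- TRUE
  }
  samples <- do.call(rbind, sig_mat[pick])
  eeg_recording(samples, fs = fs, seizure_onsets = onsets, montage = montage,
                patient_id = patient_id %||% basename(path))
}

#' Write an [eeg_recording()] to an EDF file
#'
#' Uses 1-second data records, 16-bit samples, and a per-channel linear
#' calibration spanning the channel's observed range. The recording length
#' must be a whole number of seconds and `fs` a whole number.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  n_ch <- nrow(rec$samples)
  n_samples <- ncol(rec$samples)
  if (n_samples %% fs != 0)
    stop("write_edf requires a whole number of seconds of data")
  n_records <- n_samples %/% fs

  rng <- apply(rec$samples, 1L, function(x) max(abs(range(x)), 1))
  pmax <- ceiling(rng)
  dmax <- 32767; dmin <- -32768
  digital <- lapply(seq_len(n_ch), function(i) {
    x <- rec$samples[i, ]
    as.integer(round((x - (-pmax[i])) * (dmax - dmin) / (2 * pmax[i]) + dmin))
  })

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L), edf_pad(rec$patient_id, 80L), edf_pad("peselect", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (1L + n_ch), 8L), edf_pad("", 44L),
    edf_pad(n_records, 8L), edf_pad("1", 8L), edf_pad(n_ch, 4L))
  field <- function(values, width)
    paste(vapply(values, edf_pad, "", width = width), collapse = "")
  hdr <- paste0(hdr,
    field(rec$montage$label, 16L), field(rep("", n_ch), 80L),
    field(rep("uV", n_ch), 8L), field(-pmax, 8L), field(pmax, 8L),
    field(rep(dmin, n_ch), 8L), field(rep(dmax, n_ch), 8L),
    field(rep("", n_ch), 80L), field(rep(fs, n_ch), 8L),
    field(rep("", n_ch), 32L))
  writeBin(charToRaw(hdr), con)
  for (r in seq_len(n_records)) {
    at <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(n_ch))
      writeBin(digital[[i]][at], con, size = 2L, endian = "little")
  }
  invisible(path)
}
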