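#' Windowing configuration for the seizure prediction horizon
#'
#' Fixes the labeling scheme applied to continuous recordings: the pre-ictal
#' class is the 10-minute seizure prediction horizon (SPH) ending at each
#' onset, tiled into non-overlapping 2.8-s analysis windows; the normal class
#' is sampled far from seizures (outside every SPH and the 30-minute
#' post-ictal recovery), one window per clock hour; the normal class is capped
#' at 10 windows per pre-ictal window so test sets are not swamped by
#' inter-ictal data.
#'
#' @param sph_minutes Seizure prediction horizon, minutes before onset.
#' @param window_seconds Analysis window length in seconds.
#' @param postictal_minutes Post-onset exclusion, minutes.
#' @param max_normal_to_preictal_ratio Cap on `|normal| / |preictal|`.
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(sph_minutes = 10, window_seconds = 2.8,
                             postictal_minutes = 30,
                             max_normal_to_preictal_ratio = 10) {
  assert_scalar_num(sph_minutes, "sph_minutes", min = 1e-9)
  assert_scalar_num(window_seconds, "window_seconds", min = 1e-9)
  assert_scalar_num(postictal_minutes, "postictal_minutes", min = 1e-9)
  assert_scalar_num(max_normal_to_preictal_ratio,
                    "max_normal_to_preictal_ratio", min = 1)
  structure(list(sph_minutes = sph_minutes, window_seconds = window_seconds,
                 postictal_minutes = postictal_minutes,
                 max_normal_to_preictal_ratio = max_normal_to_preictal_ratio),
            class = "windowing_config")
}

window_samples <- function(cfg, fs) as.integer(round(cfg$window_seconds * fs))

# ---- window_set container --------------------------------------------------

#' Labeled window sets
#'
#' A `window_set` holds 2.8-s (by default) multichannel segments with their
#' provenance: a list of `n_channels x w` matrices plus an `info` data.frame
#' with columns `label` ("preictal"/"normal"), `start_s`, `patient_id`,
#' `seizure_index` (NA for normal windows).
#'
#' @param data List of equally shaped numeric matrices (`n_channels x w`).
#' @param info data.frame with one row per window.
#' @return An object of class `window_set`.
#' @export
window_set <- function(data, info) {
  stopifnot(is.list(data), is.data.frame(info), length(data) == nrow(info))
  need <- c("label", "start_s", "patient_id", "seizure_index")
  if (!all(need %in% names(info)))
    stop("info must have columns: ", paste(need, collapse = ", "))
  if (length(data)) {
    dims <- vapply(data, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all windows must share the same [n_channels x w] shape")
    bad <- setdiff(unique(info$label), c("preictal", "normal"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    if (any(info$label == "preictal" & is.na(info$seizure_index)))
      stop("pre-ictal windows must carry a seizure_index")
  }
  rownames(info) <- NULL
  structure(list(data = data, info = info), class = "window_set")
}

#' @export
length.window_set <- function(x) length(x$data)

#' @export
print.window_set <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<window_set: %d windows (%d preictal, %d normal)%s>\n", n,
              sum(x$info$label == "preictal"), sum(x$info$label == "normal"),
              if (n) sprintf(", %d channels x %d samples",
                             nrow(x$data[[1]]), ncol(x$data[[1]])) else ""))
  invisible(x)
}

#' Subset or concatenate window sets
#' @param ws,a,b `window_set` objects.
#' @param idx Integer or logical index over windows.
#' @return A `window_set`.
#' @export
subset_windows <- function(ws, idx) window_set(ws$data[idx], ws$info[idx, , drop = FALSE])

#' @rdname subset_windows
#' @export
bind_windows <- function(a, b) {
  if (!length(a)) return(b)
  if (!length(b)) return(a)
  window_set(c(a$data, b$data), rbind(a$info, b$info))
}

empty_window_set <- function() {
  window_set(list(), data.frame(label = character(), start_s = numeric(),
                                patient_id = character(),
                                seizure_index = integer()))
}

# cut one window of `w` samples starting at `start_s` seconds
cut_window <- function(rec, start_s, w) {
  i0 <- as.integer(round(start_s * rec$fs))
  i0 <- max(0L, min(i0, ncol(rec$samples) - w))
  rec$samples[, (i0 + 1L):(i0 + w), drop = FALSE]
}

# ---- labeling operations ---------------------------------------------------

#' Extract pre-ictal windows under the seizure prediction horizon
#'
#' For each seizure onset `t`, non-overlapping windows tile the horizon
#' `[max(0, t - SPH), t)` back-to-back, anchored at the onset and tiling
#' backward; a fractional leftover at the far end is discarded. The horizon is
#' additionally truncated so no window reaches into the previous seizure's
#' post-ictal exclusion.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [windowing_config()].
#' @return A [window_set()] of pre-ictal windows (empty if no seizures).
#' @export
extract_preictal_windows <- function(rec, cfg = windowing_config()) {
  onsets <- rec$seizure_onsets
  if (!length(onsets)) return(empty_window_set())
  sph <- cfg$sph_minutes * 60
  post <- cfg$postictal_minutes * 60
  wsec <- cfg$window_seconds
  w <- window_samples(cfg, rec$fs)
  out <- empty_window_set()
  for (i in seq_along(onsets)) {
    lower <- max(0, onsets[i] - sph,
                 if (i > 1L) onsets[i - 1L] + post else 0)
    k <- floor((onsets[i] - lower) / wsec + 1e-9)
    if (k < 1L) next
    starts <- onsets[i] - rev(seq_len(k)) * wsec
    data <- lapply(starts, cut_window, rec = rec, w = w)
    info <- data.frame(label = "preictal", start_s = starts,
                       patient_id = rec$patient_id, seizure_index = i)
    out <- bind_windows(out, window_set(data, info))
  }
  out
}

#' Sample normal-period windows, one per clock hour
#'
#' Normal time excludes every `[onset - SPH, onset + postictal]` interval.
#' Within each clock hour the window start is drawn uniformly over all
#' admissible positions (the window must fit in the hour, the recording, and
#' normal time); hours with no admissible position contribute nothing.
#'
#' @inheritParams extract_preictal_windows
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A [window_set()] of normal windows.
#' @export
sample_normal_windows <- function(rec, cfg = windowing_config(), seed = NULL) {
  sph <- cfg$sph_minutes * 60
  post <- cfg$postictal_minutes * 60
  wsec <- cfg$window_seconds
  w <- window_samples(cfg, rec$fs)
  dur <- recording_duration(rec)
  # forbidden *start* intervals (open): window [s, s+wsec) must avoid
  # [onset - sph, onset + post]
  forb <- cbind(rec$seizure_onsets - sph - wsec, rec$seizure_onsets + post)
  n_hours <- ceiling(dur / 3600 - 1e-9)
  starts <- with_seed(seed, {
    got <- numeric(0)
    for (h in seq_len(n_hours) - 1L) {
      lo <- h * 3600
      hi <- min((h + 1) * 3600, dur) - wsec
      if (hi <= lo) next
      segs <- subtract_intervals(lo, hi, forb)
      if (!nrow(segs)) next
      len <- segs[, 2] - segs[, 1]
      tot <- sum(len)
      if (tot <= 0) next
      u <- runif(1L) * tot
      j <- which(cumsum(len) >= u)[1L]
      got <- c(got, segs[j, 1] + u - c(0, cumsum(len))[j])
    }
    got
  })
  if (!length(starts)) return(empty_window_set())
  data <- lapply(starts, cut_window, rec = rec, w = w)
  info <- data.frame(label = "normal", start_s = starts,
                     patient_id = rec$patient_id,
                     seizure_index = NA_integer_)
  window_set(data, info)
}

# subtract a set of (open) intervals [m x 2] from [lo, hi]; returns matrix of
# remaining closed segments (k x 2), possibly 0-row
subtract_intervals <- function(lo, hi, forb) {
  segs <- matrix(c(lo, hi), ncol = 2)
  if (!is.null(forb) && nrow(forb)) {
    for (i in seq_len(nrow(forb))) {
      a <- forb[i, 1]; b <- forb[i, 2]
      out <- matrix(numeric(0), ncol = 2)
      for (j in seq_len(nrow(segs))) {
        s <- segs[j, 1]; e <- segs[j, 2]
        if (b <= s || a >= e) { out <- rbind(out, c(s, e)); next }
        if (a > s) out <- rbind(out, c(s, min(a, e)))
        if (b < e) out <- rbind(out, c(max(b, s), e))
      }
      segs <- out
      if (!nrow(segs)) break
    }
  }
  segs
}

#' Cap the normal:pre-ictal class ratio
#'
#' Uniformly subsamples the normal windows down to
#' `ratio * n_preictal` (no-op when already under the cap); the pre-ictal
#' windows are never touched.
#'
#' @param normal,preictal [window_set()]s of the two classes.
#' @param ratio Maximum `|normal| / |preictal|` (default 10).
#' @param seed Integer seed for the subsample.
#' @return The (possibly subsampled) normal [window_set()].
#' @export
enforce_ratio <- function(normal, preictal, ratio = 10, seed = NULL) {
  if (!length(preictal))
    stop("pre-ictal set is empty: the normal:pre-ictal ratio is undefined")
  cap <- floor(ratio * length(preictal))
  if (length(normal) <= cap) return(normal)
  with_seed(seed, {
    keep <- sort(sample.int(length(normal), cap))
    subset_windows(normal, keep)
  })
}

#' Chronological train/test split by seizure
#'
#' Pre-ictal windows of the earliest `n_train_seizures` seizures form the
#' training partition; later seizures form the test partition (a predictor
#' must never train on its future). Normal windows are split by time at the
#' start of the first test seizure's horizon, and the normal:pre-ictal cap is
#' re-applied within each partition.
#'
#' @param windows A [window_set()] mixing both classes.
#' @param n_train_seizures Number of earliest seizures assigned to training.
#' @param ratio Normal:pre-ictal cap applied per partition (default 10).
#' @param seed Integer seed for the per-partition subsampling.
#' @return `list(train = window_set, test = window_set)`.
#' @export
chronological_split <- function(windows, n_train_seizures, ratio = 10,
                                seed = NULL) {
  pre <- subset_windows(windows, windows$info$label == "preictal")
  nor <- subset_windows(windows, windows$info$label == "normal")
  # canonical time order, so the split (and the seeded per-partition
  # subsampling) is invariant to the input ordering
  pre <- subset_windows(pre, order(pre$info$start_s))
  nor <- subset_windows(nor, order(nor$info$start_s))
  seiz <- sort(unique(pre$info$seizure_index))
  if (n_train_seizures < 1L || n_train_seizures >= length(seiz))
    stop(sprintf(
      "n_train_seizures must be in [1, %d) for %d distinct seizures",
      length(seiz), length(seiz)))
  train_seiz <- seiz[seq_len(n_train_seizures)]
  pre_train <- subset_windows(pre, pre$info$seizure_index %in% train_seiz)
  pre_test <- subset_windows(pre, !(pre$info$seizure_index %in% train_seiz))
  boundary <- min(pre_test$info$start_s)
  nor_train <- subset_windows(nor, nor$info$start_s < boundary)
  nor_test <- subset_windows(nor, nor$info$start_s >= boundary)
  s2 <- if (is.null(seed)) NULL else seed + 1L
  nor_train <- enforce_ratio(nor_train, pre_train, ratio, seed)
  nor_test <- enforce_ratio(nor_test, pre_test, ratio, s2)
  list(train = bind_windows(pre_train, nor_train),
       test = bind_windows(pre_test, nor_test))
}

# ---- serialization ---------------------------------------------------------

#' Save / load a window dataset as matrices plus a JSON manifest
#'
#' Windows are stacked row-wise into one numeric table
#' (`n_windows * n_channels` rows, `w` columns) written as `windows.csv`;
#' provenance, shape, and an optional config echo go to `manifest.json`.
#'
#' @param ws A [window_set()].
#' @param dir Output directory (created if needed).
#' @param extra Named list merged into the manifest (e.g. config echo, seed).
#' @return `dir` (save) or a [window_set()] (load).
#' @export
save_window_dataset <- function(ws, dir, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_ch <- if (length(ws)) nrow(ws$data[[1]]) else 0L
  w <- if (length(ws)) ncol(ws$data[[1]]) else 0L
  manifest <- c(list(n_windows = length(ws), n_channels = n_ch,
                     window_length = w, info = ws$info), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  mat <- if (length(ws)) do.call(rbind, ws$data) else matrix(numeric(0), 0, 0)
  utils::write.table(mat, file.path(dir, "windows.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname save_window_dataset
#' @export
load_window_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  info <- as.data.frame(manifest$info)
  if (!nrow(info)) return(empty_window_set())
  info$seizure_index <- as.integer(info$seizure_index)
  mat <- as.matrix(utils::read.table(file.path(dir, "windows.csv"), sep = ","))
  n_ch <- manifest$n_channels
  data <- lapply(seq_len(manifest$n_windows), function(i) {
    m <- mat[((i - 1L) * n_ch + 1L):(i * n_ch), , drop = FALSE]
    dimnames(m) <- NULL
    m
  })
  window_set(data, info)
}
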