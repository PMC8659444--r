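#' Specification of one synthetic EEG "patient"
#'
#' The generator targets the statistical contract that ordinal-pattern channel
#' selection relies on, not physiological realism: background activity on
#' every channel is broadband Gaussian noise (near-maximal permutation
#' entropy); during each pre-seizure horizon the *informative* channels mix in
#' a regular narrowband oscillation, lowering their ordinal complexity, while
#' non-informative channels are statistically identical in both periods.
#'
#' @param n_channels Number of channels (default 23, the CHB-MIT montage size).
#' @param fs Sampling rate in Hz (default 256).
#' @param hours Recording duration in hours.
#' @param n_seizures Number of planted seizure onsets.
#' @param informative_channels 1-based indices of channels that carry the
#'   pre-ictal signature.
#' @param preictal_regularity Mixing weight `lambda` in `(0, 1]` of the
#'   regular component on informative channels during the horizon:
#'   `x = (1 - lambda) * noise + lambda * oscillation`. Higher values make the
#'   pre-ictal windows more ordinally deterministic (lower PE).
#' @param noise_sd Background noise SD in microvolts (15 by default, keeping
#'   traces within a typical +/- 50 microvolt scalp display scale; PE itself
#'   is amplitude-invariant).
#' @param seed Integer seed; the whole recording is reproducible from it.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_channels = 23, fs = 256, hours = 2,
                                  n_seizures = 2,
                                  informative_channels = c(4, 7, 16),
                                  preictal_regularity = 0.8,
                                  noise_sd = 15, seed = 1) {
  assert_scalar_num(n_channels, "n_channels", min = 1)
  assert_scalar_num(fs, "fs", min = 1)
  assert_scalar_num(hours, "hours", min = 1e-3)
  assert_scalar_num(n_seizures, "n_seizures", min = 0)
  assert_scalar_num(preictal_regularity, "preictal_regularity",
                    min = 1e-12, max = 1)
  assert_scalar_num(noise_sd, "noise_sd", min = 1e-12)
  informative_channels <- as.integer(informative_channels)
  if (length(informative_channels) &&
      (any(informative_channels < 1) || any(informative_channels > n_channels)))
    stop("informative_channels must be within 1..n_channels")
  structure(list(n_channels = as.integer(n_channels), fs = fs, hours = hours,
                 n_seizures = as.integer(n_seizures),
                 informative_channels = informative_channels,
                 preictal_regularity = preictal_regularity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# one regular narrowband component: sinusoid whose instantaneous frequency
# performs a slow bounded random walk in [3, 12] Hz (theta/alpha range)
regular_component <- function(n, fs, amp) {
  f <- numeric(n)
  f[1] <- stats::runif(1, 3, 12)
  steps <- stats::rnorm(n - 1L, sd = 0.05)
  for (t in seq_len(n - 1L)) f[t + 1L] <- min(12, max(3, f[t] + steps[t]))
  phase <- 2 * pi * cumsum(f) / fs + stats::runif(1, 0, 2 * pi)
  amp * sin(phase)
}

#' Generate a continuous synthetic recording with planted seizures
#'
#' Onsets are spread across the recording (one per equal-length block, with
#' mild jitter) and must be feasibly spaced: consecutive onsets more than
#' `SPH + postictal` apart, so pre-ictal horizons never overlap recovery
#' periods.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param cfg A [windowing_config()] (fixes the horizon the generator plants).
#' @return An [eeg_recording()] whose montage uses generic labels
#'   (`S01, S02, ...`) unless `n_channels` is 23, in which case the CHB-MIT
#'   montage is used.
#' @export
generate_recording <- function(spec, cfg = windowing_config()) {
  dur <- spec$hours * 3600
  sph <- cfg$sph_minutes * 60
  post <- cfg$postictal_minutes * 60
  n <- as.integer(round(dur * spec$fs))
  if (spec$n_seizures > 0) {
    block <- dur / spec$n_seizures
    if (0.9 * block <= sph + post)
      stop(sprintf(
        "infeasible onset spacing: %d seizures in %.2f h cannot be > %g s apart",
        spec$n_seizures, spec$hours, sph + post))
  }
  with_seed(spec$seed, {
    onsets <- if (spec$n_seizures > 0) {
      block <- dur / spec$n_seizures
      (seq_len(spec$n_seizures) - 0.5) * block +
        stats::runif(spec$n_seizures, -0.05, 0.05) * block
    } else numeric(0)
    samples <- matrix(stats::rnorm(spec$n_channels * n, sd = spec$noise_sd),
                      nrow = spec$n_channels)
    lam <- spec$preictal_regularity
    amp <- spec$noise_sd * sqrt(2)
    for (t0 in onsets) {
      i0 <- max(0L, as.integer(round((t0 - sph) * spec$fs)))
      i1 <- min(n, as.integer(round(t0 * spec$fs)))
      if (i1 <= i0) next
      span <- (i0 + 1L):i1
      for (ch in spec$informative_channels) {
        reg <- regular_component(length(span), spec$fs, amp)
        samples[ch, span] <- (1 - lam) * samples[ch, span] + lam * reg
      }
    }
    montage <- if (spec$n_channels == 23L) chbmit_montage()
               else channel_montage(sprintf("S%02d", seq_len(spec$n_channels)))
    eeg_recording(samples, fs = spec$fs, seizure_onsets = onsets,
                  montage = montage,
                  patient_id = sprintf("synthetic-%d", spec$seed))
  })
}

#' Draw labeled windows directly from the two synthetic regimes
#'
#' Produces a balanced [window_set()] without materializing a continuous
#' recording: normal windows are pure background noise on every channel;
#' pre-ictal windows mix the regular component into the informative channels
#' exactly as [generate_recording()] does inside the horizon. Pre-ictal
#' windows are assigned seizure indices round-robin over `spec$n_seizures`
#' events so event-level metrics remain computable. Use this when a study
#' needs many windows per class; the continuous path would require one
#' recording-hour per normal window.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param n_per_class Number of windows per class.
#' @param cfg A [windowing_config()] (fixes the window length).
#' @param seed Overrides `spec$seed` when given.
#' @return A [window_set()] with `2 * n_per_class` windows.
#' @export
generate_window_set <- function(spec, n_per_class, cfg = windowing_config(),
                                seed = NULL) {
  w <- window_samples(cfg, spec$fs)
  lam <- spec$preictal_regularity
  amp <- spec$noise_sd * sqrt(2)
  with_seed(seed %||% spec$seed, {
    make <- function(preictal) {
      win <- matrix(stats::rnorm(spec$n_channels * w, sd = spec$noise_sd),
                    nrow = spec$n_channels)
      if (preictal) {
        for (ch in spec$informative_channels) {
          reg <- regular_component(w, spec$fs, amp)
          win[ch, ] <- (1 - lam) * win[ch, ] + lam * reg
        }
      }
      win
    }
    pre <- lapply(seq_len(n_per_class), function(i) make(TRUE))
    nor <- lapply(seq_len(n_per_class), function(i) make(FALSE))
    wsec <- cfg$window_seconds
    info <- data.frame(
      label = rep(c("preictal", "normal"), each = n_per_class),
      start_s = seq_len(2 * n_per_class) * wsec,
      patient_id = sprintf("synthetic-%d", seed %||% spec$seed),
      seizure_index = c(rep_len(seq_len(max(1L, spec$n_seizures)), n_per_class),
                        rep(NA_integer_, n_per_class)))
    window_set(c(pre, nor), info)
  })
}

#' Generate a labeled train/test cohort with known ground truth
#'
#' Composes [generate_recording()] with the windowing pipeline: pre-ictal
#' horizon extraction, per-hour normal sampling, the normal:pre-ictal cap,
#' and the chronological by-seizure split. The planted informative channels
#' are returned as ground truth for selector-recovery studies.
#'
#' @param spec A [synthetic_cohort_spec()] with `n_seizures >= 2`.
#' @param cfg A [windowing_config()].
#' @param n_train_seizures Earliest seizures assigned to training (default:
#'   `ceiling(n_seizures / 2)`).
#' @return `list(train = window_set, test = window_set,
#'   ground_truth = integer channel indices)`.
#' @export
generate_labeled_cohort <- function(spec, cfg = windowing_config(),
                                    n_train_seizures = NULL) {
  if (spec$n_seizures < 2L)
    stop("a cohort needs at least 2 seizures to split train/test")
  n_train_seizures <- n_train_seizures %||% ceiling(spec$n_seizures / 2)
  rec <- generate_recording(spec, cfg)
  pre <- extract_preictal_windows(rec, cfg)
  nor <- sample_normal_windows(rec, cfg, seed = spec$seed + 1L)
  split <- chronological_split(bind_windows(pre, nor), n_train_seizures,
                               ratio = cfg$max_normal_to_preictal_ratio,
                               seed = spec$seed + 2L)
  list(train = split$train, test = split$test,
       ground_truth = spec$informative_channels)
}
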