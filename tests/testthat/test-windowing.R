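test_that("pre-ictal tiling anchors at the onset and fills the horizon", {
  cfg <- windowing_config()
  rec <- small_recording(n_channels = 1, fs = 32, hours = 1.2, onsets = 3600)
  ws <- extract_preictal_windows(rec, cfg)
  expect_identical(length(ws), 214L)  # floor(600 / 2.8)
  expect_true(all(ws$info$label == "preictal"))
  expect_true(all(ws$info$seizure_index == 1L))
  # windows tile back-to-back and end exactly at the onset
  expect_equal(max(ws$info$start_s) + 2.8, 3600)
  expect_equal(diff(sort(ws$info$start_s)), rep(2.8, 213))
  expect_true(all(ws$info$start_s >= 3600 - 600))
  # constant window length: round(2.8 * fs)
  expect_identical(ncol(ws$data[[1]]), as.integer(round(2.8 * 32)))
})

test_that("a truncated horizon near the recording start still tiles", {
  cfg <- windowing_config()
  rec <- small_recording(n_channels = 1, fs = 32, hours = 0.5, onsets = 300)
  ws <- extract_preictal_windows(rec, cfg)
  expect_identical(length(ws), 107L)  # floor(300 / 2.8)
  rec0 <- small_recording(n_channels = 1, fs = 32, hours = 0.5,
                          onsets = numeric(0))
  expect_identical(length(extract_preictal_windows(rec0, cfg)), 0L)
})

test_that("window length is 717 samples at 256 Hz", {
  cfg <- windowing_config()
  spec <- synthetic_cohort_spec(n_channels = 1, fs = 256, hours = 0.25,
                                n_seizures = 0, informative_channels = 1,
                                seed = 2)
  ws <- generate_window_set(spec, 3)
  expect_identical(ncol(ws$data[[1]]), 717L)
})

test_that("horizons never reach into the previous seizure's post-ictal", {
  cfg <- windowing_config()
  # second onset 2300 s after the first: horizon truncated at onset1 + 1800
  rec <- small_recording(n_channels = 1, fs = 32, hours = 2,
                         onsets = c(1000, 3300))
  ws <- extract_preictal_windows(rec, cfg)
  s2 <- ws$info$start_s[ws$info$seizure_index == 2]
  expect_true(all(s2 >= 1000 + 1800))
  expect_equal(length(s2), floor((3300 - 2800) / 2.8))
})

test_that("normal sampling draws one admissible window per clock hour", {
  cfg <- windowing_config()
  rec <- small_recording(n_channels = 1, fs = 16, hours = 10,
                         onsets = numeric(0))
  ws <- sample_normal_windows(rec, cfg, seed = 31)
  expect_identical(length(ws), 10L)
  # one start inside each hour
  expect_identical(sort(unique(floor(ws$info$start_s / 3600))), as.numeric(0:9))
  # determinism under a fixed seed
  ws2 <- sample_normal_windows(rec, cfg, seed = 31)
  expect_identical(ws$info$start_s, ws2$info$start_s)
  ws3 <- sample_normal_windows(rec, cfg, seed = 32)
  expect_false(identical(ws$info$start_s, ws3$info$start_s))
})

test_that("hours swallowed by exclusion zones contribute no windows", {
  cfg <- windowing_config()
  # onsets at 590 and 2800 s: their [onset - 600, onset + 1800] zones cover
  # the whole first hour
  rec <- small_recording(n_channels = 1, fs = 16, hours = 1,
                         onsets = c(590, 2800))
  ws <- sample_normal_windows(rec, cfg, seed = 1)
  expect_identical(length(ws), 0L)
})

test_that("window placement invariants hold on randomized recordings", {
  cfg <- windowing_config()
  for (seed in 1:5) {
    onsets <- sort(withr::with_seed(seed, runif(2, 700, 3600 * 3 - 100)))
    if (diff(onsets) < 2500) onsets <- onsets[1]
    rec <- small_recording(n_channels = 1, fs = 16, hours = 3,
                           onsets = onsets, seed = seed)
    pre <- extract_preictal_windows(rec, cfg)
    for (i in seq_len(length(pre))) {
      t0 <- pre$info$start_s[i]
      on <- rec$seizure_onsets[pre$info$seizure_index[i]]
      expect_gte(t0, on - 600)
      expect_lte(t0 + 2.8, on + 1e-9)
    }
    nor <- sample_normal_windows(rec, cfg, seed = seed)
    for (t0 in nor$info$start_s) {
      for (on in rec$seizure_onsets) {
        overlap <- t0 < on + 1800 & t0 + 2.8 > on - 600
        expect_false(overlap)
      }
    }
  }
})

test_that("the normal:pre-ictal ratio cap subsamples uniformly at random", {
  spec <- synthetic_cohort_spec(n_channels = 1, fs = 64, hours = 0.1,
                                n_seizures = 0, informative_channels = 1,
                                seed = 13)
  big <- generate_window_set(spec, 250)
  nor <- subset_windows(big, big$info$label == "normal")  # 250 windows
  pre <- subset_windows(big, big$info$label == "preictal")
  pre40 <- subset_windows(pre, 1:20)
  kept <- enforce_ratio(nor, pre40, ratio = 10, seed = 3)
  expect_identical(length(kept), 200L)
  expect_identical(length(enforce_ratio(nor, pre40, ratio = 10, seed = 4)),
                   200L)
  # under the cap: untouched
  small <- subset_windows(nor, 1:50)
  expect_identical(length(enforce_ratio(small, pre40, ratio = 10)), 50L)
  expect_error(enforce_ratio(nor, subset_windows(pre, integer(0)), 10),
               "empty")
  # seeded determinism
  a <- enforce_ratio(nor, pre40, 10, seed = 8)
  b <- enforce_ratio(nor, pre40, 10, seed = 8)
  expect_identical(a$info$start_s, b$info$start_s)
})

test_that("chronological split separates seizures and respects the cap", {
  cfg <- windowing_config()
  onsets <- seq(3000, by = 2600, length.out = 7)
  rec <- small_recording(n_channels = 1, fs = 16, hours = 6, onsets = onsets)
  pre <- extract_preictal_windows(rec, cfg)
  nor <- sample_normal_windows(rec, cfg, seed = 2)
  all_w <- bind_windows(pre, nor)
  sp <- chronological_split(all_w, 4, ratio = 10, seed = 5)
  tr_idx <- unique(sp$train$info$seizure_index)
  te_idx <- unique(sp$test$info$seizure_index)
  expect_identical(sort(tr_idx[!is.na(tr_idx)]), 1:4)
  expect_identical(sort(te_idx[!is.na(te_idx)]), 5:7)
  expect_length(intersect(tr_idx[!is.na(tr_idx)], te_idx[!is.na(te_idx)]), 0)
  for (part in sp) {
    n_pre <- sum(part$info$label == "preictal")
    n_nor <- sum(part$info$label == "normal")
    expect_lte(n_nor, 10 * n_pre)
  }
  # train normal windows precede the first test horizon
  boundary <- min(sp$test$info$start_s[sp$test$info$label == "preictal"])
  expect_true(all(sp$train$info$start_s[sp$train$info$label == "normal"] <
                    boundary))
  # order invariance: shuffling the input leaves the split unchanged
  shuf <- subset_windows(all_w, withr::with_seed(1, sample(length(all_w))))
  sp2 <- chronological_split(shuf, 4, ratio = 10, seed = 5)
  expect_setequal(sp2$train$info$start_s, sp$train$info$start_s)
  expect_setequal(sp2$test$info$start_s, sp$test$info$start_s)
  # out-of-range train counts
  expect_error(chronological_split(all_w, 7), "n_train_seizures")
  expect_error(chronological_split(all_w, 0), "n_train_seizures")
})

test_that("window datasets round-trip through the directory layout", {
  ws <- generate_window_set(small_spec(n_channels = 3, informative = 2), 5)
  dir <- withr::local_tempdir()
  save_window_dataset(ws, dir, extra = list(seed = 7))
  back <- load_window_dataset(dir)
  expect_identical(length(back), length(ws))
  expect_equal(back$info$label, ws$info$label)
  expect_equal(back$info$start_s, ws$info$start_s)
  for (i in seq_along(ws$data))
    expect_equal(back$data[[i]], ws$data[[i]], tolerance = 1e-9)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 7)
})
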