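test_that("trim_initial drops exactly the requested samples", {
  rec <- rand_rec(130 * 250, c("F3", "F4"), 250, seed = 61)
  out <- trim_initial(rec, 10)
  expect_equal(nrow(out$data), 30000)
  expect_equal(out$t0, 10)
  expect_identical(trim_initial(rec, 0), rec)
  expect_error(trim_initial(rec, 200), "longer")
})

test_that("resampling halves the rate and preserves a sine", {
  rec <- rand_rec(1000, c("A", "B"), 500, seed = 62)
  out <- resample_recording(rec, 250)
  expect_equal(out$fs, 250)
  expect_equal(nrow(out$data), 500)
  expect_identical(resample_recording(rec, 500), rec)
  expect_error(resample_recording(rec, 1000), "upsampling")

  sr <- recording(matrix(sine_wave(5, 10, 500), ncol = 1), 500, "Cz")
  out2 <- resample_recording(sr, 250)
  expected <- sine_wave(5, 10, 250)
  core <- 100:(nrow(out2$data) - 100)
  expect_equal(rms(out2$data[core, 1]), rms(expected[core]),
               tolerance = 0.01)
  expect_lt(max(abs(out2$data[core, 1] - expected[core])), 0.02)
})

test_that("linear detrending removes ramps and preserves noise", {
  n <- 1000
  t <- seq_len(n)
  ramp <- recording(cbind(3 * t + 7, -0.5 * t + 2), 250, c("A", "B"))
  out <- detrend_linear(ramp)
  expect_lt(max(abs(out$data)), 1e-9 * 3 * n)
  const <- recording(matrix(5, n, 1), 250, "A")
  expect_lt(max(abs(detrend_linear(const)$data)), 1e-12)
  set.seed(63)
  noise <- recording(matrix(rnorm(50000), ncol = 1), 250, "A")
  out2 <- detrend_linear(noise)
  expect_gt(cor(out2$data[, 1], noise$data[, 1]), 0.999)
})

test_that("common-average reference zeroes the cross-channel mean", {
  rec <- recording(matrix(c(1, 3), 1, 2), 250, c("A", "B"))
  expect_equal(rereference_car(rec)$data, matrix(c(-1, 1), 1, 2,
               dimnames = list(NULL, c("A", "B"))))
  rnd <- rand_rec(500, letters[1:6], 250, seed = 64)
  out <- rereference_car(rnd)
  expect_lt(max(abs(rowMeans(out$data))), 1e-12 * max(abs(rnd$data)))
  # already zero-mean data passes through
  expect_equal(rereference_car(out)$data, out$data)
  expect_error(rereference_car(recording(matrix(0, 5, 1), 250, "A")),
               "2 channels")
})

test_that("FIR bandpass attenuates stopband and preserves passband", {
  fs <- 250
  low <- recording(matrix(sine_wave(0.1, 60, fs), ncol = 1), fs, "A")
  out <- bandpass_fir(low, 1, 50)
  expect_lt(rms(out$data), 0.1 * rms(low$data))
  mid <- recording(matrix(sine_wave(10, 60, fs), ncol = 1), fs, "A")
  out2 <- bandpass_fir(mid, 1, 50)
  expect_equal(rms(out2$data), rms(mid$data), tolerance = 0.05)
  zero <- recording(matrix(0, 5000, 1), fs, "A")
  expect_equal(bandpass_fir(zero, 1, 50)$data, zero$data)
  expect_error(bandpass_fir(mid, 1, 200), "fs/2")
})

test_that("bad channels are detected by deviation and decorrelation", {
  set.seed(65)
  n <- 5000
  base <- rnorm(n)
  chans <- vapply(1:7, function(i) base + 0.2 * rnorm(n), numeric(n))
  noisy <- cbind(chans, 100 * rnorm(n))                 # huge-SD channel
  rec <- recording(noisy, 250, c(paste0("G", 1:7), "BadSD"))
  expect_identical(detect_bad_channels(rec), "BadSD")

  lone <- cbind(chans, rnorm(n))                         # uncorrelated
  rec2 <- recording(lone, 250, c(paste0("G", 1:7), "Lone"))
  expect_identical(detect_bad_channels(rec2), "Lone")

  rec3 <- recording(chans, 250, paste0("G", 1:7))
  expect_identical(detect_bad_channels(rec3), character(0))
})

test_that("interpolation rebuilds a channel from its neighbours", {
  mont <- load_montage("ten20_32")
  set.seed(66)
  n <- 2000
  # spatially smooth field: common source plus position-modulated sources,
  # the regime in which neighbour interpolation is meaningful
  s1 <- rnorm(n); s2 <- rnorm(n); s3 <- rnorm(n)
  pos <- mont$positions[ten20_32_channels(), ]
  data <- vapply(seq_len(32), function(ci)
    s1 + 0.8 * pos[ci, "x"] * s2 + 0.8 * pos[ci, "y"] * s3 +
      0.05 * rnorm(n), numeric(n))
  rec <- recording(data, 250, ten20_32_channels())
  truth <- rec$data[, "Fz"]
  corrupted <- rec
  corrupted$data[, "Fz"] <- rnorm(n) * 100
  fixed <- interpolate_channels(corrupted, "Fz", mont)
  expect_gt(cor(fixed$data[, "Fz"], truth), 0.95)
  good <- setdiff(ten20_32_channels(), "Fz")
  expect_identical(fixed$data[, good], corrupted$data[, good])
  expect_identical(interpolate_channels(rec, character(0), mont), rec)
})

test_that("variance-based epoch rejection masks injected bursts", {
  set.seed(67)
  fs <- 250
  calib <- rand_rec(20 * fs, c("A", "B"), fs, sd = 10)
  rec <- rand_rec(30 * fs, c("A", "B"), fs, sd = 10)
  clean <- reject_epochs_variance(rec, calib, z = 20)
  expect_false(any(clean$mask))
  burst <- rec
  idx <- (10 * fs + 1):(11 * fs)                  # epoch 11
  burst$data[idx, 1] <- burst$data[idx, 1] + 100 * 10 * rnorm(fs)
  out <- reject_epochs_variance(burst, calib, z = 20)
  expect_identical(which(out$mask), 11L)
  expect_lt(sd(out$rec$data[idx, 1]), 10 * 20)
  # infinite threshold masks nothing
  none <- reject_epochs_variance(burst, calib, z = Inf)
  expect_false(any(none$mask))
  expect_error(reject_epochs_variance(rec, rand_rec(5 * fs, c("A", "B"), fs),
                                      z = 20), "10 epochs")
  dropped <- reject_epochs_variance(burst, calib, z = 20, mode = "drop")
  expect_equal(nrow(dropped$rec$data), nrow(rec$data) - fs)
})

test_that("detrend and CAR commute", {
  rec <- rand_rec(1000, letters[1:5], 250, seed = 68)
  a <- rereference_car(detrend_linear(rec))
  b <- detrend_linear(rereference_car(rec))
  expect_equal(a$data, b$data, tolerance = 1e-12)
})

test_that("the pipeline composes its stages in canonical order", {
  set.seed(69)
  fs_raw <- 500
  rec <- rand_rec(30 * fs_raw, c("F3", "F4", "C3", "C4", "Pz"), fs_raw)
  acc <- accel_trace(rep(0, 30 * fs_raw), fs_raw)
  cfg <- pipeline_config(trim_start = 5)
  out <- run_pipeline(rec, acc, cfg, filter_config("rls", 50))
  manual <- bandpass_fir(rereference_car(detrend_linear(
    resample_recording(trim_initial(rec, 5), 250))), 1, 50)
  # zero reference: the adaptive stage must be a no-op
  expect_equal(out$data, manual$data, tolerance = 1e-12)
  prov <- attr(out, "provenance")
  expect_length(prov, 10)
  expect_identical(vapply(prov, `[[`, character(1), "stage"),
                   c("trim", "resample", "detrend", "car", "bandpass",
                     "adaptive_filter", "bad_channels", "epoch_rejection",
                     "interpolation", "ica_hook"))
})

test_that("pipeline hooks run where documented", {
  rec <- rand_rec(15 * 500, c("F3", "F4", "C3", "C4"), 500, seed = 70)
  acc <- accel_trace(rep(0, 15 * 500), 500)
  seen <- character(0)
  cfg <- pipeline_config(trim_start = 0,
                         hooks = list(asr = function(r) { seen <<- c(seen, "asr"); r },
                                      ica = function(r) { seen <<- c(seen, "ica"); r }))
  out <- run_pipeline(rec, acc, cfg, filter_cfg = NULL)
  expect_identical(seen, c("asr", "ica"))
  prov <- attr(out, "provenance")
  expect_false(prov[[6]]$applied)            # adaptive stage disabled
})
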