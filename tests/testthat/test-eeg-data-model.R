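test_that("recording constructor enforces its invariants", {
  expect_error(recording(matrix(0, 10, 2), 250, c("A", "A")), "unique")
  expect_error(recording(matrix(0, 10, 2), 250, c("A", "B", "C")), "columns")
  expect_error(recording(matrix(0, 10, 2), 0, c("A", "B")), "positive")
  expect_error(recording(matrix(0, 10, 1), 250, character(0)), "channel")
  expect_error(recording(matrix(0, 10, 1), 250, "NotAnElectrode",
                         montage = "ten20_32"), "montage")
  rec <- recording(matrix(rnorm(64), ncol = 32), 500, ten20_32_channels(),
                   reference = "FCz", montage = "ten20_32")
  expect_s3_class(rec, "eeg_recording")
  expect_identical(colnames(rec$data), ten20_32_channels())
})

test_that("fixture-csv round-trips bit-exactly", {
  vals <- matrix(c(pi, -1 / 3, 1.2345678901234567e-13, 0, 1e17,
                   -2.718281828459045, 42, 0.1, -0.3, 7), ncol = 2)
  rec <- recording(vals, 250, c("F3", "F4"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path, "fixture-csv")
  back <- read_recording(path, "fixture-csv")
  expect_identical(back$data, rec$data)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$channel_names, rec$channel_names)
})

test_that("fixture-csv header lists all 32 montage channels in order", {
  rec <- rand_rec(10, ten20_32_channels(), 500, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path, "fixture-csv")
  header <- readLines(path, n = 1L)
  expect_identical(header, paste0("#fs=500;channels=",
                                  paste(ten20_32_channels(), collapse = ",")))
})

test_that("fixture-csv rejects rows inconsistent with the header", {
  rec <- rand_rec(5, c("A", "B", "C"), 100, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path, "fixture-csv")
  lines <- readLines(path)
  lines[3] <- sub(",[^,]*$", "", lines[3])   # drop last column of one row
  writeLines(lines, path)
  expect_error(read_recording(path, "fixture-csv"), "width")
})

test_that("EDF write/read passes fs through and quantizes within one step", {
  rec <- rand_rec(1000, c("Fp1", "Fp2", "Cz'"), 500, seed = 3, sd = 50)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path, "edf")
  back <- read_recording(path, "edf")
  expect_equal(back$fs, 500)
  expect_identical(back$channel_names, rec$channel_names)
  step <- 2 * max(abs(rec$data)) / 65535
  expect_lt(max(abs(back$data[1:1000, ] - rec$data)), 2 * step)
})

test_that("truncated EDF payload raises an integrity error", {
  rec <- rand_rec(1000, c("A", "B"), 250, seed = 4)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path, "edf")
  sz <- file.size(path)
  raw <- readBin(path, "raw", sz)
  writeBin(raw[seq_len(sz - 700)], path)
  expect_error(read_recording(path, "edf"), "truncated|records")
})

test_that("BrainVision float32 recordings read back correctly", {
  rec <- rand_rec(200, ten20_32_channels(), 500, seed = 5, sd = 30)
  base <- file.path(withr::local_tempdir(), "run01")
  vhdr <- vibeeg:::write_brainvision(rec, base)
  back <- read_recording(vhdr, "brainvision")
  expect_equal(back$fs, 500)
  expect_identical(back$channel_names, rec$channel_names)
  expect_lt(max(abs(back$data - rec$data)) / max(abs(rec$data)), 1e-6)
})

test_that("BrainVision INT_16 resolution scaling is applied", {
  dir <- withr::local_tempdir()
  raw <- c(100L, -200L, 300L, -400L)           # 2 samples x 2 channels
  con <- file(file.path(dir, "int.eeg"), "wb")
  writeBin(raw, con, size = 2L, endian = "little"); close(con)
  writeLines(c("[Common Infos]", "DataFile=int.eeg", "DataFormat=BINARY",
               "DataOrientation=MULTIPLEXED", "NumberOfChannels=2",
               "SamplingInterval=4000",
               "[Binary Infos]", "BinaryFormat=INT_16",
               "[Channel Infos]", "Ch1=C3,,0.1,uV", "Ch2=C4,,0.5,uV"),
             file.path(dir, "int.vhdr"))
  rec <- read_recording(file.path(dir, "int.vhdr"), "brainvision")
  expect_equal(rec$fs, 250)
  expect_equal(rec$data, matrix(c(10, 30, -100, -200), ncol = 2,
                                dimnames = list(NULL, c("C3", "C4"))))
})

test_that("channel-count mismatch between header and data is an error", {
  rec <- rand_rec(10, ten20_32_channels(), 500, seed = 6)
  base <- file.path(withr::local_tempdir(), "bad")
  vhdr <- vibeeg:::write_brainvision(rec, base)
  lines <- readLines(vhdr)
  lines <- sub("NumberOfChannels=32", "NumberOfChannels=33", lines)
  lines <- c(lines, "Ch33=Extra,,1,uV")
  writeLines(lines, vhdr)
  expect_error(read_recording(vhdr, "brainvision"), "multiple|channel")
})

test_that("align_pair returns matched-rate equal-length streams", {
  rec <- rand_rec(2500, c("F3", "F4"), 250, seed = 7)
  acc <- accel_trace(rnorm(2500), 250)
  al <- align_pair(rec, acc)
  expect_identical(al$rec$data, rec$data)
  expect_identical(al$acc$data, acc$data)

  # acc at 1000 Hz downsampled to 250 Hz: a pure sine must survive
  dur <- 10
  acc_hi <- accel_trace(sine_wave(5, dur, 1000), 1000)
  rec_lo <- rand_rec(dur * 250, c("F3", "F4"), 250, seed = 8)
  al2 <- align_pair(rec_lo, acc_hi)
  expect_equal(al2$acc$fs, 250)
  expect_equal(length(al2$acc$data), nrow(al2$rec$data))
  expected <- sine_wave(5, dur, 250)
  core <- 100:(length(al2$acc$data) - 100)     # ignore resampler edges
  expect_lt(max(abs(al2$acc$data[core] - expected[core])), 0.02)
})

test_that("align_pair is idempotent", {
  rec <- rand_rec(1000, c("F3", "F4"), 250, seed = 9)
  acc <- accel_trace(rnorm(1234), 500)
  once <- align_pair(rec, acc)
  twice <- align_pair(once$rec, once$acc)
  expect_identical(twice$rec$data, once$rec$data)
  expect_identical(twice$acc$data, once$acc$data)
})

test_that("packaged montage has unit-norm positions covering the layout", {
  mont <- load_montage("ten20_32")
  expect_setequal(rownames(mont$positions), ten20_32_channels())
  norms <- sqrt(rowSums(mont$positions^2))
  expect_true(all(abs(norms - 1) < 1e-9))
  rec <- rand_rec(10, ten20_32_channels(), 500, seed = 10)
  expect_true(montage_covers(mont, rec))
  rec2 <- rand_rec(10, c("F3", "Nope"), 500, seed = 11)
  expect_error(montage_covers(mont, rec2), "Nope")
})
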