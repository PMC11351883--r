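test_that("CSV round-trip preserves channels and metadata", {
  set.seed(1)
  rec <- hemo_record(rnorm(5000), rnorm(5000), rnorm(5000), rnorm(5000),
                     fs = 1000, record_id = "rA", subject_id = "sX", dose = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, path)
  back <- read_record(path)
  expect_equal(n_samples(back), 5000)
  expect_equal(back$record_id, "rA")
  expect_equal(back$subject_id, "sX")
  expect_equal(back$dose, 2)
  for (ch in c("ecg", "pcg", "ppg", "lvbp"))
    expect_equal(back[[ch]], rec[[ch]], tolerance = 1e-6)
})

test_that("missing optional LVBP is tolerated, length mismatch is not", {
  rec <- hemo_record(rnorm(3000), rnorm(3000), rnorm(3000), lvbp = NULL)
  path <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, path)
  back <- read_record(path)
  expect_null(back$lvbp)
  expect_error(hemo_record(rnorm(5000), rnorm(4999), rnorm(5000)),
               "identical length")
  # malformed file: PCG column one row short
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ecg,pcg,ppg", paste(1:5, 1, c(1, 1, 1, 1, NA), 1, sep = ",")),
             bad)
  expect_error(read_record(bad), "length mismatch")
  expect_error(read_record(path, format = "hdf5"), "not supported")
})

test_that("pass-band tones survive and stop-band content is rejected", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  tone <- function(f) sin(2 * pi * f * t)
  fft_amp <- function(x, f) {
    n <- length(x)
    2 * Mod(stats::fft(x)[round(f * n / fs) + 1]) / n
  }
  y <- bandpass_zero_phase(tone(100), fs, 30, 200)
  mid <- seq(fs, 3 * fs) # steady-state segment
  expect_lt(abs(fft_amp(y[mid], 100) - 1), 0.05)
  # DC is stop-band
  dc <- bandpass_zero_phase(rep(5, 4001), fs, 30, 200)
  expect_lt(max(abs(dc[mid])), 5e-6 * 5)
  # >= 20 dB rejection one octave outside each edge
  for (f in c(15, 400)) {
    z <- bandpass_zero_phase(tone(f), fs, 30, 200)
    expect_lt(fft_amp(z[mid], f), 10^(-20 / 20))
  }
  expect_error(bandpass_zero_phase(tone(10), fs, 30, 600), "band edges|invalid band")
})

test_that("filtering is zero-phase and length-preserving", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 100 * t)
  y <- bandpass_zero_phase(x, fs, 30, 200)
  expect_length(y, length(x))
  cc <- stats::ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("preprocess_record attenuates out-of-band power and is idempotent in band", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  drift <- sin(2 * pi * 10 * t)
  burst <- sin(2 * pi * 100 * t) * exp(-((t - 1.5)^2) / 0.02)
  rec <- hemo_record(ecg = sin(2 * pi * 10 * t), pcg = drift + burst,
                     ppg = sin(2 * pi * 2 * t), lvbp = NULL)
  out <- preprocess_record(rec)
  expect_null(out$lvbp)
  expect_length(out$pcg, length(rec$pcg))
  n <- length(t)
  p10 <- function(x) Mod(stats::fft(x)[round(10 * n / fs) + 1])^2
  expect_lt(p10(out$pcg) / p10(rec$pcg), 10^(-20 / 10)) # >= 20 dB down
  # burst (100 Hz) retained
  mid <- abs(t - 1.5) < 0.2
  expect_gt(stats::sd(out$pcg[mid]), 0.3 * stats::sd(burst[mid]))
  # refiltering changes little
  again <- preprocess_record(out)
  expect_gt(stats::cor(again$pcg, out$pcg), 0.99)
})

test_that("non-1kHz records are resampled before filtering", {
  fs0 <- 500
  t <- seq(0, 4, by = 1 / fs0)
  rec <- hemo_record(sin(2 * pi * 7 * t), sin(2 * pi * 60 * t),
                     sin(2 * pi * 2 * t), fs = fs0)
  out <- preprocess_record(rec)
  expect_equal(out$fs, 1000)
  expect_equal(n_samples(out), 2 * length(t), tolerance = 0.01)
})
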