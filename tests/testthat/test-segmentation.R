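test_that("R-peaks on clean synthetic ECG land within 10 ms of truth", {
  cfg <- synth_config(n_beats = 62, baseline_hr = 120, effect = c(
    sbp = 0, dbp = 0, mrr = 0, mrd = 0, hr = 0), seed = 9,
    snr_db = c(ecg = Inf, pcg = Inf, ppg = Inf, lvbp = Inf),
    corruption_frac = 0, jitter_sd = 0)
  sim <- simulate_record(cfg)
  prec <- preprocess_record(sim$record)
  peaks <- detect_r_peaks(prec$ecg, prec$fs)
  truth <- sim$truth$r_sample[-1] # beat 1 starts at sample 0: half its QRS is unrendered
  hits <- vapply(truth, function(r) min(abs(peaks - r)), numeric(1))
  expect_gte(sum(hits <= 10), length(truth) - 1)
  expect_equal(length(peaks), 61, tolerance = 1)
})

test_that("degenerate ECG inputs are handled", {
  expect_warning(p <- detect_r_peaks(rep(0, 10000), 1000), "zero-variance")
  expect_length(p, 0)
  expect_error(detect_r_peaks(rnorm(500), 1000), "2 s")
})

test_that("noisy detection at 20 dB SNR keeps sensitivity and PPV >= 0.99", {
  dat <- qrs_fixture()
  truth <- dat$truth[-1]
  sens <- mean(vapply(truth, function(r) any(abs(dat$peaks - r) <= 50), logical(1)))
  ppv <- mean(vapply(dat$peaks, function(p) any(abs(truth - p) <= 50), logical(1)))
  expect_gte(sens, 0.99)
  expect_gte(ppv, 0.99)
})

test_that("cycle splitting is exact index arithmetic", {
  rec <- hemo_record(rnorm(1500), rnorm(1500), rnorm(1500), rnorm(1500))
  cyc <- split_cycles(rec, c(0L, 500L, 1000L))
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$length, c(500L, 500L))
  expect_equal(cyc$start, c(0L, 500L))
  expect_equal(cyc$pcg[[1]], rec$pcg[1:500])
  expect_equal(cyc$bp[[2]], rec$lvbp[501:1000])
  expect_warning(empty <- split_cycles(rec, c(100L)), "fewer than 2")
  expect_equal(nrow(empty), 0)
})

test_that("cycles conserve the spanned interval (n peaks - 1 cycles)", {
  set.seed(2)
  peaks <- cumsum(c(0L, sample(400:700, 60, replace = TRUE)))
  n <- max(peaks) + 100
  rec <- hemo_record(rnorm(n), rnorm(n), rnorm(n))
  cyc <- split_cycles(rec, peaks)
  expect_equal(nrow(cyc), length(peaks) - 1)
  expect_equal(sum(cyc$length), max(peaks) - min(peaks))
  # contiguity: each cycle starts where the previous ended
  expect_equal(cyc$start[-1], cyc$start[-nrow(cyc)] + cyc$length[-nrow(cyc)])
})

# prominent local maxima of a pressure segment (> 40% of pulse height)
envelope_free_peaks <- function(p) {
  lm <- which(diff(sign(diff(p))) == -2) + 1
  lm <- lm[p[lm] > min(p) + 0.4 * diff(range(p))]
  length(lm)
}

test_that("per-cycle pressure segments contain exactly one systolic maximum", {
  cfg <- synth_config(n_beats = 50, seed = 23, corruption_frac = 0,
                      snr_db = c(ecg = Inf, pcg = Inf, ppg = Inf, lvbp = Inf))
  sim <- simulate_record(cfg)
  prec <- preprocess_record(sim$record)
  cyc <- split_cycles(prec, detect_r_peaks(prec$ecg, prec$fs))
  n_peaks <- vapply(cyc$bp, function(p) {
    e <- envelope_free_peaks(p)
    sum(e)
  }, numeric(1))
  expect_true(all(n_peaks[-1] == 1)) # first cycle can catch a boundary artefact
})

test_that("quality screening accepts self-similar cycles and rejects artefacts", {
  # identical cycles: template self-correlation 1
  beat <- sin(2 * pi * 3 * seq(0, 0.5, by = 1e-3))
  cyc <- tibble::tibble(subject_id = "s", record_id = "r", cycle_index = 1:5,
                        start = 0L, length = length(beat),
                        pcg = replicate(5, beat, simplify = FALSE),
                        ppg = replicate(5, beat + 2, simplify = FALSE),
                        bp = replicate(5, NULL, simplify = FALSE))
  out <- assess_quality(cyc)
  expect_true(all(out$quality_pass))
  expect_true(all(out$quality_score >= 0.99))
  # a flat PPG fails the amplitude check
  cyc$ppg[[3]] <- rep(0, length(beat))
  out2 <- assess_quality(cyc)
  expect_false(out2$quality_pass[3])
  expect_equal(out2$quality_score[3], 0)
})

test_that("corrupted beats are screened out on a noisy record", {
  res <- cached("quality200", {
    cfg <- synth_config(n_beats = 200, seed = 5, corruption_frac = 0.05)
    sim <- simulate_record(cfg)
    prec <- preprocess_record(sim$record)
    cyc <- segment_record(prec)
    match <- vapply(cyc$start, function(s) {
      d <- abs(sim$truth$r_sample - s)
      if (min(d) <= 50) which.min(d) else NA_integer_
    }, integer(1))
    list(cyc = cyc, corrupted = sim$truth$corrupted[match])
  })
  bad <- res$corrupted %in% TRUE
  clean <- res$corrupted %in% FALSE
  expect_gte(mean(!res$cyc$quality_pass[bad]), 0.9)
  expect_lte(mean(!res$cyc$quality_pass[clean]), 0.05)
})

test_that("windows are 1000 x 2 with exact zero tail padding", {
  cyc <- tibble::tibble(
    subject_id = "s", record_id = "r", cycle_index = 1:3,
    start = 0L, length = c(600L, 1000L, 1200L),
    pcg = list(rnorm(600), rnorm(1000), rnorm(1200)),
    ppg = list(rnorm(600), rnorm(1000), rnorm(1200)),
    bp = replicate(3, NULL, simplify = FALSE))
  expect_warning(out <- pad_to_window(cyc), "longer than 1000")
  w1 <- out$window[[1]]
  expect_equal(dim(w1), c(1000L, 2L))
  expect_true(all(w1[601:1000, ] == 0))
  expect_equal(w1[1:600, 1], cyc$pcg[[1]])
  expect_equal(out$window[[2]][, 2], cyc$ppg[[2]]) # exactly 1 s: no-op
  expect_null(out$window[[3]]) # > 1 s: excluded
  expect_false(out$window_ok[3])
  # truncation policy keeps the head instead
  out2 <- pad_to_window(cyc, long_cycle_policy = "truncate")
  expect_equal(out2$window[[3]][, 1], cyc$pcg[[3]][1:1000])
})

test_that("slow-rhythm records flag their over-long beats", {
  cfg <- synth_config(n_beats = 20, baseline_hr = 45, effect = c(
    sbp = 0, dbp = 0, mrr = 0, mrd = 0, hr = 0), seed = 31,
    snr_db = c(ecg = Inf, pcg = Inf, ppg = Inf, lvbp = Inf),
    corruption_frac = 0, jitter_sd = 0)
  sim <- simulate_record(cfg)
  prec <- preprocess_record(sim$record)
  cyc <- split_cycles(prec, detect_r_peaks(prec$ecg, prec$fs))
  expect_warning(out <- pad_to_window(cyc), "excluded")
  expect_true(all(!out$window_ok[cyc$length > 1000]))
  expect_gte(sum(!out$window_ok), nrow(out) - 1)
})
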