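test_that("dose raises the peak response monotonically", {
  peak_sbp <- vapply(c(0.5, 1, 2), function(d) {
    max(bolus_trajectory(synth_config(dose = d, n_beats = 150, seed = 3))$sbp)
  }, numeric(1))
  expect_true(all(diff(peak_sbp) > 0))
})

test_that("the pre-injection plateau stays near baseline", {
  cfg <- synth_config(n_beats = 200, seed = 6, jitter_sd = 0)
  traj <- bolus_trajectory(cfg)
  pre <- traj[traj$t < cfg$bolus_onset_s, ]
  expect_gt(nrow(pre), 5)
  expect_lt(max(abs(pre$sbp / cfg$baseline_sbp - 1)), 0.01)
  expect_lt(max(abs(pre$mrr / cfg$baseline_mrr - 1)), 0.01)
})

test_that("trajectories stay inside the pooled observed ranges over many seeds", {
  ranges <- cached("mc_ranges", {
    purrr::map_dfr(1:40, function(s) {
      traj <- bolus_trajectory(synth_config(dose = sample(c(0.5, 1, 2), 1),
                                            n_beats = 120, seed = s))
      tibble::tibble(sbp_min = min(traj$sbp), sbp_max = max(traj$sbp),
                     dbp_min = min(traj$dbp), dbp_max = max(traj$dbp),
                     mrr_min = min(traj$mrr), mrr_max = max(traj$mrr),
                     mrd_min = min(traj$mrd), mrd_max = max(traj$mrd))
    })
  })
  expect_gte(min(ranges$sbp_min), 77);   expect_lte(max(ranges$sbp_max), 272)
  expect_gte(min(ranges$dbp_min), -47);  expect_lte(max(ranges$dbp_max), 20)
  expect_gte(min(ranges$mrr_min), 106);  expect_lte(max(ranges$mrr_max), 9181)
  expect_gte(min(ranges$mrd_min), -5896); expect_lte(max(ranges$mrd_max), -70)
})

test_that("pressure-beat generation rejects infeasible requests", {
  expect_error(lv_pressure_beat(180, -5, 0, -3500, 500), "MRR")
  expect_error(lv_pressure_beat(180, -5, 5000, 100, 500), "MRD")
  expect_error(lv_pressure_beat(180, -5, 300, -300, 400), "does not fit")
  expect_error(lv_pressure_beat(100, 120, 5000, -3000, 500), "exceed")
})

test_that("doubling the requested MRR doubles the realised peak slope", {
  p1 <- lv_pressure_beat(180, -5, 2500, -3000, 600)
  p2 <- lv_pressure_beat(180, -5, 5000, -3000, 600)
  d1 <- max(diff(p1)) * 1000
  d2 <- max(diff(p2)) * 1000
  expect_lt(abs(d2 / d1 - 2), 0.05 * 2)
})

# analytic-signal magnitude via FFT Hilbert transform
analytic_env <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n); h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

test_that("S1 amplitude follows the linear MRR coupling", {
  prof <- subject_profile()
  env_peak <- function(mrr, profile = prof) {
    x <- pcg_beat(180, -5, mrr, -3000, rr = 600, profile = profile)
    # window around the S1 centre (upstroke midpoint), clear of S2
    p_ed <- -5 + 0.12 * 185
    ctr <- round(1000 * (profile$emd_ms / 1000 + pi * (180 - p_ed) / (4 * mrr)))
    max(analytic_env(x)[max(1, ctr - 25):(ctr + 25)])
  }
  got <- env_peak(4000) / env_peak(2000)
  want <- (prof$s1_gain * 4000 + prof$s1_offset) /
    (prof$s1_gain * 2000 + prof$s1_offset)
  expect_lt(abs(got / want - 1), 0.05)
  # degenerate coupling: amplitude independent of MRR
  p0 <- subject_profile(s1_gain = 0)
  expect_equal(env_peak(2000, p0), env_peak(8000, p0), tolerance = 1e-3)
})

test_that("pulse delay decreases with systolic pressure", {
  foot <- function(sbp) which(ppg_beat(sbp, 0, 3000, -3000, 700) > 1e-3)[1]
  expect_lt(foot(250), foot(100))
})

test_that("simulate_subject produces the requested cardinality", {
  cfg <- synth_config(n_beats = 25, seed = 15)
  sim <- simulate_subject(cfg, n_records = 3)
  expect_length(sim$records, 3)
  expect_equal(nrow(sim$truth), 75)
  expect_equal(unique(table(sim$truth$record_id)), 25, ignore_attr = TRUE)
  expect_true(all(diff(sim$truth$r_sample[sim$truth$record_id ==
                                            sim$truth$record_id[1]]) > 0))
})

test_that("the pipeline inverts the generator on noiseless records", {
  res <- cached("pipeline_closure", {
    cfg <- synth_config(n_beats = 120, seed = 19, corruption_frac = 0,
                        snr_db = c(ecg = Inf, pcg = Inf, ppg = Inf, lvbp = Inf))
    sim <- simulate_record(cfg)
    prec <- preprocess_record(sim$record)
    cyc <- segment_record(prec)
    lab <- extract_labels_cycles(cyc)
    match <- vapply(cyc$start, function(s) {
      d <- abs(sim$truth$r_sample - s)
      if (min(d) <= 50) which.min(d) else NA_integer_
    }, integer(1))
    # reference: extraction at the *true* beat boundaries of the same
    # filtered record — isolates detection/segmentation fidelity from the
    # (physical) smoothing of fast dP/dt by the 20 Hz pressure low-pass
    tru <- sim$truth[match[!is.na(match)], ]
    ref <- purrr::map_dfr(seq_len(nrow(tru)), function(i) {
      s0 <- tru$r_sample[i]
      extract_labels(prec$lvbp[(s0 + 1):(s0 + tru$rr[i])])
    })
    list(lab = lab[!is.na(match), ], ref = ref, truth = tru)
  })
  for (p in target_cols) {
    expect_gt(stats::cor(res$lab[[p]], res$ref[[p]]), 0.999)
    expect_gt(stats::cor(res$lab[[p]], res$truth[[p]]), 0.995)
  }
})
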