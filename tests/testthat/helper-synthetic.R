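# Shared fixture builders. Everything is generated in code at test time;
# heavy end-to-end artefacts are computed lazily once per session and
# cached, because several acceptance properties interrogate the same
# trained models.

target_cols <- c("sbp", "dbp", "mrr", "mrd")

# simulate -> preprocess -> segment -> label one subject
subject_beats <- function(profile, n_records, n_beats, base_seed, ...) {
  cfg <- synth_config(profile = profile, n_beats = n_beats, seed = base_seed, ...)
  sim <- simulate_subject(cfg, n_records = n_records)
  process_records(sim$records)
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Study sizes for the end-to-end checks. These are deliberate scaled-down
# simulation sizes (6 records x 85 beats within subject; 4 x 55 for the
# second subject) chosen so the full suite trains seven 30-epoch models on
# one CPU; the methods vignette discusses the choice.
acc_subject_a <- function() {
  cached("subject_a", subject_beats(subject_profile("s1"), n_records = 6,
                                    n_beats = 85, base_seed = 101))
}

# the second subject differs in surface couplings (profile) and in baseline
# hemodynamics / drug responsiveness, as real subjects do
acc_subject_b <- function() {
  cached("subject_b", subject_beats(
    subject_profile_alt("s2"), n_records = 4, n_beats = 55, base_seed = 202,
    baseline_sbp = 160, baseline_dbp = 8, baseline_mrr = 2800,
    baseline_mrd = -2600, baseline_hr = 130,
    effect = c(sbp = 80, dbp = -14, mrr = 4200, mrd = -2100, hr = 25)))
}

acc_config <- function() model_config(seed = 7)

# within-subject five-fold evaluation of subject A (shared fixture,
# reused by the scheme-ordering property)
acc_scheme1_eval <- function() {
  cached("scheme1_eval", {
    dat <- acc_subject_a()
    plan <- make_folds_scheme1(unique(dat$record_id), k = 5, seed = 41)
    run_scheme(dat, plan, acc_config(), epochs = 30)
  })
}

# cross-subject and calibrated evaluations with A as target, trained on B
acc_scheme2_eval <- function() {
  cached("scheme2_eval", {
    dat <- rbind(acc_subject_a(), acc_subject_b())
    plan <- make_split_scheme2(records_index(dat), "s1", seed = 43)
    run_scheme(dat, plan[1, ], acc_config(), epochs = 30)
  })
}

acc_calibrated_eval <- function() {
  cached("calibrated_eval", {
    dat <- rbind(acc_subject_a(), acc_subject_b())
    plan <- make_split_calibration(records_index(dat), "s1", n_cal = 1, seed = 43)
    run_scheme(dat, plan[1, ], acc_config(), epochs = 30)
  })
}

# independent brute-force metrics oracle (plain arithmetic, no shared code)
oracle_metrics <- function(yhat, y) {
  e <- yhat - y
  n <- length(e)
  me <- sum(e) / n
  mae <- sum(abs(e)) / n
  sdv <- sqrt(sum((e - me)^2) / (n - 1))
  mh <- sum(yhat) / n; my <- sum(y) / n
  cc <- sum((y - my) * (yhat - mh)) /
    sqrt(sum((y - my)^2) * sum((yhat - mh)^2))
  list(me = me, mae = mae, sd = sdv, cc = cc)
}

# noiseless analytic-beat label recovery across the pooled ranges
label_recovery_fixture <- function() {
  cached("label1000", {
    set.seed(12)
    n <- 1000
    sbp <- runif(n, 85, 270); dbp <- pmin(runif(n, -45, 18), sbp - 45)
    mrr <- runif(n, 300, 9100); mrd <- -runif(n, 300, 5800)
    rr <- sample(380:620, n, replace = TRUE)
    err <- matrix(NA_real_, n, 4)
    feasible <- logical(n)
    for (i in seq_len(n)) {
      p <- tryCatch(lv_pressure_beat(sbp[i], dbp[i], mrr[i], mrd[i], rr[i]),
                    error = function(e) NULL)
      if (is.null(p)) next
      feasible[i] <- TRUE
      l <- extract_labels(p)
      err[i, ] <- c(l$sbp - sbp[i], l$dbp - dbp[i],
                    (l$mrr - mrr[i]) / mrr[i], (l$mrd - mrd[i]) / abs(mrd[i]))
    }
    list(err = err[feasible, ], n_feasible = sum(feasible))
  })
}

# 300 detectable noisy beats for the QRS benchmark (beat 1 starts at sample
# 0 with half its QRS unrendered, hence 301 generated)
qrs_fixture <- function() {
  cached("qrs300", {
    cfg <- synth_config(n_beats = 301, seed = 17, corruption_frac = 0,
                        snr_db = c(ecg = 20, pcg = 20, ppg = 20, lvbp = 40))
    sim <- simulate_record(cfg)
    list(peaks = detect_r_peaks(preprocess_record(sim$record)$ecg, 1000),
         truth = sim$truth$r_sample)
  })
}
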