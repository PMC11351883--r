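#' Synthetic-study configuration
#'
#' Defines one simulated recording session: an epinephrine-bolus experiment
#' in an anesthetized subject. Baseline hemodynamics sit near the
#' pre-injection values seen in instrumented beagles (left-ventricular
#' SBP ~130 mmHg, LV end-diastolic pressure a few mmHg, +dP/dt_max
#' ~1900 mmHg/s, heart rate ~110 bpm). After `bolus_onset_s` the four
#' parameters and the heart rate follow a double-exponential rise/decay
#' whose magnitude grows with dose, sweeping SBP up to ~250 mmHg and
#' +dP/dt_max to ~8400 mmHg/s at the largest dose — inside the observed
#' pooled ranges SBP [77, 272] mmHg, DBP [-47, 20] mmHg,
#' MRR [106, 9181] mmHg/s, MRD [-5896, -70] mmHg/s.
#'
#' @param profile Subject profile from [subject_profile()]: the coupling
#'   coefficients linking hemodynamics to PCG/PPG morphology.
#' @param dose Epinephrine dose label in units/kg: 0.5, 1 or 2.
#' @param n_beats Beats per record.
#' @param fs Sampling rate (Hz); the pipeline expects 1000.
#' @param baseline_sbp,baseline_dbp,baseline_mrr,baseline_mrd,baseline_hr
#'   Pre-injection values (mmHg, mmHg/s, bpm).
#' @param bolus_onset_s Injection time from record start (s).
#' @param rise_tau,decay_tau Time constants of the bolus response (s).
#' @param effect Named peak deltas at unit dose-effect: `sbp`, `dbp`,
#'   `mrr`, `mrd`, `hr`.
#' @param jitter_sd Relative SD of per-beat physiological variability.
#' @param snr_db Per-channel additive white-noise SNR (dB); use `Inf` for
#'   noiseless channels.
#' @param corruption_frac Fraction of beats overwritten by movement/contact
#'   artifact bursts (flagged in the ground truth).
#' @param seed Integer seed; all waveform jitter, noise and corruption
#'   derive from it.
#' @return A `hemo_synth_config` list.
#' @export
synth_config <- function(profile = subject_profile(),
                         dose = 1, n_beats = 300, fs = 1000,
                         baseline_sbp = 130, baseline_dbp = 2,
                         baseline_mrr = 1900, baseline_mrd = -1950,
                         baseline_hr = 110,
                         bolus_onset_s = 10, rise_tau = 6, decay_tau = 20,
                         effect = c(sbp = 120, dbp = -20, mrr = 6500,
                                    mrd = -3300, hr = 40),
                         jitter_sd = 0.02,
                         snr_db = c(ecg = 20, pcg = 20, ppg = 20, lvbp = 40),
                         corruption_frac = 0.05, seed = 1) {
  if (!dose %in% c(0.5, 1, 2))
    stop("dose must be one of 0.5, 1, 2 units/kg", call. = FALSE)
  structure(list(profile = profile, dose = dose, n_beats = as.integer(n_beats),
                 fs = fs, baseline_sbp = baseline_sbp,
                 baseline_dbp = baseline_dbp, baseline_mrr = baseline_mrr,
                 baseline_mrd = baseline_mrd, baseline_hr = baseline_hr,
                 bolus_onset_s = bolus_onset_s, rise_tau = rise_tau,
                 decay_tau = decay_tau, effect = effect, jitter_sd = jitter_sd,
                 snr_db = snr_db, corruption_frac = corruption_frac,
                 seed = as.integer(seed)),
            class = "hemo_synth_config")
}

#' Subject coupling profile
#'
#' The per-subject coefficients that couple hemodynamics to the surface
#' signals: the first heart sound's amplitude grows linearly with the LV
#' pressure rising rate (`s1_gain * MRR + s1_offset`), the second heart
#' sound with the falling rate, the femoral pulse amplitude with pulse
#' pressure, and the pulse-transit delay shrinks linearly with SBP.
#' Distinct profiles create the between-subject differences that limit
#' cross-subject generalisation.
#'
#' @param subject_id Identifier.
#' @param s1_gain,s1_offset S1 amplitude coupling (per mmHg/s, and offset).
#' @param s2_gain,s2_offset S2 amplitude coupling on |MRD|.
#' @param s1_freq,s2_freq Heart-sound carrier frequencies (Hz), within the
#'   30--150 Hz band.
#' @param ptt_base Pulse-transit delay at zero pressure (ms).
#' @param ptt_slope Delay reduction per mmHg of SBP (ms/mmHg).
#' @param ppg_gain PPG amplitude per 100 mmHg pulse pressure.
#' @param emd_ms Electromechanical delay from R-wave to pressure onset (ms).
#' @param s1_gamma,s2_gamma,ppg_gamma,ptt_gamma Per-subject compliance
#'   exponents bending the respective coupling laws (1 = linear). An affine
#'   difference between two subjects' couplings cannot reduce the Pearson
#'   correlation of a model transferred between them — only the bias and
#'   spread — so the between-subject differences that degrade CC in
#'   practice are curvature differences like these.
#' @return A `hemo_subject_profile` list.
#' @export
subject_profile <- function(subject_id = "s1",
                            s1_gain = 2.0e-4, s1_offset = 0.15,
                            s2_gain = 2.5e-4, s2_offset = 0.12,
                            s1_freq = 50, s2_freq = 70,
                            ptt_base = 280, ptt_slope = 0.6,
                            ppg_gain = 1.0, emd_ms = 25,
                            s1_gamma = 1, s2_gamma = 1,
                            ppg_gamma = 1, ptt_gamma = 1) {
  structure(list(subject_id = subject_id, s1_gain = s1_gain,
                 s1_offset = s1_offset, s2_gain = s2_gain,
                 s2_offset = s2_offset, s1_freq = s1_freq, s2_freq = s2_freq,
                 ptt_base = ptt_base, ptt_slope = ptt_slope,
                 ppg_gain = ppg_gain, emd_ms = emd_ms,
                 s1_gamma = s1_gamma, s2_gamma = s2_gamma,
                 ppg_gamma = ppg_gamma, ptt_gamma = ptt_gamma),
            class = "hemo_subject_profile")
}

#' A second, physiologically distinct subject
#'
#' A convenience alternative profile whose couplings differ enough from
#' [subject_profile()]'s defaults to produce a visible cross-subject domain
#' shift in every parameter.
#'
#' @param subject_id Identifier.
#' @return A `hemo_subject_profile`.
#' @export
subject_profile_alt <- function(subject_id = "s2") {
  subject_profile(subject_id = subject_id,
                  s1_gain = 1.0e-4, s1_offset = 0.45,
                  s2_gain = 4.0e-4, s2_offset = 0.03,
                  s1_freq = 75, s2_freq = 95,
                  ptt_base = 215, ptt_slope = 0.35,
                  ppg_gain = 1.7, emd_ms = 38,
                  s1_gamma = 0.55, s2_gamma = 1.5,
                  ppg_gamma = 0.45, ptt_gamma = 1.8)
}

dose_effect <- function(dose) c(`0.5` = 0.55, `1` = 0.75, `2` = 1)[[as.character(dose)]]

#' Per-beat hemodynamic trajectory of one bolus record
#'
#' Baseline plateau for `bolus_onset_s`, then a double-exponential
#' rise/decay scaled by the dose effect, sampled beat by beat at the
#' instantaneous heart rate, with mild multiplicative beat-to-beat
#' variability (an AR(1) wander plus independent jitter).
#'
#' @param config A [synth_config()].
#' @return Tibble with one row per beat: `beat`, `t` (s), `rr` (samples),
#'   `sbp`, `dbp`, `mrr`, `mrd`, `hr`.
#' @export
bolus_trajectory <- function(config) {
  set.seed(config$seed)
  eff <- dose_effect(config$dose)
  shape <- function(t) {
    u <- pmax(t - config$bolus_onset_s, 0)
    raw <- exp(-u / config$decay_tau) - exp(-u / config$rise_tau)
    tpk <- log(config$decay_tau / config$rise_tau) /
      (1 / config$rise_tau - 1 / config$decay_tau)
    ifelse(u > 0, raw / (exp(-tpk / config$decay_tau) - exp(-tpk / config$rise_tau)), 0)
  }
  n <- config$n_beats
  # AR(1) multiplicative wander shared across parameters plus per-beat jitter
  wander <- stats::filter(stats::rnorm(n, 0, config$jitter_sd * 1.5),
                          0.95, method = "recursive")
  wander <- as.numeric(wander) * sqrt(1 - 0.95^2)
  t <- numeric(n); rr <- numeric(n)
  out <- matrix(0, n, 5, dimnames = list(NULL, c("sbp", "dbp", "mrr", "mrd", "hr")))
  tcur <- 0
  base <- c(config$baseline_sbp, config$baseline_dbp, config$baseline_mrr,
            config$baseline_mrd, config$baseline_hr)
  delta <- c(config$effect[["sbp"]], config$effect[["dbp"]], config$effect[["mrr"]],
             config$effect[["mrd"]], config$effect[["hr"]])
  for (k in seq_len(n)) {
    s <- shape(tcur)
    vals <- base + eff * s * delta
    jit <- 1 + wander[k] + stats::rnorm(5, 0, config$jitter_sd)
    vals <- vals * jit
    # DBP jitters additively: its baseline is near zero so a multiplicative
    # perturbation would be degenerate
    vals[2] <- base[2] + eff * s * delta[2] + stats::rnorm(1, 0, 0.6) + wander[k] * 5
    hr <- max(vals[5], 40)
    rr_s <- 60 / hr * (1 + stats::rnorm(1, 0, 0.01))
    t[k] <- tcur; rr[k] <- round(rr_s * config$fs)
    out[k, ] <- c(vals[1:4], hr)
    tcur <- tcur + rr_s
  }
  # enforce basic physiology: SBP above DBP, MRR positive, MRD negative
  out[, "sbp"] <- pmax(out[, "sbp"], out[, "dbp"] + 40)
  out[, "mrr"] <- pmax(out[, "mrr"], 150)
  out[, "mrd"] <- pmin(out[, "mrd"], -120)
  tibble::tibble(beat = seq_len(n), t = t, rr = as.integer(rr),
                 sbp = out[, "sbp"], dbp = out[, "dbp"],
                 mrr = out[, "mrr"], mrd = out[, "mrd"], hr = out[, "hr"])
}

#' Analytic left-ventricular pressure beat
#'
#' One R-to-R pressure waveform hitting the requested beat parameters: a
#' raised-cosine systolic upstroke from end-diastolic pressure to SBP whose
#' peak slope equals MRR, a raised-cosine decline to DBP whose steepest
#' slope equals MRD, and a slow half-cosine diastolic refill back to
#' end-diastolic pressure. Durations follow from the slope constraints
#' (T_up = pi (SBP - P_ed) / (2 MRR)), so infeasible parameter
#' combinations — slopes too small to span the pressures within the beat —
#' raise an error.
#'
#' @param sbp,dbp,mrr,mrd Target parameters (mmHg, mmHg/s).
#' @param rr Beat length in samples.
#' @param fs Sampling rate (Hz).
#' @param lead_in Samples at end-diastolic pressure before the upstroke
#'   (electromechanical delay).
#' @return Numeric pressure vector of length `rr`.
#' @export
lv_pressure_beat <- function(sbp, dbp, mrr, mrd, rr, fs = 1000, lead_in = 25) {
  if (!all(is.finite(c(sbp, dbp, mrr, mrd)))) stop("non-finite parameters", call. = FALSE)
  if (sbp <= dbp) stop("SBP must exceed DBP", call. = FALSE)
  if (mrr <= 0) stop("infeasible: non-positive MRR cannot reach the systolic peak",
                     call. = FALSE)
  if (mrd >= 0) stop("infeasible: non-negative MRD cannot return to DBP", call. = FALSE)
  p_ed <- dbp + 0.12 * (sbp - dbp)
  n_up <- pi * (sbp - p_ed) / (2 * mrr) * fs
  n_down <- pi * (sbp - dbp) / (2 * abs(mrd)) * fs
  if (lead_in + n_up + n_down > 0.9 * rr)
    stop(sprintf(paste0("infeasible: systole (%.0f samples) does not fit the ",
                        "beat (%d samples)"), lead_in + n_up + n_down, rr),
         call. = FALSE)
  t <- seq_len(rr) - 1
  p <- numeric(rr)
  t0 <- lead_in; t1 <- t0 + n_up; t2 <- t1 + n_down
  seg1 <- t < t0
  seg2 <- t >= t0 & t < t1
  seg3 <- t >= t1 & t < t2
  seg4 <- t >= t2
  p[seg1] <- p_ed
  p[seg2] <- p_ed + (sbp - p_ed) / 2 * (1 - cos(pi * (t[seg2] - t0) / n_up))
  p[seg3] <- dbp + (sbp - dbp) / 2 * (1 + cos(pi * (t[seg3] - t1) / n_down))
  n_dia <- rr - t2
  p[seg4] <- dbp + (p_ed - dbp) / 2 * (1 - cos(pi * (t[seg4] - t2) / n_dia))
  p
}

gauss_burst <- function(center, sigma, freq, amp, rr, fs, phase = 0) {
  t <- (seq_len(rr) - 1) / fs
  amp * exp(-((t - center)^2) / (2 * sigma^2)) * sin(2 * pi * freq * (t - center) + phase)
}

#' Heart-sound beat
#'
#' S1 at the onset of the pressure upstroke with amplitude
#' `s1_gain * MRR + s1_offset` (bent by the subject's `s1_gamma` compliance
#' exponent), S2 near end-systole with amplitude `s2_gain * |MRD| +
#' s2_offset` (exponent `s2_gamma`); both are Gaussian-modulated sinusoids
#' in the 30--150 Hz heart-sound band.
#'
#' @inheritParams lv_pressure_beat
#' @param profile A [subject_profile()].
#' @return Numeric PCG vector of length `rr`.
#' @export
pcg_beat <- function(sbp, dbp, mrr, mrd, rr, fs = 1000,
                     profile = subject_profile()) {
  p_ed <- dbp + 0.12 * (sbp - dbp)
  t_up <- pi * (sbp - p_ed) / (2 * mrr)
  t_down <- pi * (sbp - dbp) / (2 * abs(mrd))
  emd <- profile$emd_ms / 1000
  a1 <- profile$s1_gain * 3000 * (mrr / 3000)^profile$s1_gamma +
    profile$s1_offset
  a2 <- profile$s2_gain * 3000 * (abs(mrd) / 3000)^profile$s2_gamma +
    profile$s2_offset
  gauss_burst(emd + t_up / 2, 0.012, profile$s1_freq, a1, rr, fs) +
    gauss_burst(emd + t_up + 0.4 * t_down, 0.010, profile$s2_freq, a2, rr, fs)
}

#' Femoral pulse beat
#'
#' A single smooth pulse — half-cosine upstroke, exponential-cosine decay —
#' delayed by the pulse-transit time (which decreases linearly with SBP)
#' and scaled by pulse pressure.
#'
#' @inheritParams pcg_beat
#' @param length_out Samples to render (the pulse may spill past the R-R
#'   boundary; the record assembler adds overlapping beats).
#' @return Numeric PPG vector of length `length_out`.
#' @export
ppg_beat <- function(sbp, dbp, mrr, mrd, rr, fs = 1000,
                     profile = subject_profile(), length_out = rr + 400) {
  delay <- ppg_delay(sbp, profile) / 1000
  amp <- profile$ppg_gain * ((sbp - dbp) / 100)^profile$ppg_gamma
  t <- (seq_len(length_out) - 1) / fs - delay
  t_rise <- 0.09
  k <- numeric(length_out)
  up <- t >= 0 & t < t_rise
  dn <- t >= t_rise
  k[up] <- 0.5 * (1 - cos(pi * t[up] / t_rise))
  k[dn] <- exp(-(t[dn] - t_rise) / 0.18) * (0.8 + 0.2 * cos(2 * pi * (t[dn] - t_rise)))
  amp * k
}

ppg_delay <- function(sbp, profile) {
  drop_ms <- profile$ptt_slope * 200 * (pmax(sbp, 1) / 200)^profile$ptt_gamma
  pmax(profile$ptt_base - drop_ms, 40) # ms, floored
}

#' ECG beat
#'
#' A stylised PQRST complex anchored with its R-peak at the first sample of
#' the cycle — narrow dominant R spike, small Q/S deflections, low
#' T and P waves — sufficient for QRS detection.
#'
#' @param rr Beat length in samples.
#' @param fs Sampling rate (Hz).
#' @param lead Extra samples rendered before the R-peak (the left flank of
#'   the R wave); the returned vector has length `lead + rr`.
#' @return Numeric ECG vector (mV).
#' @export
ecg_beat <- function(rr, fs = 1000, lead = 0) {
  t <- (seq_len(rr + lead) - 1 - lead) / fs
  g <- function(mu, sig, amp) amp * exp(-((t - mu)^2) / (2 * sig^2))
  rr_s <- rr / fs
  # QRS ~70 ms wide so its energy sits in the detector's 5-15 Hz band
  g(0, 0.010, 1.0) + g(0.035, 0.012, -0.25) + g(0.35 * rr_s, 0.040, 0.15) +
    g(rr_s - 0.16, 0.025, 0.08)
}

#' Simulate one bolus record
#'
#' Assembles the four synchronized channels beat by beat from
#' [bolus_trajectory()], adds channel noise at the configured SNR, and
#' overwrites a fraction of beats with high-amplitude artifact bursts
#' (flagged in the ground truth) to exercise quality screening.
#'
#' @param config A [synth_config()].
#' @param record_id Identifier for the record.
#' @return A list: `record` (a [hemo_record()]) and `truth` (tibble of
#'   per-beat ground truth: R-sample, the four parameters, `corrupted`).
#' @export
simulate_record <- function(config, record_id = "r1") {
  traj <- bolus_trajectory(config) # seeds the RNG from config$seed
  prof <- config$profile
  fs <- config$fs
  n_total <- sum(traj$rr) + 1000L
  ecg <- numeric(n_total); pcg <- numeric(n_total)
  ppg <- numeric(n_total); lvbp <- numeric(n_total)
  starts <- cumsum(c(0L, traj$rr[-nrow(traj)]))
  for (k in seq_len(nrow(traj))) {
    rr <- traj$rr[k]; s0 <- starts[k]
    idx <- (s0 + 1):(s0 + rr)
    lvbp[idx] <- lv_pressure_beat(traj$sbp[k], traj$dbp[k], traj$mrr[k],
                                  traj$mrd[k], rr, fs,
                                  lead_in = round(prof$emd_ms / 1000 * fs))
    # render with 60 ms of left support so the R complex is symmetric
    lead <- min(60L, s0)
    ecg[(s0 - lead + 1):(s0 + rr)] <- ecg[(s0 - lead + 1):(s0 + rr)] +
      ecg_beat(rr, fs, lead = lead)
    pcg[idx] <- pcg[idx] + pcg_beat(traj$sbp[k], traj$dbp[k], traj$mrr[k],
                                    traj$mrd[k], rr, fs, prof)
    pv <- ppg_beat(traj$sbp[k], traj$dbp[k], traj$mrr[k], traj$mrd[k], rr, fs,
                   prof, length_out = min(rr + 400L, n_total - s0))
    ppg[(s0 + 1):(s0 + length(pv))] <- ppg[(s0 + 1):(s0 + length(pv))] + pv
  }
  n_used <- starts[nrow(traj)] + traj$rr[nrow(traj)]
  ecg <- ecg[seq_len(n_used)]; pcg <- pcg[seq_len(n_used)]
  ppg <- ppg[seq_len(n_used)]; lvbp <- lvbp[seq_len(n_used)]

  corrupted <- stats::runif(nrow(traj)) < config$corruption_frac
  for (k in which(corrupted)) {
    idx <- (starts[k] + 1):(starts[k] + traj$rr[k])
    pcg[idx] <- stats::rnorm(length(idx), 0, 4 * stats::sd(pcg))
    ppg[idx] <- stats::rnorm(length(idx), 0, 4 * stats::sd(ppg))
  }

  add_noise <- function(x, snr_db) {
    if (!is.finite(snr_db)) return(x)
    x + stats::rnorm(length(x), 0, sqrt(mean(x^2) / 10^(snr_db / 10)))
  }
  record <- hemo_record(
    ecg = add_noise(ecg, config$snr_db[["ecg"]]),
    pcg = add_noise(pcg, config$snr_db[["pcg"]]),
    ppg = add_noise(ppg, config$snr_db[["ppg"]]),
    lvbp = add_noise(lvbp, config$snr_db[["lvbp"]]),
    fs = fs, record_id = record_id, subject_id = prof$subject_id,
    dose = config$dose)
  truth <- dplyr::mutate(traj, subject_id = prof$subject_id,
                         record_id = record_id, r_sample = starts,
                         corrupted = corrupted, .before = 1)
  list(record = record, truth = truth)
}

#' Simulate a multi-record subject
#'
#' Generates `n_records` independent bolus records sharing one subject
#' profile, cycling through the dose levels, with per-record sub-seeds
#' derived deterministically from the configuration seed.
#'
#' @param config A [synth_config()]; its `dose` is ignored in favour of the
#'   cycled `doses`.
#' @param n_records Number of records.
#' @param doses Dose sequence cycled across records.
#' @return A list: `records` (list of [hemo_record()]) and `truth` (row-bound
#'   ground-truth tibble).
#' @export
simulate_subject <- function(config, n_records = 8, doses = c(0.5, 1, 2)) {
  doses <- rep_len(doses, n_records)
  out <- purrr::map(seq_len(n_records), function(i) {
    cfg_i <- config
    cfg_i$dose <- doses[i]
    cfg_i$seed <- (config$seed * 1000L + i) %% .Machine$integer.max
    simulate_record(cfg_i, record_id = sprintf("%s_r%02d",
                                               config$profile$subject_id, i))
  })
  list(records = purrr::map(out, "record"),
       truth = purrr::map_dfr(out, "truth"))
}
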