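#' Detect R-waves with the Pan-Tompkins algorithm
#'
#' Classical QRS detection: band-pass (5--15 Hz), five-point derivative,
#' squaring, 150 ms moving-window integration, then adaptive dual thresholds
#' on the integrated signal with search-back when an expected beat is
#' missed. Detected fiducials are refined to the local ECG maximum within
#' +/- 50 ms, a 200 ms refractory period is enforced, and RR intervals
#' outside 250--1500 ms are rejected during screening.
#'
#' @param ecg Band-pass-filtered ECG (mV).
#' @param fs Sampling rate; the detector is tuned for 1000 Hz.
#' @return An integer vector of 0-based R-peak sample indices, strictly
#'   increasing, with attribute `"fs"`.
#' @export
detect_r_peaks <- function(ecg, fs = 1000) {
  n <- length(ecg)
  if (n < 2 * fs) stop("ECG shorter than detector warm-up (need >= 2 s)", call. = FALSE)
  if (stats::var(ecg) < .Machine$double.eps) {
    warning("zero-variance ECG; no R-peaks detected")
    return(structure(integer(0), fs = fs))
  }

  f <- bandpass_zero_phase(ecg, fs, 5, 15, order = 2)
  # five-point derivative (transfer 1/8 [2 1 0 -1 -2] at unit delay)
  d <- stats::filter(f, c(2, 1, 0, -1, -2) / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  win <- round(0.150 * fs)
  mwi <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2))
  mwi[is.na(mwi)] <- 0

  refractory <- round(0.200 * fs)
  # candidate fiducials: local maxima of the integrated signal
  loc_max <- which(diff(sign(diff(mwi))) == -2) + 1
  if (!length(loc_max)) {
    warning("no QRS energy found")
    return(structure(integer(0), fs = fs))
  }

  spki <- max(mwi[seq_len(min(n, 2 * fs))]) * 0.4
  npki <- mean(mwi[seq_len(min(n, 2 * fs))]) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)

  peaks <- integer(0)
  rr_hist <- numeric(0)
  last_qrs <- -Inf
  last_val <- -Inf
  i <- 1
  while (i <= length(loc_max)) {
    p <- loc_max[i]
    v <- mwi[p]
    if (p - last_qrs <= refractory) {
      # two fiducials within the refractory period belong to one QRS:
      # keep the larger
      if (v > last_val && length(peaks)) {
        peaks[length(peaks)] <- p
        last_qrs <- p
        last_val <- v
        spki <- 0.125 * v + 0.875 * spki
        thr1 <- npki + 0.25 * (spki - npki)
      }
      i <- i + 1
      next
    }
    if (v >= thr1) {
      peaks <- c(peaks, p)
      if (length(peaks) >= 2) rr_hist <- utils::tail(c(rr_hist, p - last_qrs), 8)
      last_qrs <- p
      last_val <- v
      spki <- 0.125 * v + 0.875 * spki
    } else {
      npki <- 0.125 * v + 0.875 * npki
      # search-back: no beat for 1.66 x mean RR -> take best candidate above thr2
      if (length(rr_hist) >= 2 && (p - last_qrs) > 1.66 * mean(rr_hist)) {
        thr2 <- 0.5 * thr1
        miss <- loc_max[loc_max > last_qrs + refractory & loc_max < p]
        miss <- miss[mwi[miss] >= thr2]
        if (length(miss)) {
          pb <- miss[which.max(mwi[miss])]
          peaks <- sort(c(peaks, pb))
          rr_hist <- utils::tail(c(rr_hist, pb - last_qrs), 8)
          last_qrs <- max(peaks)
          spki <- 0.25 * mwi[pb] + 0.75 * spki
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
    i <- i + 1
  }
  if (!length(peaks)) {
    warning("no QRS energy above threshold")
    return(structure(integer(0), fs = fs))
  }

  # refine each fiducial to the local ECG maximum within +/- 50 ms
  hw <- round(0.050 * fs)
  refined <- vapply(peaks, function(p) {
    lo <- max(1, p - hw); hi <- min(n, p + hw)
    lo + which.max(ecg[lo:hi]) - 1L
  }, numeric(1))
  refined <- sort(unique(round(refined)))

  # physiological RR gating: drop the later peak of an impossibly short pair
  keep <- rep(TRUE, length(refined))
  min_rr <- 0.250 * fs
  last <- refined[1]
  for (k in seq_along(refined)[-1]) {
    if (refined[k] - last < min_rr) keep[k] <- FALSE else last <- refined[k]
  }
  refined <- refined[keep]
  structure(as.integer(refined - 1L), fs = fs) # 0-based
}

#' Split a record into R-to-R cardiac cycles
#'
#' Each cycle is the half-open interval `[R_k, R_{k+1})` in 0-based sample
#' coordinates; the final partial beat after the last R-wave is discarded.
#' The LVBP segment is attached only when the channel is present.
#'
#' @param record A `hemo_record` (normally already pre-filtered).
#' @param r_peaks 0-based R-peak indices from [detect_r_peaks()].
#' @return A tibble with one row per cycle: identifiers, `cycle_index`,
#'   `start`, `length`, and list-columns `pcg`, `ppg`, `bp` (the latter
#'   `NULL` per element when no LVBP is recorded).
#' @export
split_cycles <- function(record, r_peaks) {
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) < 2) {
    warning("fewer than 2 R-peaks; no cycles")
    return(empty_cycles())
  }
  has_bp <- !is.null(record$lvbp)
  starts <- r_peaks[-length(r_peaks)]
  lens <- diff(r_peaks)
  seg <- function(x, s, l) x[(s + 1):(s + l)] # 0-based start -> R indexing
  tibble::tibble(
    subject_id = record$subject_id,
    record_id = record$record_id,
    cycle_index = seq_along(starts),
    start = starts,
    length = lens,
    pcg = purrr::map2(starts, lens, ~seg(record$pcg, .x, .y)),
    ppg = purrr::map2(starts, lens, ~seg(record$ppg, .x, .y)),
    bp = if (has_bp) purrr::map2(starts, lens, ~seg(record$lvbp, .x, .y))
         else purrr::map(starts, ~NULL))
}

empty_cycles <- function() {
  tibble::tibble(subject_id = character(0), record_id = character(0),
                 cycle_index = integer(0), start = integer(0),
                 length = integer(0), pcg = list(), ppg = list(), bp = list())
}

#' Screen cycle signal quality
#'
#' Template-correlation gating: for PCG and PPG separately, every cycle is
#' resampled to a fixed length and correlated with a running template (an
#' exponentially weighted mean of previously accepted cycles, update weight
#' 0.1). The quality score is the smaller of the two channel correlations.
#' A cycle passes when the score reaches `threshold` and both channels pass
#' amplitude sanity checks (no flat line, no clipping at the channel rails).
#'
#' @param cycles Cycle tibble from [split_cycles()].
#' @param threshold Correlation threshold (default 0.8).
#' @param template_weight EWMA update weight for accepted cycles.
#' @param template_length Resampled comparison length.
#' @return `cycles` with `quality_score` and `quality_pass` columns added.
#' @export
assess_quality <- function(cycles, threshold = 0.8, template_weight = 0.1,
                           template_length = 300) {
  nc <- nrow(cycles)
  score <- numeric(nc); pass <- logical(nc)
  if (!nc) return(dplyr::mutate(cycles, quality_score = score, quality_pass = pass))
  tmpl <- list(pcg = NULL, ppg = NULL)
  rails <- list(
    pcg = range(unlist(cycles$pcg), finite = TRUE),
    ppg = range(unlist(cycles$ppg), finite = TRUE))
  for (i in seq_len(nc)) {
    sc <- 1; ok <- TRUE
    resampled <- list()
    for (ch in c("pcg", "ppg")) {
      x <- cycles[[ch]][[i]]
      if (!amplitude_sane(x, rails[[ch]])) { ok <- FALSE; sc <- 0; break }
      # heart sounds are narrow-band bursts whose carrier phase is not
      # beat-coherent; compare their envelope instead of the raw wave
      if (ch == "pcg") x <- envelope(x)
      xr <- stats::approx(seq_along(x), x, n = template_length)$y
      resampled[[ch]] <- xr
      if (!is.null(tmpl[[ch]])) sc <- min(sc, ncc_max(xr, tmpl[[ch]]))
    }
    score[i] <- max(0, sc)
    pass[i] <- ok && score[i] >= threshold
    if (pass[i]) {
      for (ch in c("pcg", "ppg")) {
        tmpl[[ch]] <- if (is.null(tmpl[[ch]])) resampled[[ch]]
          else (1 - template_weight) * tmpl[[ch]] + template_weight * resampled[[ch]]
      }
    }
  }
  dplyr::mutate(cycles, quality_score = score, quality_pass = pass)
}

# normalized cross-correlation maximized over lags (+/- 30% of length);
# the pulse-transit delay and heart-sound timing shift physiologically from
# beat to beat, so the quality score must be alignment-invariant
ncc_max <- function(x, y, max_lag_frac = 0.3, step = 2) {
  n <- length(x)
  max_lag <- floor(n * max_lag_frac)
  best <- -1
  for (lag in seq(-max_lag, max_lag, by = step)) {
    if (lag >= 0) { xa <- x[(1 + lag):n]; ya <- y[1:(n - lag)] }
    else { xa <- x[1:(n + lag)]; ya <- y[(1 - lag):n] }
    r <- suppressWarnings(stats::cor(xa, ya))
    if (is.finite(r) && r > best) best <- r
  }
  max(best, 0)
}

# 30 ms moving-average magnitude envelope
envelope <- function(x, width = 31) {
  e <- stats::filter(abs(x), rep(1 / width, width), sides = 2)
  e[is.na(e)] <- 0
  as.numeric(e)
}

amplitude_sane <- function(x, rail, clip_run = 5, var_eps = 1e-12) {
  if (stats::var(x) < var_eps) return(FALSE) # flat line
  span <- diff(rail)
  if (span <= 0) return(FALSE)
  # clipping shows as runs of samples pinned at a rail; a smooth waveform
  # touches its extreme only instantaneously
  at_rail <- x >= rail[2] - 1e-6 * span | x <= rail[1] + 1e-6 * span
  if (!any(at_rail)) return(TRUE)
  r <- rle(at_rail)
  max(r$lengths[r$values]) < clip_run
}

#' Zero-pad cycles to fixed 1 s model windows
#'
#' Produces the network input: a 1000-sample x 2-channel window per cycle
#' (PCG first, PPG second), zero-padded at the tail. Cycles longer than
#' 1000 samples (heart rate below 60 bpm) are excluded by default rather
#' than truncated, since truncation would discard diastolic content.
#'
#' @param cycles Cycle tibble (normally quality-screened).
#' @param window_length Samples per window (1000 = 1 s at 1 kHz).
#' @param long_cycle_policy `"exclude"` (default) flags over-long cycles as
#'   unusable; `"truncate"` keeps their first `window_length` samples.
#' @return `cycles` with list-column `window` (each a
#'   `window_length` x 2 matrix, or `NULL` when excluded) and logical
#'   `window_ok`.
#' @export
pad_to_window <- function(cycles, window_length = 1000,
                          long_cycle_policy = c("exclude", "truncate")) {
  long_cycle_policy <- match.arg(long_cycle_policy)
  mk <- function(pcg, ppg, len) {
    if (len > window_length) {
      if (long_cycle_policy == "exclude") return(NULL)
      pcg <- pcg[seq_len(window_length)]
      ppg <- ppg[seq_len(window_length)]
      len <- window_length
    }
    w <- matrix(0, window_length, 2)
    w[seq_len(len), 1] <- pcg
    w[seq_len(len), 2] <- ppg
    w
  }
  win <- purrr::pmap(list(cycles$pcg, cycles$ppg, cycles$length), mk)
  n_long <- sum(cycles$length > window_length)
  if (n_long > 0 && long_cycle_policy == "exclude")
    warning(n_long, " cycle(s) longer than ", window_length,
            " samples excluded", call. = FALSE)
  dplyr::mutate(cycles, window = win,
                window_ok = !vapply(win, is.null, logical(1)))
}

#' Segment a record end to end
#'
#' Convenience pipeline: R-peak detection, cycle splitting, quality
#' screening and window construction in one call.
#'
#' @inheritParams split_cycles
#' @inheritParams assess_quality
#' @inheritParams pad_to_window
#' @return Cycle tibble with quality and window columns.
#' @export
segment_record <- function(record, threshold = 0.8,
                           long_cycle_policy = c("exclude", "truncate")) {
  peaks <- detect_r_peaks(record$ecg, record$fs)
  cycles <- split_cycles(record, peaks)
  if (!nrow(cycles)) return(cycles)
  cycles <- assess_quality(cycles, threshold = threshold)
  pad_to_window(cycles, long_cycle_policy = long_cycle_policy)
}

#' Stack cycle windows into a model input array
#'
#' @param cycles Cycle tibble containing a `window` list-column.
#' @return A numeric array of dimension `c(1000, 2, n)`.
#' @export
windows_array <- function(cycles) {
  ok <- if ("window_ok" %in% names(cycles)) cycles$window_ok else rep(TRUE, nrow(cycles))
  w <- Filter(Negate(is.null), cycles$window[ok])
  if (!length(w)) stop("no usable windows", call. = FALSE)
  arr <- array(0, dim = c(nrow(w[[1]]), ncol(w[[1]]), length(w)))
  for (i in seq_along(w)) arr[, , i] <- w[[i]]
  arr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
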