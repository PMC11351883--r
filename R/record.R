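#' Multichannel cardiovascular recording
#'
#' A `hemo_record` holds one continuous recording session: synchronized ECG,
#' PCG (heart sounds), PPG (pulse wave) and — when available — invasive
#' left-ventricular blood pressure (LVBP), all sampled on a common 1 kHz
#' clock, plus subject/record/dose metadata.
#'
#' @param ecg ECG voltage series (mV).
#' @param pcg Phonocardiogram series (arbitrary units).
#' @param ppg Photoplethysmogram series (arbitrary units).
#' @param lvbp Left-ventricular pressure series (mmHg), or `NULL` for
#'   inference-only data.
#' @param fs Sampling rate in Hz (default 1000).
#' @param record_id,subject_id Identifiers.
#' @param dose Epinephrine dose label in units/kg (0.5, 1, 2) or `NA`.
#'
#' @return An object of class `hemo_record`.
#' @export
hemo_record <- function(ecg, pcg, ppg, lvbp = NULL, fs = 1000,
                        record_id = "r1", subject_id = "s1", dose = NA_real_) {
  x <- structure(
    list(record_id = as.character(record_id),
         subject_id = as.character(subject_id),
         fs = as.numeric(fs), dose = as.numeric(dose),
         ecg = as.numeric(ecg), pcg = as.numeric(pcg), ppg = as.numeric(ppg),
         lvbp = if (is.null(lvbp)) NULL else as.numeric(lvbp),
         filtered = FALSE),
    class = "hemo_record")
  validate_hemo_record(x)
}

validate_hemo_record <- function(x) {
  if (!is.numeric(x$fs) || length(x$fs) != 1 || x$fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  lens <- vapply(record_channels(x), function(ch) length(x[[ch]]), integer(1))
  if (any(lens != lens[1]))
    stop("all present channels must have identical length; got ",
         paste(paste0(record_channels(x), "=", lens), collapse = ", "),
         call. = FALSE)
  if (lens[1] < 1) stop("record must contain at least one sample", call. = FALSE)
  x
}

record_channels <- function(record) {
  chs <- c("ecg", "pcg", "ppg", "lvbp")
  chs[vapply(chs, function(ch) !is.null(record[[ch]]), logical(1))]
}

#' @export
print.hemo_record <- function(x, ...) {
  n <- n_samples(x)
  cat(sprintf("<hemo_record> %s / %s: %d samples (%.1f s at %g Hz), channels: %s%s\n",
              x$subject_id, x$record_id, n, n / x$fs, x$fs,
              paste(record_channels(x), collapse = ", "),
              if (isTRUE(x$filtered)) " [filtered]" else ""))
  invisible(x)
}

#' @export
#' @importFrom tibble as_tibble
as_tibble.hemo_record <- function(x, ...) {
  out <- tibble::tibble(t = (seq_len(n_samples(x)) - 1) / x$fs)
  for (ch in record_channels(x)) out[[ch]] <- x[[ch]]
  out
}

#' Number of samples in a record
#' @param record A `hemo_record`.
#' @return Integer sample count.
#' @export
n_samples <- function(record) length(record$ecg)

#' Per-channel band-pass filter specification
#'
#' The pre-filter passbands applied before any downstream analysis:
#' 30–200 Hz for PCG, 0.5–40 Hz for ECG, 0.5–20 Hz for PPG, and 0–20 Hz
#' (a pure low-pass) for LV pressure; all are applied as zero-phase
#' (forward–backward) Butterworth filters so no channel is delayed relative
#' to another. The pressure channel keeps its DC component because the
#' absolute calibrated level carries the SBP/DBP labels — a sub-hertz
#' high-pass would subtract the slow pressure excursion that the drug
#' response produces.
#'
#' @param order Butterworth design order for the one-way filter; the
#'   forward–backward application doubles the effective order.
#' @return A tibble with one row per channel: `channel`, `passband_low`
#'   (0 = low-pass), `passband_high`, `order`, `design`.
#' @export
filter_specs <- function(order = 4) {
  tibble::tibble(
    channel = c("ecg", "pcg", "ppg", "lvbp"),
    passband_low = c(0.5, 30, 0.5, 0),
    passband_high = c(40, 200, 20, 20),
    order = as.integer(order),
    design = "butterworth")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward so the net phase
#' response is zero (no time delay). The signal is extended at both ends by
#' odd-reflection padding before filtering and trimmed afterwards, which
#' suppresses start-up transients on short records.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param low,high Passband edges (Hz); must satisfy
#'   `0 <= low < high < fs/2`. `low = 0` designs a pure low-pass.
#' @param order Butterworth order of the one-way filter (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, low, high, order = 4) {
  if (!(low >= 0 && low < high && high < fs / 2))
    stop("invalid band edges: need 0 <= low < high < fs/2", call. = FALSE)
  # bandpass has 2*order+1 numerator taps; pad as filtfilt conventionally does
  padlen <- 3L * (2L * order + 1L)
  if (length(x) <= padlen)
    stop("signal too short for stable zero-phase filtering (need > ",
         padlen, " samples)", call. = FALSE)
  bf <- if (low > 0) signal::butter(order, c(low, high) / (fs / 2), type = "pass")
        else signal::butter(order, high / (fs / 2), type = "low")
  n <- length(x)
  # odd reflection about the end points
  head_pad <- 2 * x[1] - x[seq(padlen + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[seq(padlen + 1, padlen + n)]
}

#' Pre-filter all channels of a record
#'
#' Applies the per-channel zero-phase band-pass pre-filters from
#' [filter_specs()]: ECG 0.5–40 Hz, PCG 30–200 Hz, PPG and LVBP 0.5–20 Hz.
#' A record sampled at a rate other than 1 kHz is first resampled to 1 kHz
#' by polyphase resampling, since the model input window is defined in
#' samples at 1 kHz. A missing LVBP channel is skipped without error.
#'
#' @param record A `hemo_record`.
#' @param specs Filter specification tibble, defaults to [filter_specs()].
#' @return The filtered record; the specification applied is attached as
#'   attribute `"filters"` and `record$filtered` is set.
#' @export
preprocess_record <- function(record, specs = filter_specs()) {
  record <- validate_hemo_record(record)
  if (record$fs != 1000) {
    rr <- ratio_approx(1000 / record$fs)
    for (ch in record_channels(record))
      record[[ch]] <- as.numeric(signal::resample(record[[ch]], rr[1], rr[2]))
    record$fs <- 1000
  }
  for (ch in record_channels(record)) {
    sp <- specs[specs$channel == ch, ]
    if (nrow(sp) != 1) next
    record[[ch]] <- bandpass_zero_phase(record[[ch]], record$fs,
                                        sp$passband_low, sp$passband_high,
                                        sp$order)
  }
  record$filtered <- TRUE
  attr(record, "filters") <- specs
  record
}

# small rational approximation p/q for a resampling ratio
ratio_approx <- function(r, max_den = 1000) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), as.integer(q)) }
    if (err < 1e-12) break
  }
  best
}

#' Read a multichannel record
#'
#' Reads a record from the package's plain-text CSV layout: optional
#' metadata comment lines (`# key: value`) followed by a header row
#' `t,ecg,pcg,ppg,lvbp` (the `lvbp` column may be absent).
#'
#' @param path File path.
#' @param format Storage format; only `"csv"` is supported.
#' @return A `hemo_record`.
#' @export
read_record <- function(path, format = c("csv", "hdf5", "wfdb")) {
  format <- match.arg(format)
  if (format != "csv")
    stop("format '", format, "' is not supported by this build; use csv",
         call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta_lines <- character(0)
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    meta_lines <- c(meta_lines, ln)
  }
  meta <- list(record_id = "r1", subject_id = "s1", fs = 1000, dose = NA_real_)
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([a-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3 && m[2] %in% names(meta))
      meta[[m[2]]] <- if (m[2] %in% c("fs", "dose"))
        suppressWarnings(as.numeric(m[3])) else m[3]
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("ecg", "pcg", "ppg")
  if (!all(need %in% names(df)))
    stop("CSV must contain columns ", paste(need, collapse = ", "), call. = FALSE)
  lens <- vapply(df[intersect(c(need, "lvbp"), names(df))],
                 function(col) sum(!is.na(col)), integer(1))
  if (length(unique(lens[names(lens) != "lvbp"])) > 1 ||
      ("lvbp" %in% names(lens) && lens[["lvbp"]] > 0 &&
       lens[["lvbp"]] != lens[["ecg"]]))
    stop("channel length mismatch in ", path, call. = FALSE)
  lv <- if ("lvbp" %in% names(df) && any(!is.na(df$lvbp))) df$lvbp else NULL
  hemo_record(df$ecg, df$pcg, df$ppg, lv, fs = meta$fs,
              record_id = meta$record_id, subject_id = meta$subject_id,
              dose = meta$dose)
}

#' Write a multichannel record
#'
#' @param record A `hemo_record`.
#' @param path Output file path.
#' @param format Storage format; only `"csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "hdf5", "wfdb")) {
  format <- match.arg(format)
  if (format != "csv")
    stop("format '", format, "' is not supported by this build; use csv",
         call. = FALSE)
  record <- validate_hemo_record(record)
  hdr <- sprintf("# %s: %s",
                 c("record_id", "subject_id", "fs", "dose"),
                 c(record$record_id, record$subject_id,
                   format(record$fs), format(record$dose)))
  df <- as_tibble.hemo_record(record)
  writeLines(hdr, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
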