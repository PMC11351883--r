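#' Extract beat-wise hemodynamic parameters from an LV pressure segment
#'
#' For one R-to-R pressure segment: SBP is the peak systolic pressure (the
#' cycle maximum), DBP is the minimum pressure in the diastolic phase (after
#' the systolic peak), and MRR/MRD are the maximum and minimum of the
#' first-order pressure derivative (LV +dP/dt_max and -dP/dt_max, mmHg/s).
#' The derivative uses central differences scaled by `fs` (one-sided at the
#' segment edges); no extra smoothing is applied because the pressure
#' channel is already low-pass filtered at 20 Hz.
#'
#' @param bp_seg Pressure segment (mmHg), at least 5 samples.
#' @param fs Sampling rate (Hz).
#' @return A one-row tibble with `sbp`, `dbp`, `mrr`, `mrd`.
#' @export
extract_labels <- function(bp_seg, fs = 1000) {
  if (length(bp_seg) < 5) stop("pressure segment too short (need >= 5 samples)", call. = FALSE)
  if (any(!is.finite(bp_seg))) stop("non-finite pressure samples", call. = FALSE)
  n <- length(bp_seg)
  ipk <- which.max(bp_seg)
  sbp <- bp_seg[ipk]
  dbp <- min(bp_seg[ipk:n])
  d <- numeric(n)
  d[2:(n - 1)] <- (bp_seg[3:n] - bp_seg[1:(n - 2)]) * fs / 2
  d[1] <- (bp_seg[2] - bp_seg[1]) * fs
  d[n] <- (bp_seg[n] - bp_seg[n - 1]) * fs
  tibble::tibble(sbp = sbp, dbp = dbp, mrr = max(d), mrd = min(d))
}

#' Extract labels for every cycle of a segmented record
#'
#' @param cycles Cycle tibble with a `bp` list-column (see [split_cycles()]).
#' @param fs Sampling rate (Hz).
#' @return Label tibble: identifiers, `cycle_index`, `sbp`, `dbp`, `mrr`,
#'   `mrd`, and `repaired = FALSE`.
#' @export
extract_labels_cycles <- function(cycles, fs = 1000) {
  keep <- !vapply(cycles$bp, is.null, logical(1))
  if (!all(keep)) stop("cycles lack LVBP segments; labels need invasive pressure",
                       call. = FALSE)
  lab <- purrr::map_dfr(cycles$bp, extract_labels, fs = fs)
  dplyr::bind_cols(
    dplyr::select(cycles, dplyr::any_of(c("subject_id", "record_id", "cycle_index"))),
    lab, tibble::tibble(repaired = FALSE))
}

#' Repair beat-to-beat label outliers
#'
#' Implements the rule that parameters whose beat-to-beat difference values
#' are extreme (the "3 standard deviations from the mean" screen) are fixed
#' from nearby beats. For each record and each parameter independently, the
#' first-difference series is screened with a robust three-sigma rule
#' (median and 1.4826 x MAD of the differences; the moment estimates
#' themselves are masked by any large spike, which would hide exactly the
#' beats the rule is meant to catch). A beat is flagged as a spike when its
#' two adjacent differences are both extreme with opposite signs (an edge
#' beat when its single adjacent difference is extreme); flagged beats are
#' replaced by linear interpolation of the nearest unflagged neighbours.
#' A degenerate record with constant differences flags nothing.
#'
#' @param labels Label tibble from [extract_labels_cycles()], >= 3 rows per
#'   record.
#' @param params Parameter columns to screen.
#' @return `labels` with outliers repaired and `repaired` set on changed
#'   beats.
#' @export
fix_outliers <- function(labels, params = c("sbp", "dbp", "mrr", "mrd")) {
  if (!nrow(labels)) return(labels)
  grp <- if ("record_id" %in% names(labels)) labels$record_id else "all"
  out <- labels
  for (rid in unique(grp)) {
    idx <- which(grp == rid)
    if (length(idx) < 3)
      stop("need at least 3 beats per record to screen outliers", call. = FALSE)
    for (p in params) {
      x <- out[[p]][idx]
      fl <- flag_spikes(x)
      if (all(fl)) stop("all beats flagged in record ", rid, "; record unusable",
                        call. = FALSE)
      if (any(fl)) {
        ok <- which(!fl)
        x[fl] <- stats::approx(ok, x[ok], xout = which(fl), rule = 2)$y
        out[[p]][idx] <- x
        out$repaired[idx][fl] <- TRUE
      }
    }
  }
  out
}

flag_spikes <- function(x) {
  n <- length(x)
  d <- diff(x)
  med <- stats::median(d)
  scale <- 1.4826 * stats::median(abs(d - med))
  fl_d <- if (scale <= 0) rep(FALSE, n - 1) else abs(d - med) > 3 * scale
  fl <- rep(FALSE, n)
  if (n >= 3) {
    for (i in 2:(n - 1))
      fl[i] <- fl_d[i - 1] && fl_d[i] && sign(d[i - 1]) != sign(d[i])
  }
  # edge beats have only one adjacent difference
  if (fl_d[1] && !fl[2]) {
    ref <- stats::median(x)
    if (abs(x[1] - ref) > abs(x[2] - ref)) fl[1] <- TRUE
  }
  if (fl_d[n - 1] && !fl[n - 1]) {
    ref <- stats::median(x)
    if (abs(x[n] - ref) > abs(x[n - 1] - ref)) fl[n] <- TRUE
  }
  fl
}

# fixed divisors putting the four target scales on comparable footing
target_divisors <- function() c(sbp = 50, dbp = 10, mrr = 2000, mrd = 1000)

#' Scale labels to network targets (and back)
#'
#' Network reference outputs are SBP/50, DBP/10, MRR/2000 and MRD/1000 so
#' the four parameters contribute comparably to the squared-error loss.
#' `inverse_scale()` is the exact inverse.
#'
#' @param labels Data frame with columns `sbp`, `dbp`, `mrr`, `mrd` (extra
#'   columns pass through unchanged).
#' @return The data frame with scaled (or unscaled) parameter columns.
#' @export
scale_targets <- function(labels) {
  div <- target_divisors()
  for (p in names(div)) labels[[p]] <- labels[[p]] / div[[p]]
  labels
}

#' @rdname scale_targets
#' @param targets Data frame of scaled targets.
#' @export
inverse_scale <- function(targets) {
  div <- target_divisors()
  for (p in names(div)) targets[[p]] <- targets[[p]] * div[[p]]
  targets
}
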