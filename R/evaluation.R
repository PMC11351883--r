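#' Within-subject five-fold split at record level
#'
#' Implements the record-level 3-1-1 train/validation/test protocol: the
#' records are shuffled and divided into `k` near-equal subsets; each
#' subset is the test set of one fold and the remaining records are split
#' 3:1 into training and validation. Splits are always at record level,
#' never at cycle level, so no cycle from a test record can leak into
#' training through the similarity of neighbouring beats.
#'
#' @param record_ids Character vector of record identifiers (one subject).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffles.
#' @return A `hemo_split_plan`: tibble with `fold` and list-columns
#'   `train`, `validation`, `test`.
#' @export
make_folds_scheme1 <- function(record_ids, k = 5, seed = 1) {
  record_ids <- as.character(record_ids)
  n <- length(record_ids)
  if (n < k) stop("need at least ", k, " records for ", k, "-fold splitting",
                  call. = FALSE)
  set.seed(seed)
  shuffled <- sample(record_ids)
  # near-equal subset sizes: first (n mod k) subsets get the extra record
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  subsets <- split(shuffled, rep(seq_len(k), times = sizes))
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    test <- subsets[[f]]
    rest <- sample(setdiff(shuffled, test))
    n_train <- round(length(rest) * 3 / 4)
    tibble::tibble(fold = f,
                   train = list(rest[seq_len(n_train)]),
                   validation = list(rest[-seq_len(n_train)]),
                   test = list(test))
  })
  new_split_plan(folds, scheme = "within_subject_5fold", seed = seed)
}

#' Cross-subject split
#'
#' The target subject's records are held out entirely: all other subjects'
#' records form the training set, and the target's records are divided into
#' two equal halves, one for validation and one for testing, which are then
#' swapped for a second pass.
#'
#' @param records_by_subject Tibble with columns `subject_id`, `record_id`.
#' @param target_subject The held-out subject.
#' @param seed Integer seed.
#' @return A `hemo_split_plan` with two rows (the swapped passes).
#' @export
make_split_scheme2 <- function(records_by_subject, target_subject, seed = 1) {
  stopifnot(all(c("subject_id", "record_id") %in% names(records_by_subject)))
  subj <- unique(records_by_subject$subject_id)
  if (!target_subject %in% subj)
    stop("target subject '", target_subject, "' not present", call. = FALSE)
  if (length(setdiff(subj, target_subject)) < 1)
    stop("need at least one other subject to train on", call. = FALSE)
  train <- records_by_subject$record_id[records_by_subject$subject_id != target_subject]
  target <- records_by_subject$record_id[records_by_subject$subject_id == target_subject]
  if (length(target) < 2)
    stop("target subject needs at least 2 records", call. = FALSE)
  set.seed(seed)
  target <- sample(target)
  half <- ceiling(length(target) / 2)
  a <- target[seq_len(half)]; b <- target[-seq_len(half)]
  folds <- tibble::tibble(fold = 1:2,
                          train = list(train, train),
                          validation = list(a, b),
                          test = list(b, a))
  new_split_plan(folds, scheme = "cross_subject", seed = seed,
                 target_subject = target_subject)
}

#' Cross-subject split with target-subject calibration
#'
#' Identical to [make_split_scheme2()] except that `n_cal` records are
#' moved from each pass's validation set into its training set, giving the
#' model a little individual information about the target subject. Test
#' sets are unchanged.
#'
#' @inheritParams make_split_scheme2
#' @param n_cal Number of validation records moved into training.
#' @return A `hemo_split_plan`.
#' @export
make_split_calibration <- function(records_by_subject, target_subject,
                                   n_cal = 1, seed = 1) {
  plan <- make_split_scheme2(records_by_subject, target_subject, seed = seed)
  if (n_cal == 0) {
    attr(plan, "scheme") <- "cross_subject_calibrated"
    return(plan)
  }
  for (i in seq_len(nrow(plan))) {
    val <- plan$validation[[i]]
    if (n_cal >= length(val))
      stop("n_cal must leave at least one validation record", call. = FALSE)
    cal <- val[seq_len(n_cal)]
    plan$train[[i]] <- c(plan$train[[i]], cal)
    plan$validation[[i]] <- setdiff(val, cal)
  }
  attr(plan, "scheme") <- "cross_subject_calibrated"
  plan
}

new_split_plan <- function(folds, scheme, seed, target_subject = NULL) {
  plan <- structure(folds, class = c("hemo_split_plan", class(folds)),
                    scheme = scheme, seed = seed)
  if (!is.null(target_subject)) attr(plan, "target_subject") <- target_subject
  validate_split_plan(plan)
}

validate_split_plan <- function(plan) {
  for (i in seq_len(nrow(plan))) {
    sets <- list(plan$train[[i]], plan$validation[[i]], plan$test[[i]])
    pairs <- utils::combn(3, 2)
    for (j in seq_len(ncol(pairs))) {
      ov <- intersect(sets[[pairs[1, j]]], sets[[pairs[2, j]]])
      if (length(ov))
        stop("split sets overlap in fold ", i, ": ", paste(ov, collapse = ", "),
             call. = FALSE)
    }
  }
  plan
}

#' Agreement metrics between estimated and measured parameters
#'
#' For each parameter: mean error ME, mean absolute error MAE, the standard
#' deviation SD of the mean-centred errors (N-1 denominator), and the
#' Pearson correlation coefficient CC with a two-sided t-test p-value
#' (N-2 degrees of freedom) and a 95% Fisher-z confidence interval.
#'
#' @param estimated,measured Data frames with columns `sbp`, `dbp`, `mrr`,
#'   `mrd` (or numeric vectors for a single parameter).
#' @return A tibble with one row per parameter: `parameter`, `n`, `me`,
#'   `mae`, `sd`, `cc`, `p_value`, `ci_low`, `ci_high`, `cc_defined`.
#' @export
compute_metrics <- function(estimated, measured) {
  if (is.numeric(estimated) && is.null(dim(estimated))) {
    estimated <- tibble::tibble(value = estimated)
    measured <- tibble::tibble(value = measured)
  }
  estimated <- tibble::as_tibble(estimated)
  measured <- tibble::as_tibble(measured)
  params <- intersect(names(estimated), names(measured))
  params <- params[vapply(estimated[params], is.numeric, logical(1))]
  if (!length(params)) stop("no shared numeric parameter columns", call. = FALSE)
  if (nrow(estimated) != nrow(measured))
    stop("estimated and measured must be paired (equal length)", call. = FALSE)
  purrr::map_dfr(params, function(p) {
    yhat <- estimated[[p]]; y <- measured[[p]]
    e <- yhat - y
    n <- length(e)
    me <- mean(e)
    out <- tibble::tibble(parameter = p, n = n, me = me, mae = mean(abs(e)),
                          sd = stats::sd(e), cc = NA_real_,
                          p_value = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, cc_defined = FALSE)
    if (n >= 3 && stats::sd(y) > 0 && stats::sd(yhat) > 0) {
      r <- stats::cor(yhat, y)
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      pv <- 2 * stats::pt(-abs(tt), df = n - 2)
      z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
      hw <- 1.96 / sqrt(n - 3)
      out$cc <- r; out$p_value <- pv
      out$ci_low <- tanh(z - hw); out$ci_high <- tanh(z + hw)
      out$cc_defined <- TRUE
    }
    out
  })
}

#' Run an evaluation scheme end to end
#'
#' For every fold (or pass) of a split plan: assemble the training,
#' validation and test windows from the per-record data, train the network,
#' predict the held-out test records, and compute agreement metrics. Fold
#' metrics are aggregated as their unweighted mean (a cycle-weighted mean is
#' also reported).
#'
#' @param data Tibble with one row per usable cycle: `record_id`, a
#'   `window` list-column, and label columns `sbp`, `dbp`, `mrr`, `mrd` in
#'   physical units (see [prepare_model_data()]).
#' @param plan A `hemo_split_plan`.
#' @param config A [model_config()].
#' @param epochs Training epochs per fold (defaults to the configuration).
#' @return A `hemo_eval` object: per-fold metrics, aggregate metrics,
#'   predictions and training histories.
#' @export
run_scheme <- function(data, plan, config = model_config(), epochs = NULL) {
  stopifnot(all(c("record_id", "window", names(target_divisors())) %in% names(data)))
  missing_rec <- setdiff(unlist(c(plan$train, plan$validation, plan$test)),
                         unique(data$record_id))
  if (length(missing_rec))
    stop("plan references absent records: ", paste(missing_rec, collapse = ", "),
         call. = FALSE)
  scaled <- scale_targets(data)
  folds <- seq_len(nrow(plan))
  fold_out <- purrr::map(folds, function(f) {
    pick <- function(ids) scaled[scaled$record_id %in% ids, ]
    tr <- pick(plan$train[[f]]); va <- pick(plan$validation[[f]])
    te <- pick(plan$test[[f]])
    est <- build_estimator(config)
    fit <- train_estimator(est,
                           windows_array(tr), as_target_matrix(tr),
                           windows_array(va), as_target_matrix(va),
                           epochs = epochs)
    pred <- predict(fit, windows_array(te))
    meas <- inverse_scale(te[names(target_divisors())])
    met <- compute_metrics(pred, meas)
    list(metrics = dplyr::mutate(met, fold = f, .before = 1),
         predictions = dplyr::bind_cols(
           tibble::tibble(fold = f, record_id = te$record_id,
                          cycle_index = te$cycle_index %||% seq_len(nrow(te))),
           stats::setNames(pred, paste0("est_", names(pred))),
           stats::setNames(meas, paste0("meas_", names(meas)))),
         history = dplyr::mutate(glance.hemo_trained(fit), fold = f))
  })
  per_fold <- purrr::map_dfr(fold_out, "metrics")
  aggregate <- per_fold |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      n = sum(.data$n),
      dplyr::across(c("me", "mae", "sd", "cc"), mean),
      cc_weighted = sum(.data$cc * .data$n) / sum(.data$n),
      .groups = "drop")
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 predictions = purrr::map_dfr(fold_out, "predictions"),
                 fits = purrr::map_dfr(fold_out, "history"),
                 scheme = attr(plan, "scheme"), seed = attr(plan, "seed")),
            class = "hemo_eval")
}

#' @export
print.hemo_eval <- function(x, ...) {
  cat(sprintf("<hemo_eval> scheme %s: %d fold(s)\n", x$scheme, nrow(x$fits)))
  print(x$aggregate)
  invisible(x)
}

#' Tidy per-fold evaluation metrics
#' @param x A `hemo_eval`.
#' @param ... Unused.
#' @return The per-fold metrics tibble.
#' @export
tidy.hemo_eval <- function(x, ...) x$per_fold

#' Aggregate evaluation summary
#' @param x A `hemo_eval`.
#' @param ... Unused.
#' @return The across-fold aggregate metrics tibble.
#' @export
glance.hemo_eval <- function(x, ...) x$aggregate

#' Plot estimated against measured parameter traces
#'
#' @param object A `hemo_eval`.
#' @param type `"trace"` for beat-indexed overlay of estimated and measured
#'   values, `"scatter"` for the correlation view.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hemo_eval <- function(object, type = c("trace", "scatter"), ...) {
  type <- match.arg(type)
  long <- object$predictions |>
    dplyr::mutate(beat = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::matches("^(est|meas)_"),
                        names_to = c("source", "parameter"), names_sep = "_",
                        values_to = "value")
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$beat, y = .data$value,
                                       colour = .data$source)) +
      ggplot2::geom_line(alpha = 0.8) +
      ggplot2::facet_wrap(~.data$parameter, scales = "free_y") +
      ggplot2::labs(x = "beat", y = NULL, colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    wide <- tidyr::pivot_wider(long, names_from = "source", values_from = "value")
    ggplot2::ggplot(wide, ggplot2::aes(x = .data$meas, y = .data$est)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.6) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::facet_wrap(~.data$parameter, scales = "free") +
      ggplot2::labs(x = "measured", y = "estimated") +
      ggplot2::theme_minimal()
  }
}

#' Assemble per-cycle model data
#'
#' Joins quality-passed, windowed cycles with their (repaired) labels into
#' the flat per-beat table consumed by [run_scheme()].
#'
#' @param cycles Cycle tibble after [segment_record()] / [pad_to_window()].
#' @param labels Label tibble after [fix_outliers()].
#' @return Tibble with `record_id`, `cycle_index`, `window` and the four
#'   label columns, restricted to usable cycles.
#' @export
prepare_model_data <- function(cycles, labels) {
  ok <- cycles$quality_pass & cycles$window_ok
  usable <- cycles[ok, c("subject_id", "record_id", "cycle_index", "window")]
  dplyr::inner_join(usable, labels,
                    by = intersect(c("subject_id", "record_id", "cycle_index"),
                                   names(labels)))
}
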