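#' Process records into model-ready beats
#'
#' Runs the full preprocessing chain on a list of records: per-channel
#' zero-phase filtering, R-peak detection, cycle segmentation, quality
#' screening, window construction, label extraction from LV pressure and
#' beat-to-beat outlier repair, returning the flat per-beat table consumed
#' by [run_scheme()].
#'
#' @param records A list of [hemo_record()] objects (each with LVBP).
#' @param quality_threshold Correlation threshold for quality screening.
#' @return Tibble with one row per usable beat: `subject_id`, `record_id`,
#'   `cycle_index`, `window`, `sbp`, `dbp`, `mrr`, `mrd`, `repaired`.
#' @export
process_records <- function(records, quality_threshold = 0.8) {
  purrr::map_dfr(records, function(rec) {
    prec <- preprocess_record(rec)
    cyc <- segment_record(prec, threshold = quality_threshold)
    if (!nrow(cyc)) return(NULL)
    lab <- fix_outliers(extract_labels_cycles(cyc, fs = prec$fs))
    prepare_model_data(cyc, lab)
  })
}

#' Records-by-subject index of a beat table
#'
#' @param data Per-beat tibble from [process_records()].
#' @return Tibble with unique `subject_id`, `record_id` pairs.
#' @export
records_index <- function(data) {
  dplyr::distinct(data, .data$subject_id, .data$record_id)
}
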