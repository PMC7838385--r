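#' Quality-filter probe cells by signal-to-noise ratio
#'
#' A (probe, sample) cell is kept as detected only when its SNR is strictly
#' greater than `snr_min` (default 2); cells at or below the cutoff become
#' undetected and probes left with no detected cell drop out of the table.
#'
#' @param signal long raw probe table with columns `probe_id`, `sample_id`,
#'   `signal`, `snr` (rows are detected cells).
#' @param snr_min SNR cutoff; strict inequality.
#' @return the filtered long table.
#' @export
filter_by_snr <- function(signal, snr_min = 2) {
  if (!"snr" %in% names(signal)) abort("input has no `snr` column")
  if (nrow(signal) == 0) abort("input table is empty")
  out <- dplyr::filter(signal, .data$snr > snr_min)
  if (nrow(out) == 0) {
    warn("no cell passed the SNR filter; returning an empty table")
  }
  out
}

#' Prevalence-filter probes by within-lake detection counts
#'
#' Keeps a probe when it is detected in at least `min_detected_per_lake`
#' samples of at least one lake (default 2, i.e. more than ~30% of six
#' samples). With `min_detected_per_lake = NULL` the rule generalizes to
#' `ceiling(0.3 * n)` for a lake with `n` samples.
#'
#' @param signal SNR-filtered long probe table.
#' @param design study design (`sample_id`, `lake_id`, `elevation_group`).
#' @param min_detected_per_lake detection count required within one lake,
#'   or NULL for the 30% rule.
#' @return the filtered long table.
#' @export
filter_by_prevalence <- function(signal, design, min_detected_per_lake = 2) {
  assert_design(design)
  missing_samples <- setdiff(unique(signal$sample_id), design$sample_id)
  if (length(missing_samples)) {
    abort(paste0("samples absent from the study design: ",
                 paste(missing_samples, collapse = ", ")))
  }
  lake_sizes <- dplyr::count(design, .data$lake_id, name = "n_samples")
  counts <- signal |>
    dplyr::left_join(design[, c("sample_id", "lake_id")], by = "sample_id") |>
    dplyr::count(.data$probe_id, .data$lake_id, name = "n_detected") |>
    dplyr::left_join(lake_sizes, by = "lake_id")
  counts$needed <- if (is.null(min_detected_per_lake)) {
    ceiling(0.3 * counts$n_samples)
  } else {
    min_detected_per_lake
  }
  keep <- unique(counts$probe_id[counts$n_detected >= counts$needed])
  dplyr::filter(signal, .data$probe_id %in% keep)
}

#' Transform and normalize signal intensities
#'
#' Per sample, each detected signal is `ln(x + 1)`-transformed and then
#' divided by the mean intensity of the positive-control probes of that
#' sample. By default the divisor is the mean of the *transformed* control
#' intensities so both operands share a scale; `divide = "raw"` instead
#' divides the raw signal by the mean raw control intensity before the log
#' transform. Undetected cells become 0 and positive-control probes are
#' dropped from the output matrix.
#'
#' @param signal filtered long probe table including positive-control rows
#'   (`is_positive_control` column).
#' @param divide `"transformed"` (default) or `"raw"`; see Details.
#' @return a signal matrix: tibble with `probe_id` and one numeric column per
#'   sample, carrying `transformed`/`normalized` provenance attributes.
#' @export
normalize_signals <- function(signal, divide = c("transformed", "raw")) {
  divide <- match.arg(divide)
  if (!"is_positive_control" %in% names(signal)) {
    abort("input has no `is_positive_control` column")
  }
  samples <- sort(unique(signal$sample_id))
  pos <- dplyr::filter(signal, .data$is_positive_control)
  no_ctrl <- setdiff(samples, unique(pos$sample_id))
  if (length(no_ctrl)) {
    abort(paste0("no detected positive-control probe in sample(s): ",
                 paste(no_ctrl, collapse = ", ")))
  }
  if (divide == "transformed") {
    denom <- pos |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(denom = mean(log(.data$signal + 1)), .groups = "drop")
    vals <- signal |>
      dplyr::left_join(denom, by = "sample_id") |>
      dplyr::mutate(value = log(.data$signal + 1) / .data$denom)
  } else {
    denom <- pos |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(denom = mean(.data$signal), .groups = "drop")
    vals <- signal |>
      dplyr::left_join(denom, by = "sample_id") |>
      dplyr::mutate(value = log(.data$signal / .data$denom + 1))
  }
  wide <- vals |>
    dplyr::filter(!.data$is_positive_control) |>
    dplyr::select("probe_id", "sample_id", "value") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value",
                       values_fill = 0) |>
    dplyr::arrange(.data$probe_id)
  # samples where only controls were detected still need a (zero) column
  for (s in setdiff(samples, names(wide))) wide[[s]] <- 0
  wide <- wide[, c("probe_id", samples)]
  new_signal_matrix(wide, transformed = TRUE, normalized = TRUE)
}

#' Convert normalized intensities to relative intensities
#'
#' Divides each probe's normalized intensity by the total normalized
#' intensity of its sample, so every sample column sums to 1.
#'
#' @param sig a normalized signal matrix from [normalize_signals()].
#' @return a relative signal matrix (columns sum to 1).
#' @export
relative_intensity <- function(sig) {
  assert_signal_stage(sig, normalized = TRUE, relative = FALSE)
  m <- signal_as_matrix(sig)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort(paste0("sample(s) with zero total intensity: ",
                 paste(colnames(m)[totals <= 0], collapse = ", ")))
  }
  rel <- sweep(m, 2, totals, "/")
  out <- dplyr::bind_cols(tibble::tibble(probe_id = sig$probe_id),
                          tibble::as_tibble(rel))
  new_signal_matrix(out, transformed = TRUE, normalized = TRUE, relative = TRUE)
}

#' Group difference in total signal intensity
#'
#' For each gene family, subcategory or category, sums the chosen intensity
#' over all member probes and all samples of each elevation group and
#' reports `delta = S_high / S_low - 1`, the fractional change in the
#' high-elevation group relative to the low-elevation group. Units whose
#' low-group total is zero are flagged (`undefined = TRUE`) rather than
#' divided.
#'
#' @param sig a (normalized or relative) signal matrix.
#' @param design study design.
#' @param annotation probe annotation table.
#' @param level `"gene_family"`, `"subcategory"` or `"category"`.
#' @return tibble with `unit`, `s_high`, `s_low`, `delta`, `undefined`.
#' @export
group_difference <- function(sig, design, annotation,
                             level = c("gene_family", "subcategory", "category")) {
  level <- match.arg(level)
  assert_design(design)
  signal_long(sig) |>
    dplyr::inner_join(annotation[, c("probe_id", level)], by = "probe_id") |>
    dplyr::inner_join(design[, c("sample_id", "elevation_group")], by = "sample_id") |>
    dplyr::group_by(unit = .data[[level]], .data$elevation_group) |>
    dplyr::summarise(s = sum(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "elevation_group", values_from = "s",
                       values_fill = 0, names_prefix = "s_") |>
    dplyr::mutate(
      undefined = .data$s_low <= 0,
      delta = dplyr::if_else(.data$undefined, NA_real_,
                             .data$s_high / .data$s_low - 1)
    ) |>
    dplyr::select("unit", "s_high", "s_low", "delta", "undefined")
}
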