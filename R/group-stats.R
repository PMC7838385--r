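#' Functional gene richness per sample and per group
#'
#' A probe counts as detected in a sample when its (normalized) intensity is
#' greater than zero; group richness counts probes detected in at least one
#' sample of the group. Counts are reported overall and per functional
#' category.
#'
#' @param sig a signal matrix.
#' @param design study design.
#' @param annotation probe annotation table.
#' @return tibble with `level` ("sample" or "group"), `id`, `category`
#'   (including `"all"`), `richness`.
#' @export
richness <- function(sig, design, annotation) {
  assert_design(design)
  det <- signal_long(sig) |>
    dplyr::filter(.data$value > 0) |>
    dplyr::left_join(annotation[, c("probe_id", "category")], by = "probe_id") |>
    dplyr::left_join(design[, c("sample_id", "elevation_group")], by = "sample_id")

  per_sample <- dplyr::bind_rows(
    dplyr::count(det, id = .data$sample_id, name = "richness") |>
      dplyr::mutate(category = "all"),
    dplyr::count(det, id = .data$sample_id, .data$category, name = "richness")
  ) |> dplyr::mutate(level = "sample")

  grp <- dplyr::distinct(det, .data$elevation_group, .data$probe_id, .data$category)
  per_group <- dplyr::bind_rows(
    dplyr::count(grp, id = .data$elevation_group, name = "richness") |>
      dplyr::mutate(category = "all"),
    dplyr::count(grp, id = .data$elevation_group, .data$category, name = "richness")
  ) |> dplyr::mutate(level = "group")

  dplyr::bind_rows(per_sample, per_group)[, c("level", "id", "category", "richness")]
}

#' Shared and unique detected genes between the two groups
#'
#' Set algebra on the group-level detected-probe sets: probes detected in at
#' least one sample of each group. Percentages use the union of the two sets
#' as denominator; per-group denominators are emitted alongside since figure
#' conventions differ.
#'
#' @param sig a signal matrix.
#' @param design study design.
#' @param scope `"all"` for one overall row, `"category"` for one row per
#'   functional category (requires `annotation`).
#' @param annotation probe annotation table (needed for `scope = "category"`).
#' @return tibble with counts, union-based percentages (summing to 100) and
#'   per-group-denominator percentages.
#' @export
overlap <- function(sig, design, scope = c("all", "category"), annotation = NULL) {
  scope <- match.arg(scope)
  assert_design(design)
  det <- signal_long(sig) |>
    dplyr::filter(.data$value > 0) |>
    dplyr::left_join(design[, c("sample_id", "elevation_group")], by = "sample_id") |>
    dplyr::distinct(.data$probe_id, .data$elevation_group)
  if (scope == "category") {
    if (is.null(annotation)) abort("`annotation` is required for scope = 'category'")
    det <- dplyr::left_join(det, annotation[, c("probe_id", "category")], by = "probe_id")
  } else {
    det$category <- "all"
  }
  det |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_low = dplyr::n_distinct(.data$probe_id[.data$elevation_group == "low"]),
      n_high = dplyr::n_distinct(.data$probe_id[.data$elevation_group == "high"]),
      n_shared = dplyr::n_distinct(intersect(
        .data$probe_id[.data$elevation_group == "low"],
        .data$probe_id[.data$elevation_group == "high"])),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_unique_low = .data$n_low - .data$n_shared,
      n_unique_high = .data$n_high - .data$n_shared,
      n_union = .data$n_shared + .data$n_unique_low + .data$n_unique_high,
      pct_shared = 100 * .data$n_shared / .data$n_union,
      pct_unique_low = 100 * .data$n_unique_low / .data$n_union,
      pct_unique_high = 100 * .data$n_unique_high / .data$n_union,
      pct_shared_of_low = 100 * .data$n_shared / .data$n_low,
      pct_shared_of_high = 100 * .data$n_shared / .data$n_high
    )
}

#' Two-group tests on summed intensities per functional unit
#'
#' For each category, subcategory or gene family, sums the intensity over
#' member probes within each sample, then compares the two elevation groups
#' with a two-sided two-sample t test (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance variant). Units with fewer
#' than two samples carrying signal in a group are flagged not-testable
#' instead of raising.
#'
#' @param sig a signal matrix.
#' @param design study design.
#' @param annotation probe annotation table.
#' @param level `"category"`, `"subcategory"` or `"gene_family"`.
#' @param var_equal pooled-variance t test if TRUE.
#' @param adjust add a Benjamini-Hochberg adjusted `p_adj` column.
#' @return tibble with group means and standard errors, `statistic`, `df`,
#'   `p_value` and `testable`.
#' @export
category_ttest <- function(sig, design, annotation,
                           level = c("category", "subcategory", "gene_family"),
                           var_equal = FALSE, adjust = FALSE) {
  level <- match.arg(level)
  assert_design(design)
  sums <- signal_long(sig) |>
    dplyr::inner_join(annotation[, c("probe_id", level)], by = "probe_id") |>
    dplyr::group_by(unit = .data[[level]], .data$sample_id) |>
    dplyr::summarise(total = sum(.data$value), .groups = "drop") |>
    tidyr::complete(.data$unit, sample_id = design$sample_id,
                    fill = list(total = 0)) |>
    dplyr::left_join(design[, c("sample_id", "elevation_group")], by = "sample_id")

  out <- sums |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(
      n_low = sum(.data$elevation_group == "low"),
      n_high = sum(.data$elevation_group == "high"),
      mean_low = mean(.data$total[.data$elevation_group == "low"]),
      mean_high = mean(.data$total[.data$elevation_group == "high"]),
      se_low = sd(.data$total[.data$elevation_group == "low"]) / sqrt(.data$n_low),
      se_high = sd(.data$total[.data$elevation_group == "high"]) / sqrt(.data$n_high),
      present_low = any(.data$total[.data$elevation_group == "low"] > 0),
      present_high = any(.data$total[.data$elevation_group == "high"] > 0),
      test = list(safe_t_test(.data$total[.data$elevation_group == "high"],
                              .data$total[.data$elevation_group == "low"],
                              var_equal = var_equal)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      testable = .data$present_low & .data$present_high,
      statistic = ifelse(.data$testable,
                         purrr::map_dbl(.data$test, "statistic"), NA_real_),
      df = ifelse(.data$testable, purrr::map_dbl(.data$test, "df"), NA_real_),
      p_value = ifelse(.data$testable,
                       purrr::map_dbl(.data$test, "p_value"), NA_real_)
    ) |>
    dplyr::select(-"test", -"present_low", -"present_high")
  if (adjust) out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

#' Taxa-function aggregation and per-lineage tests within a category
#'
#' Sums intensities within (lineage, category) before testing, so that
#' category-level differences can be attributed to lineages. Lineages whose
#' signal is entirely absent from one group are reported as group-exclusive
#' and not tested.
#'
#' @param sig a signal matrix.
#' @param annotation probe annotation with a lineage column.
#' @param design study design.
#' @param category functional category to decompose.
#' @param lineage_level annotation column holding the lineage (default
#'   `"lineage"`).
#' @return tibble with per-lineage group totals, `exclusive_to` ("low",
#'   "high" or NA) and Welch test results for testable lineages.
#' @export
taxa_function_aggregate <- function(sig, annotation, design, category,
                                    lineage_level = "lineage") {
  assert_design(design)
  if (!category %in% annotation$category) {
    abort(paste0("unknown category: ", category))
  }
  probes <- annotation$probe_id[annotation$category == category]
  ann <- annotation[annotation$probe_id %in% probes, c("probe_id", lineage_level)]
  sums <- signal_long(sig) |>
    dplyr::inner_join(ann, by = "probe_id") |>
    dplyr::group_by(lineage = .data[[lineage_level]], .data$sample_id) |>
    dplyr::summarise(total = sum(.data$value), .groups = "drop") |>
    tidyr::complete(.data$lineage, sample_id = design$sample_id,
                    fill = list(total = 0)) |>
    dplyr::left_join(design[, c("sample_id", "elevation_group")], by = "sample_id")

  sums |>
    dplyr::group_by(.data$lineage) |>
    dplyr::summarise(
      s_low = sum(.data$total[.data$elevation_group == "low"]),
      s_high = sum(.data$total[.data$elevation_group == "high"]),
      test = list(safe_t_test(.data$total[.data$elevation_group == "high"],
                              .data$total[.data$elevation_group == "low"])),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      exclusive_to = dplyr::case_when(
        .data$s_low > 0 & .data$s_high == 0 ~ "low",
        .data$s_high > 0 & .data$s_low == 0 ~ "high",
        TRUE ~ NA_character_
      ),
      statistic = ifelse(is.na(.data$exclusive_to),
                         purrr::map_dbl(.data$test, "statistic"), NA_real_),
      p_value = ifelse(is.na(.data$exclusive_to),
                       purrr::map_dbl(.data$test, "p_value"), NA_real_)
    ) |>
    dplyr::select(-"test")
}
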