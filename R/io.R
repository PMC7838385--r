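#' Read a probe signal table
#'
#' Parses the canonical wide TSV dialect: annotation columns `probe_id`,
#' `gene_family`, `subcategory`, `category`, `lineage`, `is_positive`,
#' followed by one `<sample>_signal` / `<sample>_snr` column pair per sample.
#' Empty cells mark undetected (probe, sample) cells.
#'
#' @param path path to a TSV file.
#' @return list with `signal` (long tibble: `probe_id`, `sample_id`,
#'   `signal`, `snr`, `is_positive_control`) and `annotation`.
#' @export
read_signal_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ann_cols <- c("probe_id", "gene_family", "subcategory", "category",
                "lineage", "is_positive")
  missing_cols <- setdiff(ann_cols, names(df))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$probe_id)) {
    abort(paste0("duplicate probe_id: ",
                 paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", ")))
  }
  value_cols <- setdiff(names(df), ann_cols)
  sig_cols <- grep("_signal$", value_cols, value = TRUE)
  snr_cols <- grep("_snr$", value_cols, value = TRUE)
  samples <- sub("_signal$", "", sig_cols)
  missing_snr <- setdiff(paste0(samples, "_snr"), snr_cols)
  if (length(missing_snr) || length(sig_cols) == 0) {
    abort(paste0("every sample needs a _signal and a _snr column; missing: ",
                 paste(c(if (!length(sig_cols)) "*_signal", missing_snr),
                       collapse = ", ")))
  }
  for (col in c(sig_cols, snr_cols)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(as.numeric(df[[col]]))))
      abort(paste0("non-numeric value in column ", col,
                   " at data line(s): ", paste(head(bad, 5), collapse = ", ")))
    }
  }
  long <- purrr::map_dfr(samples, function(s) {
    tibble::tibble(
      probe_id = df$probe_id,
      sample_id = s,
      signal = df[[paste0(s, "_signal")]],
      snr = df[[paste0(s, "_snr")]],
      is_positive_control = df$is_positive
    )
  }) |> dplyr::filter(!is.na(.data$signal)) |>
    dplyr::arrange(.data$probe_id, .data$sample_id)
  annotation <- tibble::as_tibble(df[, ann_cols]) |>
    dplyr::rename(is_positive_control = "is_positive")
  list(signal = long, annotation = annotation)
}

#' Write a probe signal table
#'
#' Inverse of [read_signal_table()]; undetected cells are written empty.
#'
#' @param signal long signal tibble.
#' @param annotation probe annotation table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(signal, annotation, path) {
  samples <- sort(unique(signal$sample_id))
  wide <- annotation |>
    dplyr::rename(is_positive = "is_positive_control") |>
    dplyr::select("probe_id", "gene_family", "subcategory", "category",
                  "lineage", "is_positive")
  for (s in samples) {
    sub <- signal[signal$sample_id == s, ]
    wide[[paste0(s, "_signal")]] <- sub$signal[match(wide$probe_id, sub$probe_id)]
    wide[[paste0(s, "_snr")]] <- sub$snr[match(wide$probe_id, sub$probe_id)]
  }
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Write a gene network to GraphML or SIF
#'
#' GraphML keeps typed node attributes (annotation, degree) and edge
#' attributes (sign, weight); SIF writes one line per edge with the
#' interaction label `pp+` / `pp-` according to the correlation sign, for
#' import into Cytoscape.
#'
#' @param network an `fmen_network`.
#' @param path output file.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  g <- network$graph
  if (format == "graphml") {
    g <- igraph::set_vertex_attr(g, "degree", value = igraph::degree(g))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(g, what = "edges")
    lines <- if (nrow(ed)) {
      paste(ed$from, paste0("pp", ed$sign), ed$to, sep = "\t")
    } else {
      character(0)
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a GraphML network back as an igraph graph
#'
#' @param path GraphML file written by [write_network()].
#' @return an \pkg{igraph} graph.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
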