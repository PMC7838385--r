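# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Signal matrix -> long tibble (probe_id, sample_id, value).
signal_long <- function(sig) {
  tidyr::pivot_longer(tibble::as_tibble(sig),
                      cols = -dplyr::all_of("probe_id"),
                      names_to = "sample_id", values_to = "value")
}

# Column names of a signal matrix that hold per-sample values.
sample_cols <- function(sig) setdiff(names(sig), "probe_id")

# Signal matrix (tibble, probe_id + one column per sample) -> numeric matrix
# with probes in rows, samples in columns.
signal_as_matrix <- function(sig) {
  m <- as.matrix(sig[, sample_cols(sig), drop = FALSE])
  rownames(m) <- sig$probe_id
  m
}

new_signal_matrix <- function(df, transformed, normalized, relative = FALSE) {
  structure(
    tibble::as_tibble(df),
    transformed = transformed,
    normalized = normalized,
    relative = relative,
    class = c("fmen_signal", class(tibble::tibble()))
  )
}

is_signal_matrix <- function(x) inherits(x, "fmen_signal")

assert_signal_stage <- function(sig, normalized = NULL, relative = NULL) {
  if (!is_signal_matrix(sig)) {
    abort("expected a signal matrix produced by `normalize_signals()`")
  }
  if (!is.null(normalized) && !isTRUE(attr(sig, "normalized") == normalized)) {
    abort("signal matrix has the wrong provenance: run the preprocessing steps in order")
  }
  if (!is.null(relative) && !isTRUE(attr(sig, "relative") == relative)) {
    abort("signal matrix has the wrong provenance: run the preprocessing steps in order")
  }
  invisible(sig)
}

assert_design <- function(design) {
  needed <- c("sample_id", "lake_id", "elevation_group")
  if (!all(needed %in% names(design))) {
    abort(paste0("study design must have columns: ", paste(needed, collapse = ", ")))
  }
  bad <- setdiff(unique(design$elevation_group), c("low", "high"))
  if (length(bad)) {
    abort(paste0("elevation_group must be 'low' or 'high', found: ", paste(bad, collapse = ", ")))
  }
  invisible(design)
}

# samples belonging to a group, in design order
group_samples <- function(design, group) {
  design$sample_id[design$elevation_group == group]
}

# Welch (or pooled) two-sample t test that tolerates constant inputs.
safe_t_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, df = length(x) + length(y) - 2, p_value = 1))
    }
    return(list(statistic = Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2, p_value = 0))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
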