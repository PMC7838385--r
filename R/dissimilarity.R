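#' Sample-by-sample dissimilarity matrix
#'
#' Computes Euclidean, Bray-Curtis or Morisita-Horn dissimilarities between
#' sample profiles via \pkg{vegan}. Input is a signal matrix (samples in
#' columns) or a plain samples-by-variables matrix/data frame.
#'
#' @param x a signal matrix, or a matrix/data frame with samples in rows.
#' @param metric `"euclidean"`, `"bray"` or `"horn"`.
#' @return a `dist` object with a `metric` attribute.
#' @export
distance_matrix <- function(x, metric = c("euclidean", "bray", "horn")) {
  metric <- match.arg(metric)
  m <- if (is_signal_matrix(x)) t(signal_as_matrix(x)) else as.matrix(x)
  if (nrow(m) < 2) abort("need at least two samples")
  if (metric %in% c("bray", "horn")) {
    if (any(m < 0)) abort("bray/horn require non-negative abundances")
    empty <- rowSums(m) == 0
    if (any(empty)) {
      abort(paste0("all-zero sample(s), distance undefined: ",
                   paste(rownames(m)[empty], collapse = ", ")))
    }
  }
  d <- vegan::vegdist(m, method = metric)
  attr(d, "metric") <- metric
  d
}

# ---- permutation engine ----------------------------------------------------

# all distinct assignments of the multiset of group labels to positions;
# recursion over combn, each distinct labeling produced exactly once
enumerate_labelings <- function(groups) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  sizes <- table(factor(groups, levels = lv))
  n <- length(groups)
  rec <- function(open, lv_left) {
    if (length(lv_left) == 1) {
      lab <- character(n)
      lab[open] <- lv_left
      return(list(lab))
    }
    g <- lv_left[1]
    k <- sizes[[g]]
    picks <- combn(open, k, simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- rec(setdiff(open, p), lv_left[-1])
      out <- c(out, lapply(rest, function(lab) { lab[p] <- g; lab }))
    }
    out
  }
  rec(seq_len(n), lv)
}

new_perm_result <- function(test, statistic, p, n_perm, scheme) {
  structure(
    list(test = test, statistic = statistic, p_value = p,
         n_permutations = n_perm, scheme = scheme),
    class = "fmen_perm"
  )
}

#' @export
print.fmen_perm <- function(x, ...) {
  cat(toupper(x$test), ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4),
      " (", x$scheme, ", ", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

# shared permutation machinery: stat_fn(D-matrix, labels) -> scalar;
# direction "greater" counts stat_perm >= stat_obs as extreme, "less" <=.
# With strata (e.g. lakes), whole strata swap group labels: samples within a
# stratum are pseudo-replicates and never split across groups.
run_perm_test <- function(test, D, groups, stat_fn, direction,
                          n_perm = 999, seed = NULL, exact = FALSE,
                          strata = NULL) {
  dm <- as.matrix(D)
  groups <- as.character(groups)
  if (length(groups) != nrow(dm)) abort("`groups` length must match the distance matrix")
  tab <- table(groups)
  if (length(tab) < 2) abort("need at least two groups")
  if (any(tab < 2)) abort("every group needs at least two samples")
  obs <- stat_fn(dm, groups)
  cmp <- if (direction == "greater") {
    function(s) s >= obs - 1e-12
  } else {
    function(s) s <= obs + 1e-12
  }
  if (!is.null(strata)) {
    strata <- as.character(strata)
    if (length(strata) != length(groups)) abort("`strata` length must match `groups`")
    per_stratum <- tapply(groups, strata, unique)
    if (any(lengths(per_stratum) != 1)) {
      abort("each stratum must carry a single group label")
    }
    stratum_ids <- names(per_stratum)
    stratum_groups <- unlist(per_stratum)
    expand <- function(stratum_labels) {
      stratum_labels[match(strata, stratum_ids)]
    }
    if (exact) {
      labs <- enumerate_labelings(stratum_groups)
      stats <- vapply(labs, function(l) stat_fn(dm, expand(l)), numeric(1))
      return(new_perm_result(test, obs, mean(cmp(stats)), length(labs),
                             "exhaustive stratum enumeration"))
    }
    if (!is.null(seed)) set.seed(as.integer(seed))
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (cmp(stat_fn(dm, expand(sample(stratum_groups))))) hits <- hits + 1L
    }
    return(new_perm_result(test, obs, (1 + hits) / (n_perm + 1), n_perm,
                           "stratum label permutation, add-observed"))
  }
  if (exact) {
    labs <- enumerate_labelings(groups)
    stats <- vapply(labs, function(l) stat_fn(dm, l), numeric(1))
    p <- mean(cmp(stats))
    return(new_perm_result(test, obs, p, length(labs), "exhaustive enumeration"))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    s <- stat_fn(dm, sample(groups))
    if (cmp(s)) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_perm + 1)
  new_perm_result(test, obs, p, n_perm, "free label permutation, add-observed")
}

# ---- statistics ------------------------------------------------------------

permanova_stat <- function(dm, groups) {
  n <- nrow(dm)
  a <- length(unique(groups))
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

anosim_stat <- function(dm, groups) {
  n <- nrow(dm)
  iu <- upper.tri(dm)
  r <- rank(dm[iu]) # mid-ranks for ties
  same <- outer(groups, groups, "==")[iu]
  (mean(r[!same]) - mean(r[same])) / (n * (n - 1) / 4)
}

mrpp_stat <- function(dm, groups) {
  n <- nrow(dm)
  delta <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dm[idx, idx, drop = FALSE]
    delta <- delta + (length(idx) / n) * mean(sub[upper.tri(sub)])
  }
  delta
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based pseudo-F: with `SS_total = (1/N) sum_{i<j} d_ij^2` and
#' `SS_within` the analogous within-group sum scaled by group size,
#' `F = ((SS_total - SS_within)/(a - 1)) / (SS_within/(N - a))`. The p-value
#' permutes whole-sample group labels freely; with `exact = TRUE` every
#' distinct labeling is enumerated (the observed one included), otherwise
#' the add-observed convention `p = (1 + hits)/(n_perm + 1)` is used.
#'
#' @param D a `dist` or square distance matrix.
#' @param groups group label per sample.
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutations.
#' @param exact enumerate all distinct labelings instead of sampling.
#' @param strata optional stratum label per sample (e.g. lake); whole strata
#'   then swap group labels, so pseudo-replicated samples never split. Off by
#'   default, matching a pooled-replicate contrast.
#' @return an `fmen_perm` result (tidy with [tidy()]).
#' @export
permanova <- function(D, groups, n_perm = 999, seed = NULL, exact = FALSE,
                      strata = NULL) {
  run_perm_test("permanova", D, groups, permanova_stat, "greater",
                n_perm = n_perm, seed = seed, exact = exact, strata = strata)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based statistic `R = (mean between-group rank - mean within-group
#' rank) / (n(n-1)/4)` with mid-ranks for tied distances; permutation p-value
#' as in [permanova()].
#'
#' @inheritParams permanova
#' @return an `fmen_perm` result.
#' @export
anosim <- function(D, groups, n_perm = 999, seed = NULL, exact = FALSE,
                      strata = NULL) {
  run_perm_test("anosim", D, groups, anosim_stat, "greater",
                n_perm = n_perm, seed = seed, exact = exact, strata = strata)
}

#' Multiple response permutation procedure (MRPP)
#'
#' Weighted mean within-group distance
#' `delta = sum_g (n_g/N) * mean within-group distance`; small delta means
#' tight groups, so the permutation p-value counts permuted deltas at or
#' below the observed one.
#'
#' @inheritParams permanova
#' @return an `fmen_perm` result.
#' @export
mrpp <- function(D, groups, n_perm = 999, seed = NULL, exact = FALSE,
                      strata = NULL) {
  run_perm_test("mrpp", D, groups, mrpp_stat, "less",
                n_perm = n_perm, seed = seed, exact = exact, strata = strata)
}

#' Run all three dissimilarity tests across metrics
#'
#' Convenience wrapper producing one row per metric x test, the shape used
#' to summarise group contrasts.
#'
#' @param sig a signal matrix.
#' @param design study design; `groups` defaults to its elevation groups.
#' @param metrics distance metrics to use.
#' @param n_perm,seed passed to the tests.
#' @return tibble with `metric`, `test`, `statistic`, `p_value`.
#' @export
compare_groups_dissim <- function(sig, design,
                                  metrics = c("euclidean", "horn", "bray"),
                                  n_perm = 999, seed = NULL) {
  assert_design(design)
  groups <- design$elevation_group[match(sample_cols(sig), design$sample_id)]
  purrr::map_dfr(metrics, function(m) {
    D <- distance_matrix(sig, m)
    purrr::map_dfr(
      list(mrpp = mrpp, anosim = anosim, permanova = permanova),
      function(f) {
        r <- f(D, groups, n_perm = n_perm, seed = seed)
        tibble::tibble(statistic = r$statistic, p_value = r$p_value)
      },
      .id = "test"
    ) |> dplyr::mutate(metric = m, .before = 1)
  })
}
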