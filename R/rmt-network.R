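#' Default functional categories used for network construction
#'
#' Networks focus on the commonly detected genes of the key biogeochemical
#' and ecological processes: carbon, nitrogen and phosphorus cycling, and
#' stress responses.
#' @return character vector of category names.
#' @export
network_categories <- function() {
  c("carbon cycling", "nitrogen cycling", "phosphorus cycling", "stress response")
}

#' Select commonly detected genes for one group's network
#'
#' Keeps probes in the named functional categories that are detected
#' (intensity > 0) in at least `ceiling(min_prevalence_fraction * n)` of the
#' group's `n` samples.
#'
#' @param sig a signal matrix.
#' @param design study design.
#' @param annotation probe annotation table.
#' @param group `"low"` or `"high"`: the group being networked.
#' @param min_prevalence_fraction required detection fraction (default 0.5).
#' @param categories functional categories to include.
#' @return character vector of probe IDs.
#' @export
select_common_genes <- function(sig, design, annotation, group,
                                min_prevalence_fraction = 0.5,
                                categories = network_categories()) {
  assert_design(design)
  samples <- intersect(group_samples(design, group), sample_cols(sig))
  need <- ceiling(min_prevalence_fraction * length(samples))
  m <- signal_as_matrix(sig)[, samples, drop = FALSE]
  in_cat <- annotation$probe_id[annotation$category %in% categories]
  prev <- rowSums(m > 0)
  keep <- rownames(m)[prev >= need & rownames(m) %in% in_cat]
  if (length(keep) == 0) {
    abort("no gene passed category + prevalence selection; lower `min_prevalence_fraction`")
  }
  keep
}

#' Pairwise Pearson correlation matrix over samples
#'
#' @param sig a signal matrix (optionally restricted via `genes`).
#' @param samples sample columns to use (default all).
#' @param genes probe IDs to include (default all rows).
#' @return symmetric correlation matrix (genes x genes), zero-variance genes
#'   dropped with a warning.
#' @export
pearson_matrix <- function(sig, samples = NULL, genes = NULL) {
  m <- signal_as_matrix(sig)
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  if (ncol(m) < 4) abort("need at least 4 samples for correlation")
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    warn(paste0(sum(v == 0), " zero-variance gene(s) dropped before correlation"))
    m <- m[v > 0, , drop = FALSE]
  }
  cor(t(m))
}

# ---- eigenvalue unfolding & NNSD ------------------------------------------

# Unfold eigenvalues so the local mean spacing is 1: fit a cubic smoothing
# spline to the cumulative spectral function (staircase) and evaluate it at
# the eigenvalues. Degenerate eigenvalues (within tol) are collapsed first;
# they arise in thresholded matrices (e.g. identical isolated blocks) and
# would otherwise flood the spacing distribution with zeros.
unfold_eigenvalues <- function(lambda, dedup_tol = 1e-8, df = 20) {
  lambda <- sort(lambda)
  keep <- c(TRUE, diff(lambda) > dedup_tol)
  lambda <- lambda[keep]
  m <- length(lambda)
  if (m < 20) abort("too few distinct eigenvalues for spacing analysis")
  fit <- stats::smooth.spline(lambda, seq_len(m), df = min(df, floor(m / 2)))
  zeta <- stats::predict(fit, lambda)$y
  s <- diff(zeta)
  s[s < 0] <- 0
  s
}

# Wigner-Dyson (GOE) surmise CDF, P(s) = (pi s / 2) exp(-pi s^2 / 4)
pwigner <- function(q) 1 - exp(-pi * q^2 / 4)

nnsd_gof <- function(s, gof) {
  if (gof == "ks") {
    p_pois <- suppressWarnings(ks.test(s, pexp, 1))$p.value
    p_wig <- suppressWarnings(ks.test(s, pwigner))$p.value
  } else {
    brks <- c(seq(0, max(3, ceiling(max(s))), by = 0.5), Inf)
    obs <- table(cut(s, brks))
    chisq_p <- function(cdf) {
      pr <- diff(cdf(brks))
      pr[length(pr)] <- 1 - cdf(brks[length(brks) - 1])
      ex <- length(s) * pr
      keep <- ex > 0
      stat <- sum((as.numeric(obs)[keep] - ex[keep])^2 / ex[keep])
      stats::pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
    }
    p_pois <- chisq_p(function(q) pexp(pmin(q, 1e6), 1))
    p_wig <- chisq_p(function(q) pwigner(pmin(q, 1e6)))
  }
  list(p_poisson = p_pois, p_wigner = p_wig)
}

#' Nearest-neighbour spacing distribution test at one threshold
#'
#' Thresholds the absolute correlation matrix at `st` (entries with
#' `|r| < st` set to 0, diagonal 1), restricts to genes retaining at least
#' one off-diagonal entry, computes eigenvalues, unfolds them to unit mean
#' spacing, and tests the spacing distribution against the Poisson form
#' `P(s) = exp(-s)` and the Wigner-Dyson (GOE) form
#' `P(s) = (pi s/2) exp(-pi s^2/4)`. The verdict is `"poisson"` when the
#' Poisson fit is not rejected and the Wigner fit is, `"goe"` for the
#' converse, `"ambiguous"` otherwise.
#'
#' @param corr symmetric correlation (or similarity) matrix.
#' @param st similarity threshold in \[0, 1\].
#' @param gof `"ks"` (one-sample Kolmogorov-Smirnov, default) or `"chisq"`.
#' @param alpha significance level for the fit decisions.
#' @param min_genes minimum surviving genes for a meaningful spectrum.
#' @param on_small `"error"` (default) or `"ambiguous"`: behaviour when
#'   fewer than `min_genes` genes survive the threshold.
#' @return an `fmen_nnsd` list: `st`, `n_genes`, `eigenvalues`, `spacings`,
#'   `p_poisson`, `p_wigner`, `verdict`.
#' @export
nnsd_test <- function(corr, st, gof = c("ks", "chisq"), alpha = 0.05,
                      min_genes = 50, on_small = c("error", "ambiguous")) {
  gof <- match.arg(gof)
  on_small <- match.arg(on_small)
  a <- abs(corr)
  a[a < st] <- 0
  diag(a) <- 1
  alive <- rowSums(a > 0) > 1
  a <- a[alive, alive, drop = FALSE]
  if (nrow(a) < min_genes) {
    if (on_small == "error") {
      abort(paste0("only ", nrow(a), " genes survive st = ", st,
                   "; too few eigenvalues for an NNSD"))
    }
    return(structure(list(st = st, n_genes = nrow(a), eigenvalues = numeric(0),
                          spacings = numeric(0), p_poisson = NA_real_,
                          p_wigner = NA_real_, verdict = "ambiguous"),
                     class = "fmen_nnsd"))
  }
  lambda <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  s <- tryCatch(unfold_eigenvalues(lambda), error = function(e) NULL)
  if (is.null(s)) {
    if (on_small == "error") {
      abort(paste0("spectrum at st = ", st,
                   " has too few distinct eigenvalues for an NNSD"))
    }
    return(structure(list(st = st, n_genes = nrow(a), eigenvalues = lambda,
                          spacings = numeric(0), p_poisson = NA_real_,
                          p_wigner = NA_real_, verdict = "ambiguous"),
                     class = "fmen_nnsd"))
  }
  gofp <- nnsd_gof(s, gof)
  verdict <- if (gofp$p_poisson > alpha && gofp$p_wigner <= alpha) {
    "poisson"
  } else if (gofp$p_wigner > alpha && gofp$p_poisson <= alpha) {
    "goe"
  } else {
    "ambiguous"
  }
  structure(
    list(st = st, n_genes = nrow(a), eigenvalues = lambda, spacings = s,
         p_poisson = gofp$p_poisson, p_wigner = gofp$p_wigner, verdict = verdict),
    class = "fmen_nnsd"
  )
}

#' @export
print.fmen_nnsd <- function(x, ...) {
  cat("NNSD at st = ", x$st, ": ", x$n_genes, " genes, verdict ", x$verdict,
      " (p_poisson = ", signif(x$p_poisson, 3),
      ", p_wigner = ", signif(x$p_wigner, 3), ")\n", sep = "")
  invisible(x)
}

#' RMT threshold scan
#'
#' Scans an ascending grid of similarity thresholds, testing the eigenvalue
#' spacing distribution at each, and selects the smallest threshold whose
#' verdict is Poisson and whose successors (all higher grid values with
#' enough surviving genes) remain Poisson — the transition point where the
#' thresholded matrix stops behaving like a full random matrix (Wigner
#' spacings) and decomposes into nearly independent modules (Poisson
#' spacings).
#'
#' The Poisson verdict must persist over the next `stability` assessable
#' grid values: at thresholds approaching the strongest correlations the
#' graph fragments and the spectrum degenerates, so demanding Poisson
#' verdicts on the entire remainder of the grid would reject every scan.
#'
#' @param corr symmetric correlation matrix.
#' @param grid ascending thresholds, default `seq(0.30, 0.99, 0.01)`.
#' @param stability number of consecutive assessable successors that must
#'   also be Poisson (default 3).
#' @inheritParams nnsd_test
#' @return an `fmen_scan`: tibble of per-threshold diagnostics (`st`,
#'   `n_genes`, `p_poisson`, `p_wigner`, `verdict`) with the chosen
#'   threshold in `attr(, "selected_st")`.
#' @export
select_threshold <- function(corr, grid = seq(0.30, 0.99, by = 0.01),
                             gof = "ks", alpha = 0.05, min_genes = 50,
                             stability = 3) {
  if (length(grid) == 0 || is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be non-empty and strictly increasing")
  }
  rows <- purrr::map_dfr(grid, function(st) {
    r <- nnsd_test(corr, st, gof = gof, alpha = alpha,
                   min_genes = min_genes, on_small = "ambiguous")
    verdict <- if (r$n_genes < min_genes) {
      "too_few"
    } else if (length(r$spacings) == 0) {
      "degenerate"
    } else {
      r$verdict
    }
    tibble::tibble(st = st, n_genes = r$n_genes,
                   p_poisson = r$p_poisson, p_wigner = r$p_wigner,
                   verdict = verdict)
  })
  assessable <- !rows$verdict %in% c("too_few", "degenerate")
  selected <- NA_real_
  for (i in seq_len(nrow(rows))) {
    if (rows$verdict[i] != "poisson") next
    succ <- which(assessable & seq_len(nrow(rows)) > i)
    succ <- head(succ, stability)
    if (all(rows$verdict[succ] == "poisson")) {
      selected <- rows$st[i]
      break
    }
  }
  if (is.na(selected)) {
    abort(paste0(
      "no threshold on the grid yields a stable Poisson spacing verdict; ",
      "verdict counts: ",
      paste(names(table(rows$verdict)), table(rows$verdict),
            sep = "=", collapse = ", ")
    ))
  }
  structure(rows, selected_st = selected,
            class = c("fmen_scan", class(rows)))
}

#' @export
print.fmen_scan <- function(x, ...) {
  cat("RMT threshold scan over", nrow(x), "thresholds; selected st =",
      attr(x, "selected_st"), "\n")
  NextMethod()
}

#' Build the gene network at a threshold
#'
#' Places an undirected edge between genes `i` and `j` when `|r_ij| >= st`,
#' with the correlation sign and `|r|` as edge attributes; isolated genes
#' are excluded from the network size.
#'
#' @param corr symmetric correlation matrix with gene names.
#' @param st similarity threshold in (0, 1\].
#' @param annotation optional probe annotation attached to nodes.
#' @return an `fmen_network`: list with the \pkg{igraph} graph, `st`, node
#'   count `n`, link count `links`, and positive/negative link percentages.
#' @export
build_network <- function(corr, st, annotation = NULL) {
  if (st <= 0 || st > 1) abort("`st` must lie in (0, 1]")
  a <- abs(corr) >= st
  diag(a) <- FALSE
  idx <- which(a & upper.tri(a), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warn("no edge at this threshold; returning an empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g, st = st, n = 0L, links = 0L,
                          pct_positive = NA_real_, pct_negative = NA_real_),
                     class = "fmen_network"))
  }
  r <- corr[idx]
  edges <- tibble::tibble(
    from = rownames(corr)[idx[, 1]],
    to = rownames(corr)[idx[, 2]],
    weight = abs(r),
    sign = ifelse(r >= 0, "+", "-")
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(annotation)) {
    ann <- annotation[match(igraph::V(g)$name, annotation$probe_id), ]
    for (col in setdiff(names(ann), "probe_id")) {
      g <- igraph::set_vertex_attr(g, col, value = ann[[col]])
    }
  }
  structure(
    list(graph = g, st = st, n = igraph::vcount(g), links = igraph::ecount(g),
         pct_positive = 100 * mean(edges$sign == "+"),
         pct_negative = 100 * mean(edges$sign == "-")),
    class = "fmen_network"
  )
}

#' @export
print.fmen_network <- function(x, ...) {
  cat("fMEN: ", x$n, " nodes, ", x$links, " links at st = ", x$st,
      " (", round(x$pct_positive, 1), "% positive)\n", sep = "")
  invisible(x)
}

#' R-squared of the power-law fit to the degree distribution
#'
#' Ordinary least squares of `log10(frequency)` on `log10(degree)` over the
#' degrees that occur in the network; requires at least three distinct
#' degrees, otherwise returns `NA` with a warning.
#'
#' @param network an `fmen_network`.
#' @return R-squared of the log-log fit, or `NA` if undefined.
#' @export
powerlaw_r2 <- function(network) {
  deg <- igraph::degree(network$graph)
  tab <- table(deg[deg > 0])
  if (length(tab) < 3) {
    warn("fewer than 3 distinct degrees; power-law fit undefined")
    return(NA_real_)
  }
  fit <- lm(log10(as.numeric(tab)) ~ log10(as.numeric(names(tab))))
  summary(fit)$r.squared
}
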