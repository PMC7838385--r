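# broom-style tidiers for the package's result objects

#' @rdname fmen_tidiers
#' @title Tidy and glance methods for fmenr result objects
#' @description Turn permutation tests, networks, threshold scans, module
#'   partitions and eigengene sets into tidy tibbles (`tidy`) or one-row
#'   summaries (`glance`).
#' @param x an fmenr result object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.fmen_perm <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
                 n_permutations = x$n_permutations, scheme = x$scheme)
}

#' @rdname fmen_tidiers
#' @export
glance.fmen_perm <- function(x, ...) tidy(x)

#' @rdname fmen_tidiers
#' @export
tidy.fmen_network <- function(x, ...) {
  if (x$links == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          weight = numeric(), sign = character()))
  }
  tibble::as_tibble(igraph::as_data_frame(x$graph, what = "edges"))
}

#' @rdname fmen_tidiers
#' @export
glance.fmen_network <- function(x, ...) {
  tibble::tibble(st = x$st, n = x$n, links = x$links,
                 pct_positive = x$pct_positive, pct_negative = x$pct_negative)
}

#' @rdname fmen_tidiers
#' @export
tidy.fmen_scan <- function(x, ...) tibble::as_tibble(x)

#' @rdname fmen_tidiers
#' @export
glance.fmen_scan <- function(x, ...) {
  tibble::tibble(selected_st = attr(x, "selected_st"),
                 n_thresholds = nrow(x),
                 n_poisson = sum(x$verdict == "poisson"))
}

#' @rdname fmen_tidiers
#' @export
tidy.fmen_partition <- function(x, ...) x$nodes

#' @rdname fmen_tidiers
#' @export
glance.fmen_partition <- function(x, ...) {
  tibble::tibble(n_modules = x$n_modules, modularity = x$q)
}

#' @rdname fmen_tidiers
#' @export
tidy.fmen_nnsd <- function(x, ...) {
  tibble::tibble(spacing = x$spacings)
}

#' @rdname fmen_tidiers
#' @export
glance.fmen_nnsd <- function(x, ...) {
  tibble::tibble(st = x$st, n_genes = x$n_genes, p_poisson = x$p_poisson,
                 p_wigner = x$p_wigner, verdict = x$verdict)
}

#' @rdname fmen_tidiers
#' @export
tidy.fmen_eigengenes <- function(x, ...) tibble::as_tibble(x)

#' @rdname fmen_tidiers
#' @export
glance.fmen_eigengenes <- function(x, ...) attr(x, "summary")
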