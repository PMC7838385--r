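# unweighted, unsigned, simple view of a network's graph
as_plain_graph <- function(g) {
  g <- igraph::as_undirected(igraph::simplify(g))
  for (a in intersect(igraph::edge_attr_names(g), c("weight"))) {
    g <- igraph::delete_edge_attr(g, a)
  }
  g
}

#' Module detection by fast greedy modularity optimization
#'
#' Agglomerative greedy maximization of Newman-Girvan modularity
#' `Q = sum_m (e_mm - a_m^2)` on the unweighted, unsigned graph
#' (\code{igraph::cluster_fast_greedy}; the merge order is deterministic).
#' An edgeless network yields every node as its own module with `Q = 0`.
#'
#' @param network an `fmen_network`.
#' @return an `fmen_partition`: list with `membership` (named integer
#'   vector), `n_modules`, modularity `q`, and a `nodes` tibble.
#' @export
fast_greedy_modules <- function(network) {
  g <- as_plain_graph(network$graph)
  if (igraph::ecount(g) == 0) {
    mem <- seq_len(igraph::vcount(g))
    names(mem) <- igraph::V(g)$name
    return(structure(list(membership = mem, n_modules = length(mem), q = 0,
                          nodes = tibble::tibble(node = names(mem), module = mem)),
                     class = "fmen_partition"))
  }
  cm <- igraph::cluster_fast_greedy(g, weights = NA)
  # cut the merge dendrogram at its own max-modularity step: membership()
  # can disagree with the modularity path by one merge on degenerate graphs
  mem <- igraph::cut_at(cm, steps = which.max(cm$modularity) - 1)
  names(mem) <- igraph::V(g)$name
  q <- igraph::modularity(g, mem)
  structure(
    list(membership = mem, n_modules = length(unique(mem)), q = q,
         nodes = tibble::tibble(node = names(mem), module = as.integer(mem))),
    class = "fmen_partition"
  )
}

#' @export
print.fmen_partition <- function(x, ...) {
  cat("Module partition:", x$n_modules, "modules, Q =", signif(x$q, 4), "\n")
  invisible(x)
}

# harmonic mean of geodesic distances; disconnected pairs contribute
# reciprocal 0, so sparse/disconnected graphs still get a finite value
harmonic_geodesic <- function(g) {
  d <- igraph::distances(g, weights = NA)
  r <- 1 / d[upper.tri(d)]
  r[!is.finite(r)] <- 0
  if (mean(r) == 0) return(Inf)
  1 / mean(r)
}

avg_clustering <- function(g) {
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0 # degree < 2 contributes 0
  mean(cc)
}

#' Topological indices of a gene network
#'
#' Computes, on the unweighted unsigned graph: average connectivity
#' `avgK = 2L/n`, harmonic geodesic distance HD (harmonic mean of shortest
#' paths, disconnected pairs contributing zero reciprocal), average
#' clustering coefficient avgCC (nodes with degree < 2 contribute 0),
#' transitivity, modularity and module count from [fast_greedy_modules()]
#' (unless a partition is supplied), and the power-law R-squared.
#'
#' @param network an `fmen_network` with at least 2 nodes.
#' @param partition optional `fmen_partition`; computed if missing.
#' @return one-row tibble: `n`, `links`, `avg_k`, `hd`, `avg_cc`,
#'   `transitivity`, `modularity`, `n_modules`, `powerlaw_r2`.
#' @export
topology_summary <- function(network, partition = NULL) {
  if (network$n < 2) abort("network must have at least 2 nodes")
  g <- as_plain_graph(network$graph)
  if (is.null(partition)) partition <- fast_greedy_modules(network)
  trans <- igraph::transitivity(g, type = "global")
  tibble::tibble(
    n = network$n,
    links = network$links,
    avg_k = 2 * network$links / network$n,
    hd = harmonic_geodesic(g),
    avg_cc = avg_clustering(g),
    transitivity = ifelse(is.nan(trans), 0, trans),
    modularity = partition$q,
    n_modules = partition$n_modules,
    powerlaw_r2 = suppressWarnings(powerlaw_r2(network))
  )
}

#' Random-network ensemble and Z-tests against the empirical network
#'
#' Generates `n_networks` random networks matching the empirical one —
#' `"degree_preserving"` (default): repeated double-edge swaps keeping every
#' node's degree, 10 x L rewiring trials per network, no multi-edges or
#' self-loops; `"size_links"`: uniform random graphs with the same node and
#' link counts — and compares harmonic geodesic distance, average clustering
#' and modularity with a two-sided Z test.
#'
#' @param network an `fmen_network` with at least 2 links.
#' @param n_networks ensemble size (default 100).
#' @param method `"degree_preserving"` or `"size_links"`.
#' @param seed integer seed.
#' @param keep_graphs retain the sampled graphs in a `graphs` attribute
#'   (for auditing the null-model contract).
#' @return an `fmen_ensemble` tibble: `index`, `empirical`, `null_mean`,
#'   `null_sd`, `z`, `p_value`; the method and ensemble size as attributes.
#' @export
random_ensemble <- function(network, n_networks = 100,
                            method = c("degree_preserving", "size_links"),
                            seed = NULL, keep_graphs = FALSE) {
  method <- match.arg(method)
  if (network$links < 2) abort("need at least 2 links")
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- as_plain_graph(network$graph)

  index_fns <- list(
    hd = harmonic_geodesic,
    avg_cc = avg_clustering,
    modularity = function(gg) {
      if (igraph::ecount(gg) == 0) return(0)
      igraph::modularity(gg, igraph::membership(
        igraph::cluster_fast_greedy(gg, weights = NA)))
    }
  )
  empirical <- vapply(index_fns, function(f) f(g), numeric(1))

  draws <- matrix(NA_real_, nrow = n_networks, ncol = length(index_fns),
                  dimnames = list(NULL, names(index_fns)))
  graphs <- if (keep_graphs) vector("list", n_networks) else NULL
  for (b in seq_len(n_networks)) {
    rg <- if (method == "degree_preserving") {
      igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                               niter = 10 * network$links))
    } else {
      igraph::sample_gnm(network$n, network$links, directed = FALSE)
    }
    if (keep_graphs) graphs[[b]] <- rg
    draws[b, ] <- vapply(index_fns, function(f) f(rg), numeric(1))
  }

  out <- tibble::tibble(
    index = names(index_fns),
    empirical = unname(empirical),
    null_mean = colMeans(draws),
    null_sd = apply(draws, 2, sd)
  )
  zt <- purrr::map2(out$empirical, purrr::map2(out$null_mean, out$null_sd, c),
                    function(e, ms) z_test(e, ms[1], ms[2]))
  out$z <- purrr::map_dbl(zt, "z")
  out$p_value <- purrr::map_dbl(zt, "p_value")
  structure(out, method = method, n_networks = n_networks, graphs = graphs,
            class = c("fmen_ensemble", class(out)))
}

#' Z test of an empirical index against a null ensemble
#'
#' `Z = (empirical - mean)/sd` with a two-sided normal p-value. With zero
#' ensemble spread, a differing empirical value yields an infinite Z and
#' `p = 0`; an equal one yields `Z = 0`, `p = 1`.
#'
#' @param empirical observed index value.
#' @param ensemble_mean,ensemble_sd null-ensemble moments (`sd >= 0`).
#' @return list with `z` and `p_value`.
#' @export
z_test <- function(empirical, ensemble_mean, ensemble_sd) {
  if (ensemble_sd < 0) abort("`ensemble_sd` must be >= 0")
  if (ensemble_sd == 0) {
    if (empirical == ensemble_mean) return(list(z = 0, p_value = 1))
    return(list(z = Inf * sign(empirical - ensemble_mean), p_value = 0))
  }
  z <- (empirical - ensemble_mean) / ensemble_sd
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}
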