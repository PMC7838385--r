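#' Node-role classification by within- and among-module connectivity
#'
#' For each node, `Zi` is the z-score of its within-module degree relative
#' to the other members of its module, and `Pi = 1 - sum_s (k_is/k_i)^2` is
#' the participation coefficient over modules `s`. Roles follow the standard
#' thresholds: network hubs (`Zi > 2.5` and `Pi > 0.62`), module hubs
#' (`Zi > 2.5`), connectors (`Pi > 0.62`), peripherals otherwise; boundary
#' values fall to the peripheral side of each strict inequality. Modules of
#' size 1 or with zero spread in within-module degree give `Zi = 0`,
#' flagged.
#'
#' @param network an `fmen_network`.
#' @param partition an `fmen_partition` covering the network.
#' @return tibble: `node`, `module`, `k`, `k_within`, `zi`, `pi`, `role`,
#'   `zi_degenerate`.
#' @export
node_roles <- function(network, partition) {
  g <- igraph::as_undirected(igraph::simplify(network$graph))
  nodes <- igraph::V(g)$name
  mem <- partition$membership[nodes]
  if (anyNA(mem)) abort("partition does not cover every network node")
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(adj)
  # per-node link counts into each module
  mods <- sort(unique(mem))
  k_is <- sapply(mods, function(m) rowSums(adj[, mem == m, drop = FALSE]))
  if (is.null(dim(k_is))) k_is <- matrix(k_is, ncol = length(mods))
  k_within <- k_is[cbind(seq_along(nodes), match(mem, mods))]

  mu <- tapply(k_within, mem, mean)[as.character(mem)]
  sg <- tapply(k_within, mem, sd)[as.character(mem)]
  size <- tapply(rep(1, length(mem)), mem, sum)[as.character(mem)]
  degenerate <- size == 1 | is.na(sg) | sg == 0
  zi <- ifelse(degenerate, 0, (k_within - mu) / sg)
  pi_ <- 1 - rowSums((k_is / k)^2)

  role <- dplyr::case_when(
    zi > 2.5 & pi_ > 0.62 ~ "network_hub",
    zi > 2.5 ~ "module_hub",
    pi_ > 0.62 ~ "connector",
    TRUE ~ "peripheral"
  )
  tibble::tibble(node = nodes, module = as.integer(mem), k = as.integer(k),
                 k_within = as.integer(k_within), zi = as.numeric(zi),
                 pi = as.numeric(pi_), role = role,
                 zi_degenerate = as.logical(degenerate))
}

#' Genes ranked by connectivity
#'
#' Sorts nodes by degree, descending, with ties broken lexicographically by
#' gene ID, and returns the top `k`.
#'
#' @param network an `fmen_network`.
#' @param k how many genes to return (default 5).
#' @return tibble `node`, `degree`, `rank`.
#' @export
top_connectivity_genes <- function(network, k = 5) {
  if (network$n == 0) abort("network is empty")
  deg <- igraph::degree(network$graph)
  ord <- order(-deg, names(deg))
  tibble::tibble(node = names(deg)[ord], degree = as.integer(deg[ord]),
                 rank = seq_along(ord))[seq_len(min(k, length(ord))), ]
}

#' Module eigengenes (first principal components)
#'
#' For each of the `top_k_modules` largest modules, member gene profiles are
#' standardized (z-score per gene across samples) and the module eigengene
#' `E` is the first principal component score vector over samples, oriented
#' so that the mean correlation between `E` and the member profiles is
#' positive. A single-gene module's eigengene is that gene's standardized
#' profile with variance explained 1. Constant genes are dropped from a
#' module before the PCA.
#'
#' @param sig a signal matrix.
#' @param partition an `fmen_partition`.
#' @param top_k_modules how many modules, largest first (default 5).
#' @return an `fmen_eigengenes` tibble (`module`, `sample_id`, `value`) with
#'   a `summary` attribute tibble (`module`, `n_genes`, `var_explained`).
#' @export
module_eigengene <- function(sig, partition, top_k_modules = 5) {
  m <- signal_as_matrix(sig)
  sizes <- sort(table(partition$membership), decreasing = TRUE)
  mods <- as.integer(names(sizes))[seq_len(min(top_k_modules, length(sizes)))]
  rows <- list(); summ <- list()
  for (mod in mods) {
    genes <- names(partition$membership)[partition$membership == mod]
    x <- m[rownames(m) %in% genes, , drop = FALSE]
    sds <- apply(x, 1, sd)
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) == 0) next
    xs <- t(scale(t(x))) # genes standardized across samples
    if (nrow(xs) == 1) {
      e <- as.numeric(xs)
      ve <- 1
    } else {
      pc <- prcomp(t(xs), center = FALSE, scale. = FALSE)
      e <- pc$x[, 1]
      ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
    }
    if (mean(apply(xs, 1, function(gp) cor(gp, e))) < 0) e <- -e
    rows[[length(rows) + 1]] <- tibble::tibble(module = mod,
                                               sample_id = colnames(m),
                                               value = unname(e))
    summ[[length(summ) + 1]] <- tibble::tibble(module = mod,
                                               n_genes = nrow(xs),
                                               var_explained = ve)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, summary = dplyr::bind_rows(summ),
            class = c("fmen_eigengenes", class(out)))
}

#' Spearman correlation of module eigengenes with environmental variables
#'
#' Mid-rank Spearman rho with a two-sided p-value per (module, variable)
#' pair. Constant environmental variables are flagged with `NA` rho.
#'
#' @param eigengenes result of [module_eigengene()].
#' @param env environment table: `sample_id` plus numeric variables.
#' @return tibble `module`, `variable`, `rho`, `p_value`.
#' @export
env_correlation <- function(eigengenes, env) {
  vars <- setdiff(names(env), "sample_id")
  wide <- tidyr::pivot_wider(tibble::as_tibble(eigengenes),
                             names_from = "module", values_from = "value",
                             names_prefix = "mod")
  joined <- dplyr::inner_join(wide, env, by = "sample_id")
  mods <- unique(eigengenes$module)
  purrr::map_dfr(mods, function(mod) {
    e <- joined[[paste0("mod", mod)]]
    purrr::map_dfr(vars, function(v) {
      x <- joined[[v]]
      if (sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
        return(tibble::tibble(module = mod, variable = v,
                              rho = NA_real_, p_value = NA_real_))
      }
      ct <- suppressWarnings(cor.test(e, x, method = "spearman", exact = FALSE))
      tibble::tibble(module = mod, variable = v,
                     rho = unname(ct$estimate), p_value = ct$p.value)
    })
  })
}
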