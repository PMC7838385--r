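#' Run the full analysis pipeline
#'
#' Executes preprocessing (SNR filter, prevalence filter, normalization,
#' relative intensities), group statistics (richness, overlap, per-category
#' tests, group differences), dissimilarity permutation tests, and — per
#' elevation group — RMT network inference, topology with a random-network
#' ensemble, node roles, module eigengenes and their environmental
#' correlations. Every stage's output, the parameters and the seed are
#' collected into a run report; rerunning with the same inputs and seed
#' reproduces it.
#'
#' @param data either a `synth_dataset` from [generate_dataset()] or a list
#'   with `signal`, `annotation`, `design` and optionally `env`.
#' @param snr_min SNR cutoff (strict).
#' @param min_detected_per_lake within-lake prevalence rule; NULL for the
#'   30% rule.
#' @param metrics dissimilarity metrics for the group tests.
#' @param n_perm permutations for the dissimilarity tests.
#' @param network_groups which elevation groups to network (default both).
#' @param categories functional categories entering the networks.
#' @param min_prevalence_fraction network gene prevalence rule.
#' @param st_grid threshold grid for the RMT scan.
#' @param n_random random networks per ensemble.
#' @param null_method `"degree_preserving"` or `"size_links"`.
#' @param top_k_modules modules to summarise with eigengenes.
#' @param run_network set FALSE to skip the network stages.
#' @param seed integer seed controlling every stochastic step.
#' @param out_dir if non-NULL, writes TSV/JSON/GraphML outputs there.
#' @return an `fmen_report` list.
#' @export
run_pipeline <- function(data,
                         snr_min = 2,
                         min_detected_per_lake = 2,
                         metrics = c("euclidean", "horn", "bray"),
                         n_perm = 999,
                         network_groups = c("low", "high"),
                         categories = network_categories(),
                         min_prevalence_fraction = 0.5,
                         st_grid = seq(0.30, 0.99, by = 0.01),
                         n_random = 100,
                         null_method = "degree_preserving",
                         top_k_modules = 5,
                         run_network = TRUE,
                         seed = 1L,
                         out_dir = NULL) {
  stopifnot(all(c("signal", "annotation", "design") %in% names(data)))
  design <- assert_design(data$design)
  params <- list(snr_min = snr_min, min_detected_per_lake = min_detected_per_lake,
                 metrics = metrics, n_perm = n_perm,
                 network_groups = network_groups, categories = categories,
                 min_prevalence_fraction = min_prevalence_fraction,
                 st_grid = range(st_grid), n_random = n_random,
                 null_method = null_method, top_k_modules = top_k_modules,
                 seed = as.integer(seed))

  ## preprocessing, with per-stage probe counts for the report
  raw <- data$signal
  counts <- list(input_probes = dplyr::n_distinct(raw$probe_id))
  snr_ok <- filter_by_snr(raw, snr_min = snr_min)
  counts$after_snr <- dplyr::n_distinct(snr_ok$probe_id)
  prev_ok <- filter_by_prevalence(snr_ok, design,
                                  min_detected_per_lake = min_detected_per_lake)
  counts$after_prevalence <- dplyr::n_distinct(prev_ok$probe_id)
  sig <- normalize_signals(prev_ok)
  counts$in_matrix <- nrow(sig)
  rel <- relative_intensity(sig)

  stats_tbls <- list(
    richness = richness(sig, design, data$annotation),
    overlap = overlap(sig, design, scope = "all"),
    overlap_by_category = overlap(sig, design, scope = "category",
                                  annotation = data$annotation),
    category_tests = category_ttest(sig, design, data$annotation,
                                    level = "category"),
    group_difference = group_difference(sig, design, data$annotation,
                                        level = "gene_family")
  )

  dissim <- compare_groups_dissim(sig, design, metrics = metrics,
                                  n_perm = n_perm, seed = seed)

  networks <- list()
  if (run_network) {
    for (grp in network_groups) {
      genes <- select_common_genes(sig, design, data$annotation, grp,
                                   min_prevalence_fraction = min_prevalence_fraction,
                                   categories = categories)
      corr <- pearson_matrix(sig, samples = group_samples(design, grp),
                             genes = genes)
      scan <- select_threshold(corr, grid = st_grid)
      st <- attr(scan, "selected_st")
      net <- build_network(corr, st, annotation = data$annotation)
      part <- fast_greedy_modules(net)
      topo <- topology_summary(net, part)
      nulls <- random_ensemble(net, n_networks = n_random,
                               method = null_method, seed = seed)
      roles <- node_roles(net, part)
      eg <- module_eigengene(sig, part, top_k_modules = top_k_modules)
      envc <- if (!is.null(data$env)) env_correlation(eg, data$env) else NULL
      networks[[grp]] <- list(
        n_candidate_genes = length(genes), selected_st = st,
        scan = scan, network = net, partition = part, topology = topo,
        nulls = nulls, roles = roles, eigengenes = eg, env_correlation = envc,
        top_genes = top_connectivity_genes(net, 5)
      )
    }
  }

  report <- structure(
    list(params = params, counts = counts, signal_matrix = sig,
         relative_matrix = rel, stats = stats_tbls, dissimilarity = dissim,
         networks = networks, version = as.character(utils::packageVersion("fmenr"))),
    class = "fmen_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.fmen_report <- function(x, ...) {
  cat("fmenr run report\n")
  cat("  probes: ", x$counts$input_probes, " -> SNR ", x$counts$after_snr,
      " -> prevalence ", x$counts$after_prevalence, "\n", sep = "")
  for (g in names(x$networks)) {
    nw <- x$networks[[g]]
    cat("  ", g, " network: st = ", nw$selected_st, ", n = ", nw$network$n,
        ", links = ", nw$network$links, "\n", sep = "")
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits the summary tables as TSV, networks as GraphML + SIF, and a JSON
#' report with parameters, seed, per-stage probe counts and the headline
#' network numbers — enough to audit and re-execute the run.
#'
#' @param report an `fmen_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$dissimilarity, file.path(out_dir, "dissimilarity_tests.tsv"))
  for (nm in names(report$stats)) {
    readr::write_tsv(report$stats[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  net_summaries <- list()
  for (g in names(report$networks)) {
    nw <- report$networks[[g]]
    write_network(nw$network, file.path(out_dir, paste0("network_", g, ".graphml")),
                  "graphml")
    write_network(nw$network, file.path(out_dir, paste0("network_", g, ".sif")), "sif")
    readr::write_tsv(nw$roles, file.path(out_dir, paste0("node_roles_", g, ".tsv")))
    readr::write_tsv(tibble::as_tibble(nw$scan),
                     file.path(out_dir, paste0("threshold_scan_", g, ".tsv")))
    net_summaries[[g]] <- c(list(selected_st = nw$selected_st),
                            as.list(nw$topology))
  }
  json <- list(params = report$params, counts = report$counts,
               networks = net_summaries, version = report$version)
  jsonlite::write_json(json, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
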