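# fixtures built in code; no data files

# symmetric matrix with iid Gaussian entries (GOE), scaled into [-1, 1]
goe_matrix <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  s <- (a + t(a)) / sqrt(2)
  s <- s / max(abs(s))
  rownames(s) <- colnames(s) <- paste0("g", seq_len(n))
  s
}

# block-diagonal symmetric matrix: independent GOE blocks
block_diag_matrix <- function(n_blocks, block_size, seed) {
  set.seed(seed)
  n <- n_blocks * block_size
  m <- matrix(0, n, n)
  for (b in seq_len(n_blocks)) {
    i <- ((b - 1) * block_size + 1):(b * block_size)
    a <- matrix(rnorm(block_size^2), block_size)
    m[i, i] <- (a + t(a)) / sqrt(2)
  }
  m <- m / max(abs(m))
  rownames(m) <- colnames(m) <- paste0("g", seq_len(n))
  m
}

# symmetric "correlation" matrix from an edge list of (i, j, r) triples
corr_from_edges <- function(nodes, edges) {
  m <- diag(length(nodes))
  rownames(m) <- colnames(m) <- nodes
  for (k in seq_len(nrow(edges))) {
    i <- edges[[1]][k]; j <- edges[[2]][k]; r <- edges[[3]][k]
    m[i, j] <- m[j, i] <- r
  }
  m
}

# fmen_network directly from an igraph graph (all edges positive, weight 0.9)
network_from_graph <- function(g, st = 0.5) {
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  }
  igraph::E(g)$weight <- 0.9
  igraph::E(g)$sign <- "+"
  structure(list(graph = g, st = st, n = igraph::vcount(g),
                 links = igraph::ecount(g),
                 pct_positive = 100, pct_negative = 0),
            class = "fmen_network")
}

# two disjoint triangles, as a network
triangle_pair_network <- function() {
  edges <- data.frame(i = c("a", "b", "a", "d", "e", "d"),
                      j = c("b", "c", "c", "e", "f", "f"),
                      r = 0.95)
  build_network(corr_from_edges(letters[1:6], edges), 0.9)
}

# wide signal matrix from a plain genes x samples matrix
signal_from_matrix <- function(m, normalized = TRUE) {
  fmenr:::new_signal_matrix(
    dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)),
                     tibble::as_tibble(m)),
    transformed = TRUE, normalized = normalized
  )
}

# minimal long raw table from vectors
raw_row <- function(probe, sample, signal, snr, pos = FALSE) {
  tibble::tibble(probe_id = probe, sample_id = sample, signal = signal,
                 snr = snr, is_positive_control = pos)
}

# two-lake-per-group design, k samples per lake
toy_design <- function(samples_per_lake = 3) {
  lakes <- paste0("lake", 1:4)
  groups <- c("low", "low", "high", "high")
  tibble::tibble(
    sample_id = paste0("L", rep(1:4, each = samples_per_lake), "S",
                       rep(seq_len(samples_per_lake), 4)),
    lake_id = rep(lakes, each = samples_per_lake),
    elevation_group = rep(groups, each = samples_per_lake),
    elevation_m = rep(c(525, 530, 4608, 4652), each = samples_per_lake)
  )
}

# a planted-block dataset with no detection dropout: correlation structure
# is exactly the planted one (used by network-recovery tests)
clean_planted_dataset <- function(seed = 1, ...) {
  generate_dataset(synth_config(detection_prob = 1, snr_fail_prob = 0,
                                seed = seed, ...))
}

preprocess_dataset <- function(d) {
  normalize_signals(filter_by_prevalence(filter_by_snr(d$signal), d$design))
}
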