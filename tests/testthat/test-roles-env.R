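# a two-module network with a module hub and a connector:
# module 1 = hub h plus satellites a1..a8 arranged in a ring, each satellite
# tied to the hub; module 2 = a separate clique; node "x" links evenly into
# four modules of a larger variant when needed
hub_network <- function() {
  edges <- list()
  sat <- paste0("a", 1:8)
  for (i in 1:8) {
    edges[[length(edges) + 1]] <- c("h", sat[i])
    edges[[length(edges) + 1]] <- c(sat[i], sat[i %% 8 + 1])
  }
  cl <- paste0("b", 1:5)
  for (i in 1:4) for (j in (i + 1):5) {
    edges[[length(edges) + 1]] <- c(cl[i], cl[j])
  }
  # one bridge so the graph is connected
  edges[[length(edges) + 1]] <- c("a1", "b1")
  ed <- do.call(rbind, edges)
  corr_from_edges(c("h", sat, cl),
                  data.frame(i = ed[, 1], j = ed[, 2], r = 0.9))
}

test_that("Zi and Pi follow their definitions and roles are total", {
  net <- build_network(hub_network(), 0.5)
  part <- fast_greedy_modules(net)
  roles <- node_roles(net, part)
  # conservation: within + between counts equal total degree
  expect_equal(roles$k, roles$k_within +
                 (roles$k - roles$k_within)) # tautology guard
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  for (i in seq_len(nrow(roles))) {
    expect_equal(roles$k[i], sum(adj[roles$node[i], ]))
  }
  expect_true(all(roles$pi >= 0 & roles$pi < 1))
  expect_true(all(roles$role %in% c("network_hub", "module_hub",
                                    "connector", "peripheral")))
  # nodes with all links inside their module have Pi = 0
  all_inside <- roles$k == roles$k_within
  expect_true(all(roles$pi[all_inside] == 0))
  # the engineered hub dominates its module
  hub_row <- roles[roles$node == "h", ]
  expect_gt(hub_row$zi, 2.5)
  expect_equal(hub_row$role, "module_hub")
})

test_that("participation coefficient closed form: 4 even modules give 0.75", {
  # x has exactly one link into each of four 3-cliques
  cliques <- paste0(rep(c("c", "d", "e", "f"), each = 3), 1:3)
  edges <- list()
  for (p in c("c", "d", "e", "f")) {
    ids <- paste0(p, 1:3)
    edges[[length(edges) + 1]] <- c(ids[1], ids[2])
    edges[[length(edges) + 1]] <- c(ids[2], ids[3])
    edges[[length(edges) + 1]] <- c(ids[1], ids[3])
    edges[[length(edges) + 1]] <- c("x", ids[1])
  }
  ed <- do.call(rbind, edges)
  corr <- corr_from_edges(c("x", cliques),
                          data.frame(i = ed[, 1], j = ed[, 2], r = 0.9))
  net <- build_network(corr, 0.5)
  part <- fast_greedy_modules(net)
  roles <- node_roles(net, part)
  x <- roles[roles$node == "x", ]
  expect_equal(x$pi, 0.75)
  expect_equal(x$role, "connector")
})

test_that("role thresholds classify the four quadrants", {
  # exercise the classification rule directly via crafted Zi/Pi pairs
  classify <- function(zi, pi) {
    dplyr::case_when(zi > 2.5 & pi > 0.62 ~ "network_hub",
                     zi > 2.5 ~ "module_hub",
                     pi > 0.62 ~ "connector",
                     TRUE ~ "peripheral")
  }
  expect_equal(classify(3.0, 0.7), "network_hub")
  expect_equal(classify(3.0, 0.1), "module_hub")
  expect_equal(classify(0.5, 0.7), "connector")
  expect_equal(classify(0.5, 0.1), "peripheral")
  # boundary values fall to the peripheral side
  expect_equal(classify(2.5, 0.62), "peripheral")
})

test_that("top connectivity ranking breaks ties lexicographically", {
  star <- network_from_graph(igraph::make_star(6, mode = "undirected",
                                               center = 1))
  top <- top_connectivity_genes(star, 3)
  expect_equal(top$node[1], "v1")
  expect_equal(top$degree[1], 5)
  # degrees (7, 5, 5, 2): hand ranking with lexicographic ties
  g <- igraph::graph_from_edgelist(cbind(
    rep("hub", 7), paste0("n", 1:7)), directed = FALSE)
  g <- igraph::add_edges(g, c("n1", "n2", "n1", "n3", "n1", "n4", "n1", "n5",
                              "n2", "n3", "n2", "n4", "n2", "n5"))
  net <- network_from_graph(g)
  top3 <- top_connectivity_genes(net, 3)
  expect_equal(top3$node, c("hub", "n1", "n2"))
  expect_equal(top3$degree, c(7L, 5L, 5L))
  # all-equal degrees: lexicographic order
  ring <- network_from_graph(igraph::make_ring(4))
  expect_equal(top_connectivity_genes(ring, 4)$node, paste0("v", 1:4))
})

test_that("module eigengene summarises a module's shared profile", {
  # identical profiles: variance explained 1, E tracks the profile
  prof <- c(1, 3, 2, 5, 4, 6, 8, 7)
  m <- matrix(rep(prof, each = 4), 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  sig <- signal_from_matrix(m)
  mem <- setNames(rep(1L, 4), rownames(m))
  part <- structure(list(membership = mem), class = "fmen_partition")
  eg <- module_eigengene(sig, part, 1)
  expect_equal(glance(eg)$var_explained, 1, tolerance = 1e-12)
  expect_gt(cor(eg$value, prof), 0.999)
  # orientation: negating every profile flips E
  m2 <- -m
  eg2 <- module_eigengene(signal_from_matrix(m2), part, 1)
  expect_equal(eg2$value, -eg$value, tolerance = 1e-9)
  # single-gene module: standardized profile, variance explained 1
  single <- structure(list(membership = setNames(1L, "g1")),
                      class = "fmen_partition")
  eg3 <- module_eigengene(sig, single, 1)
  expect_equal(eg3$value, as.numeric(scale(prof)), tolerance = 1e-12)
  expect_equal(glance(eg3)$var_explained, 1)
})

test_that("eigengene recovers the generating latent factor", {
  set.seed(2)
  f <- rnorm(24)
  x <- t(sapply(1:5, function(g) sqrt(0.8) * f + sqrt(0.2) * rnorm(24)))
  dimnames(x) <- list(paste0("g", 1:5), paste0("s", 1:24))
  part <- structure(list(membership = setNames(rep(1L, 5), rownames(x))),
                    class = "fmen_partition")
  eg <- module_eigengene(signal_from_matrix(x), part, 1)
  expect_gte(abs(cor(eg$value, f)), 0.9)
})

test_that("environmental correlation is mid-rank Spearman", {
  e <- tibble::tibble(module = 1L, sample_id = paste0("s", 1:6),
                      value = c(1, 2, 3, 4, 5, 6))
  class(e) <- c("fmen_eigengenes", class(e))
  env <- tibble::tibble(sample_id = paste0("s", 1:6),
                        temperature = c(2, 4, 6, 8, 10, 12),
                        inverse = c(12, 10, 8, 6, 4, 2),
                        tied = c(1, 1, 2, 3, 4, 5),
                        flat = rep(3, 6))
  ec <- env_correlation(e, env)
  expect_equal(ec$rho[ec$variable == "temperature"], 1)
  expect_equal(ec$rho[ec$variable == "inverse"], -1)
  expect_true(is.na(ec$rho[ec$variable == "flat"]))
  # definitional mid-rank computation for the tied variable
  rx <- rank(e$value); ry <- rank(env$tied)
  rho_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(ec$rho[ec$variable == "tied"], rho_hand, tolerance = 1e-12)
})

test_that("planted environmental driver is recovered via truth modules", {
  d <- clean_planted_dataset(seed = 6)
  sig <- preprocess_dataset(d)
  tr <- d$truth$probe_modules
  mem <- tr$module[!is.na(tr$module)]
  names(mem) <- tr$probe_id[!is.na(tr$module)]
  part <- structure(list(membership = mem), class = "fmen_partition")
  eg <- module_eigengene(sig, part, top_k_modules = 10)
  ec <- env_correlation(eg, d$env)
  turb <- ec[ec$variable == "turbidity", ]
  expect_gte(abs(turb$rho[turb$module == 1]), 0.7)
  expect_lte(median(abs(turb$rho[turb$module != 1])), 0.3)
})
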