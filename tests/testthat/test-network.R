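screen_from_r <- function(r, p = 0) {
  list(r = r, p_adj = matrix(p, nrow(r), ncol(r), dimnames = dimnames(r)),
       n_samples = 30, method = "spearman")
}

full_r <- function(n, v = 0.9) {
  r <- matrix(v, n, n, dimnames = list(paste0("O", 1:n), paste0("O", 1:n)))
  diag(r) <- 1
  r
}

test_that("rank correlations match hand-computed Spearman values", {
  # equal read depths so relative abundances preserve the planted ranks
  x <- matrix(c(3L, 1L, 2L, 3L, 1L, 2L, 1L, 3L, 2L, 3L, 5L, 4L), ncol = 4,
              dimnames = list(paste0("s", 1:3), c("a", "b", "c", "pad")))
  stopifnot(all(rowSums(x) == 10))
  tab <- otu_table(x)
  scr <- correlation_screen(tab, min_prevalence = 0)
  expect_equal(unname(scr$r["a", "b"]), 1)
  # ranks (3,1,2) vs (1,3,2): rho = 1 - 6*8/(3*(9-1)) = -1
  expect_equal(unname(scr$r["a", "c"]), -1)
  expect_equal(unname(scr$r["a", "c"]),
               cor(c(3, 1, 2), c(1, 3, 2), method = "spearman"))
  # perfectly reversed ranks
  y <- otu_table(matrix(c(1L, 2L, 3L, 4L, 40L, 30L, 20L, 10L), 4,
                        dimnames = list(paste0("s", 1:4), c("up", "down"))))
  expect_equal(unname(correlation_screen(y, min_prevalence = 0)$r["up", "down"]), -1)
})

test_that("prevalence filtering and constant vectors are handled", {
  sim <- small_sim(1)
  scr <- correlation_screen(sim$table, min_prevalence = 0.5)
  expect_true(all(colMeans(unclass(sim$table)[, colnames(scr$r)] > 0) >= 0.5))
  # equal depths so the constant OTU stays constant after normalization
  x <- cbind(v = c(1L, 2L, 3L, 4L), const = c(2L, 2L, 2L, 2L),
             pad = c(7L, 6L, 5L, 4L))
  rownames(x) <- paste0("s", 1:4)
  expect_warning(correlation_screen(otu_table(x), min_prevalence = 0),
                 "constant")
})

test_that("network construction respects thresholds and monotonicity", {
  scr <- screen_from_r(full_r(3))
  net <- build_network(scr)
  expect_equal(igraph::gsize(net), 3)
  topo <- topology(net)
  expect_equal(topo$avg_degree, 2)
  expect_equal(topo$avg_path_length, 1)
  expect_equal(topo$clustering_coefficient, 1)
  expect_equal(topo$positive_edge_ratio, 1)
  expect_error(build_network(scr, r_min = 1.01), "relax")

  set.seed(4)
  r <- cor(matrix(rnorm(200), 20))
  dimnames(r) <- list(paste0("O", 1:10), paste0("O", 1:10))
  scr2 <- screen_from_r(r)
  counts <- sapply(c(0.1, 0.3, 0.5), function(rm)
    igraph::gsize(build_network(scr2, r_min = rm)))
  expect_true(all(diff(counts) <= 0))
})

test_that("path-graph and star closed forms hold", {
  pg <- igraph::make_graph(~ A - B, B - C, C - D)
  expect_equal(topology(pg)$avg_path_length, 10 / 6)
  st <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(st)$name <- paste0("n", 1:5)
  topo <- topology(st)
  expect_equal(topo$clustering_coefficient, 0)
  roles <- keystone_taxa(st, list(membership = setNames(rep(1L, 5), paste0("n", 1:5))))
  expect_equal(roles$otu_id[which.max(roles$degree)], "n1")
  expect_equal(roles$otu_id[which.max(roles$betweenness)], "n1")
})

test_that("module detection recovers planted cliques deterministically", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("O", 1:10)
  igraph::E(g)$weight <- 1
  m <- detect_modules(g, seed = 3)
  expect_equal(sort(m$sizes), c(5L, 5L))
  expect_gt(m$modularity, 0.4)
  expect_identical(m$membership, detect_modules(g, seed = 3)$membership)
  # complete graph: one module, Q ~ 0
  k <- igraph::make_full_graph(6)
  igraph::V(k)$name <- paste0("O", 1:6)
  igraph::E(k)$weight <- 1
  mk <- detect_modules(k, seed = 1)
  expect_equal(length(mk$sizes), 1L)
  expect_lt(abs(mk$modularity), 1e-8)
  # detected partition beats the trivial one-module partition
  expect_gte(m$modularity,
             igraph::modularity(g, rep(1, 10), weights = igraph::E(g)$weight))
})

test_that("module composition fractions sum to one per module", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("O", 1:10)
  igraph::E(g)$weight <- 1
  m <- detect_modules(g, seed = 3)
  cls <- data.frame(otu_id = paste0("O", 1:10),
                    category = rep(c("specialist", "generalist"), c(8, 2)))
  comp <- module_composition(g, m, cls)
  sums <- comp$composition$frac_generalist + comp$composition$frac_specialist +
    comp$composition$frac_neutral
  expect_equal(sums, rep(1, nrow(comp$composition)))
  expect_equal(comp$top_k_size_fraction, 1)
  expect_error(module_composition(g, m, cls[1:5, ]), "unlabelled")
})

test_that("Zi-Pi node roles follow their definitions", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("O", 1:10)
  igraph::E(g)$weight <- 1
  m <- detect_modules(g, seed = 3)
  roles <- keystone_taxa(g, m)
  # all-in-module nodes have Pi = 0
  expect_true(all(roles$pi[!roles$otu_id %in% c("O1", "O6")] == 0))
  # bridge endpoints: 4 of 5 edges inside -> Pi = 1 - (4/5)^2 - (1/5)^2
  expect_equal(roles$pi[roles$otu_id == "O1"], 1 - (4 / 5)^2 - (1 / 5)^2)
  # Zi is a z-score within each module
  for (mod in unique(roles$module)) {
    expect_lt(abs(mean(roles$zi[roles$module == mod])), 1e-8)
  }
  # node with edges split evenly across 2 modules has Pi = 0.5
  h <- igraph::make_graph(~ hub - a, hub - b, a - a2, b - b2)
  mem <- setNames(c(1L, 1L, 2L, 1L, 2L), c("hub", "a", "b", "a2", "b2"))
  rh <- suppressWarnings(keystone_taxa(h, list(membership = mem)))
  expect_equal(rh$pi[rh$otu_id == "hub"], 0.5)
})

test_that("topology statistics are invariant to node order", {
  sim <- small_sim(1)
  scr <- correlation_screen(sim$table, min_prevalence = 0.4)
  net <- build_network(scr, r_min = 0.5)
  perm <- sample(ncol(scr$r))
  scr2 <- list(r = scr$r[perm, perm], p_adj = scr$p_adj[perm, perm])
  net2 <- build_network(scr2, r_min = 0.5)
  t1 <- topology(net); t2 <- topology(net2)
  expect_equal(t1[names(t1) != "positive_edge_ratio"],
               t2[names(t2) != "positive_edge_ratio"])
})
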