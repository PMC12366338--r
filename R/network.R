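#' Pairwise correlation screen for co-occurrence networks
#'
#' Rank (Spearman, default) or Pearson correlations between OTU relative
#' abundances across samples, after removing low-prevalence OTUs. Two-sided
#' p-values use the t approximation and are Benjamini-Hochberg adjusted over
#' all tested pairs. Constant OTU vectors (undefined correlation) are
#' dropped with a warning.
#'
#' @param table an [otu_table()].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_prevalence minimum fraction of samples occupied (default 0.2).
#' @return list with `r` (correlation matrix), `p_adj` (BH-adjusted p
#'   matrix), `n_samples`.
#' @export
correlation_screen <- function(table, method = c("spearman", "pearson"),
                               min_prevalence = 0.2) {
  method <- match.arg(method)
  x <- rel_abund(table, "sample")
  keep <- colMeans(x > 0) >= min_prevalence
  x <- x[, keep, drop = FALSE]
  const <- apply(x, 2L, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warning(sprintf("dropping %d constant OTU vector(s)", sum(const)), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  assert_that(ncol(x) >= 2, "fewer than 2 OTUs pass the prevalence filter")
  n <- nrow(x)
  r <- cor(x, method = method)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  iu <- upper.tri(p)
  p_adj <- p
  p_adj[iu] <- p.adjust(p[iu], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  diag(p_adj) <- 0
  list(r = r, p_adj = p_adj, n_samples = n, method = method)
}

#' Build a thresholded co-occurrence network
#'
#' Keeps an edge for every OTU pair with `|rho| >= r_min` and adjusted
#' `p <= p_max`; records the correlation, its sign, and the adjusted p.
#' Isolated nodes are dropped. Edge weights are `|rho|`.
#'
#' @param screen result of [correlation_screen()] (or a list with `r`,
#'   `p_adj`).
#' @param r_min correlation magnitude threshold (default 0.6).
#' @param p_max adjusted-p threshold (default 0.05).
#' @return an `igraph` graph with edge attributes `rho`, `sign`, `p_adj`,
#'   `weight`.
#' @export
build_network <- function(screen, r_min = 0.6, p_max = 0.05) {
  r <- screen$r; p_adj <- screen$p_adj
  assert_that(all(dim(r) == dim(p_adj)), "correlation and p matrices must align")
  iu <- which(upper.tri(r) & abs(r) >= r_min & p_adj <= p_max, arr.ind = TRUE)
  assert_that(nrow(iu) > 0,
              "no edges pass the thresholds; relax r_min or p_max")
  edges <- data.frame(from = rownames(r)[iu[, 1]], to = colnames(r)[iu[, 2]],
                      rho = r[iu], sign = ifelse(r[iu] > 0, "positive", "negative"),
                      p_adj = p_adj[iu], weight = abs(r[iu]),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Topology statistics of a co-occurrence network
#'
#' Node and edge counts, average degree `2E/N`, average shortest path length
#' on the largest connected component (unweighted), mean local clustering
#' coefficient (nodes of degree < 2 contribute 0), and the positive-edge
#' ratio.
#'
#' @param network an igraph graph from [build_network()].
#' @return named list of statistics.
#' @export
topology <- function(network) {
  assert_that(igraph::gorder(network) > 0, "empty network")
  n <- igraph::gorder(network); e <- igraph::gsize(network)
  comps <- igraph::components(network)
  giant <- igraph::induced_subgraph(network,
                                    which(comps$membership == which.max(comps$csize)))
  apl <- igraph::mean_distance(giant, weights = NA)
  cc_local <- igraph::transitivity(network, type = "local", isolates = "zero")
  cc_local[is.na(cc_local)] <- 0
  pos <- if ("sign" %in% igraph::edge_attr_names(network)) {
    mean(igraph::E(network)$sign == "positive")
  } else NA_real_
  list(n_nodes = n, n_edges = e, avg_degree = 2 * e / n,
       avg_path_length = apl, clustering_coefficient = mean(cc_local),
       positive_edge_ratio = pos,
       largest_component_size = max(comps$csize))
}

#' Detect network modules by seeded modularity maximization
#'
#' Louvain-style greedy modularity maximization on absolute edge weights
#' (the sign of a correlation is ignored for partitioning). The partition is
#' seed-deterministic; modules are relabelled in decreasing size order.
#'
#' @param network igraph graph.
#' @param seed integer seed.
#' @return list with `membership` (named integer, module ids 1 = largest),
#'   `modularity` (Newman Q of the partition), `sizes`.
#' @export
detect_modules <- function(network, seed = 1L) {
  set.seed(as.integer(seed))
  w <- if ("weight" %in% igraph::edge_attr_names(network)) {
    abs(igraph::E(network)$weight)
  } else NULL
  cl <- igraph::cluster_louvain(network, weights = w)
  mem <- igraph::membership(cl)
  sizes <- sort(base::table(mem), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  mem2 <- setNames(as.integer(relabel[as.character(mem)]), names(mem))
  list(membership = mem2,
       modularity = igraph::modularity(network, mem, weights = w),
       sizes = as.integer(sizes))
}

#' Niche-category composition of network modules
#'
#' @param network igraph graph.
#' @param modules result of [detect_modules()].
#' @param classification a [classify_taxa()] result covering every node.
#' @param top_k how many (largest) modules the cumulative size fraction
#'   reports (default 4).
#' @return list with `composition` (data.frame module x category counts and
#'   fractions) and `top_k_size_fraction`.
#' @export
module_composition <- function(network, modules, classification, top_k = 4) {
  nodes <- igraph::V(network)$name
  cat_map <- setNames(classification$category, classification$otu_id)
  missing <- nodes[!nodes %in% names(cat_map)]
  assert_that(length(missing) == 0,
              paste("unlabelled nodes:", paste(head(missing, 5), collapse = ", ")))
  df <- data.frame(module = as.integer(modules$membership[nodes]),
                   category = unname(cat_map[nodes]))
  tab <- as.data.frame.matrix(base::table(df$module, df$category))
  tab$module <- as.integer(rownames(tab))
  tab$n <- rowSums(tab[, setdiff(names(tab), "module"), drop = FALSE])
  for (cl in c("generalist", "specialist", "neutral")) {
    if (!cl %in% names(tab)) tab[[cl]] <- 0L
    tab[[paste0("frac_", cl)]] <- tab[[cl]] / tab$n
  }
  tab <- tab[order(-tab$n), ]
  rownames(tab) <- NULL
  top <- head(tab$n, top_k)
  list(composition = tab,
       top_k_size_fraction = sum(top) / length(nodes))
}

#' Node roles and keystone taxa by the Zi-Pi framework
#'
#' Per node: degree, betweenness centrality, within-module degree z-score
#' `Zi`, and among-module connectivity `Pi = 1 - sum_m (k_im / k_i)^2`.
#' Roles follow the standard thresholds: module hub (`Zi > 2.5`,
#' `Pi <= 0.62`), connector (`Zi <= 2.5`, `Pi > 0.62`), network hub (both),
#' peripheral (neither); keystone taxa are the non-peripheral nodes. Nodes
#' in singleton modules (or modules with zero degree spread) get `Zi = 0`
#' with a warning.
#'
#' @param network igraph graph.
#' @param modules result of [detect_modules()].
#' @param zi_cut,pi_cut role thresholds (defaults 2.5 and 0.62).
#' @return data.frame: `otu_id`, `module`, `degree`, `betweenness`, `zi`,
#'   `pi`, `role`, `keystone`.
#' @export
keystone_taxa <- function(network, modules, zi_cut = 2.5, pi_cut = 0.62) {
  nodes <- igraph::V(network)$name
  mem <- modules$membership[nodes]
  deg <- igraph::degree(network)
  btw <- igraph::betweenness(network, weights = NA)
  adj <- igraph::as_adjacency_matrix(network, sparse = FALSE) > 0
  # within-module degree and module degree profile
  k_in <- numeric(length(nodes))
  pi <- numeric(length(nodes))
  mods <- sort(unique(mem))
  mod_idx <- lapply(mods, function(m) which(mem == m))
  names(mod_idx) <- mods
  for (i in seq_along(nodes)) {
    k_im <- vapply(mod_idx, function(idx) sum(adj[i, idx]), numeric(1))
    k_in[i] <- k_im[[as.character(mem[i])]]
    pi[i] <- if (deg[i] > 0) 1 - sum((k_im / deg[i])^2) else 0
  }
  zi <- numeric(length(nodes))
  warned <- FALSE
  for (m in mods) {
    idx <- mod_idx[[as.character(m)]]
    mu <- mean(k_in[idx]); sdv <- sd(k_in[idx])
    if (length(idx) < 2 || is.na(sdv) || sdv == 0) {
      zi[idx] <- 0
      if (length(idx) < 2) warned <- TRUE
    } else zi[idx] <- (k_in[idx] - mu) / sdv
  }
  if (warned) warning("singleton module(s): Zi set to 0", call. = FALSE)
  role <- ifelse(zi > zi_cut & pi > pi_cut, "network_hub",
          ifelse(zi > zi_cut, "module_hub",
          ifelse(pi > pi_cut, "connector", "peripheral")))
  data.frame(otu_id = nodes, module = as.integer(mem), degree = as.integer(deg),
             betweenness = unname(btw), zi = zi, pi = pi, role = role,
             keystone = role != "peripheral", row.names = NULL,
             stringsAsFactors = FALSE)
}
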