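#' Configure a full pipeline run
#'
#' Either a synthetic scenario or input paths (table, tree, metadata) plus
#' per-stage parameters. Every stochastic stage derives its seed
#' deterministically from the master seed and the stage name (see
#' [derive_seed()]), so a re-run with the same config is bit-identical.
#'
#' @param scenario a [synthetic_scenario()], or `NULL` when paths are given.
#' @param table_path,tree_path,metadata_path input files (used when
#'   `scenario` is `NULL`).
#' @param out_dir output directory (created if needed); `NULL` = no files.
#' @param n_perm quasiswap permutations for classification.
#' @param n_null betaNTI / RC-Bray randomizations.
#' @param n_sim sequential-swap null matrices for the C-score.
#' @param r_min,p_max network thresholds.
#' @param min_prevalence network prevalence filter.
#' @param alpha significance level (classification and forward selection).
#' @param run_assembly,run_network,run_pathmodel stage switches.
#' @param subcommunity_tree `"pruned"` (default) computes subcommunity
#'   betaNTI on the tree pruned to the subcommunity's OTUs; `"full"` keeps
#'   the complete tree.
#' @param seed master integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(scenario = NULL, table_path = NULL, tree_path = NULL,
                       metadata_path = NULL, out_dir = NULL,
                       n_perm = 1000, n_null = 999, n_sim = 1000,
                       r_min = 0.6, p_max = 0.05, min_prevalence = 0.2,
                       alpha = 0.05, run_assembly = TRUE, run_network = TRUE,
                       run_pathmodel = TRUE,
                       subcommunity_tree = c("pruned", "full"), seed = 1L) {
  subcommunity_tree <- match.arg(subcommunity_tree)
  if (is.null(scenario)) {
    assert_that(!is.null(table_path), "either a scenario or a table_path is required")
    assert_that(!run_assembly || !is.null(tree_path),
                "assembly stage enabled but no tree supplied")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full generalist/specialist analysis pipeline
#'
#' Stages: niche classification (quasiswap nulls) and subcommunity split;
#' assembly processes per subcommunity and overall (betaNTI, RC-Bray,
#' five-process partition, Sloan neutral model, C-score SES); co-occurrence
#' network with modules, composition, and Zi-Pi keystones; PCNM eigenvectors
#' with forward selection; and PLS path models of overall and per-category
#' richness. Subcommunity tables are the subset of classified OTUs
#' re-normalized within the subset. Writes tab-delimited stage tables and a
#' machine-readable JSON report when `out_dir` is set; a stage failure
#' halts with the stage name, keeping earlier outputs.
#'
#' @param config a [run_config()].
#' @return a `pipeline_result` list with one element per stage plus
#'   `report` (parameters, seeds, summary statistics).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  outd <- config$out_dir
  if (!is.null(outd)) dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (!is.null(outd))
      write.table(df, file.path(outd, paste0(name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  res <- list()

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$scenario)) {
    sim <- stage("simulate", simulate_structured_table(config$scenario))
    tab <- sim$table; meta <- sim$metadata; truth <- sim$truth
    ph <- stage("simulate", simulate_phylogeny(config$scenario$n_otus, 1,
                                               derive_seed(seed, "phylogeny")))
    tree <- ape::keep.tip(ph$tree, colnames(tab))
    res$truth <- truth
    if (!is.null(outd)) {
      write_otu_table(tab, file.path(outd, "otu_table.tsv"))
      write_metadata(meta, file.path(outd, "metadata.tsv"))
      emit(truth, "ground_truth")
      ape::write.tree(tree, file.path(outd, "tree.nwk"))
    }
  } else {
    tab <- stage("read", read_otu_table(config$table_path))
    tree <- if (!is.null(config$tree_path))
      stage("read", read_tree(config$tree_path, tab)) else NULL
    meta <- if (!is.null(config$metadata_path))
      stage("read", read_metadata(config$metadata_path, tab)) else NULL
  }

  # --- classification -----------------------------------------------------
  cls <- stage("classify", classify_taxa(tab, n_perm = config$n_perm,
                                         alpha = config$alpha,
                                         seed = derive_seed(seed, "classify")))
  res$classification <- cls
  emit(as.data.frame(cls), "classification")
  rich_test <- stage("classify", group_richness_test(tab, cls))
  res$richness <- rich_test
  emit(rich_test$richness, "richness_by_group")

  sub_ids <- list(overall = cls$otu_id,
                  generalist = cls$otu_id[cls$category == "generalist"],
                  specialist = cls$otu_id[cls$category == "specialist"],
                  neutral = cls$otu_id[cls$category == "neutral"])
  sub_tables <- lapply(sub_ids, function(ids) {
    ids <- ids[colSums(tab[, ids, drop = FALSE]) > 0]
    if (length(ids) < 10) return(NULL)
    keep <- rowSums(tab[, ids, drop = FALSE]) > 0
    suppressWarnings(otu_table(unclass_table(tab)[keep, ids, drop = FALSE]))
  })

  # --- assembly -----------------------------------------------------------
  if (config$run_assembly && !is.null(tree)) {
    res$assembly <- list()
    for (g in names(sub_tables)) {
      st <- sub_tables[[g]]
      if (is.null(st)) next
      gtree <- if (config$subcommunity_tree == "pruned")
        ape::keep.tip(tree, colnames(st)) else tree
      bnti <- stage("assembly", beta_nti(st, gtree, n_null = config$n_null,
                                         seed = derive_seed(seed, paste0("bnti_", g))))
      rc <- stage("assembly", raup_crick_bray(st, n_null = config$n_null,
                                              seed = derive_seed(seed, paste0("rc_", g))))
      part <- partition_processes(bnti, rc)
      ncm <- tryCatch(fit_sloan_ncm(st), error = function(e) NULL)
      cs <- stage("assembly", c_score_ses(st, n_sim = config$n_sim,
                                          seed = derive_seed(seed, paste0("cs_", g))))
      res$assembly[[g]] <- list(partition = part, ncm = ncm, c_score = cs)
      iu <- which(upper.tri(bnti), arr.ind = TRUE)
      emit(data.frame(sample_i = rownames(bnti)[iu[, 1]],
                      sample_j = colnames(bnti)[iu[, 2]],
                      bnti = bnti[iu], rc_bray = rc[iu]),
           paste0("assembly_pairs_", g))
    }
  }

  # --- network ------------------------------------------------------------
  if (config$run_network) {
    scr <- stage("network", correlation_screen(tab, min_prevalence = config$min_prevalence))
    net <- stage("network", build_network(scr, r_min = config$r_min,
                                          p_max = config$p_max))
    mods <- detect_modules(net, seed = derive_seed(seed, "modules"))
    topo <- topology(net)
    topo$modularity <- mods$modularity
    comp <- module_composition(net, mods, cls)
    keys <- keystone_taxa(net, mods)
    res$network <- list(graph = net, topology = topo, modules = mods,
                        composition = comp, keystones = keys)
    emit(keys, "node_roles")
    emit(comp$composition, "module_composition")
  }

  # --- spatial + path model ----------------------------------------------
  if (config$run_pathmodel && !is.null(meta)) {
    pc <- stage("pcnm", pcnm_eigenvectors(meta))
    rich_overall <- sample_richness(tab)
    fs <- stage("pcnm", forward_select(pc$vectors, rich_overall,
                                       alpha = config$alpha, n_perm = 499,
                                       seed = derive_seed(seed, "forward")))
    res$pcnm <- list(pcnm = pc, selection = fs)
    axes <- if (length(fs$selected) >= 2) fs$selected[1:2] else
      seq_len(min(2, ncol(pc$vectors)))
    pm_data <- meta
    pm_data$PC2 <- pc$vectors[, axes[1]]
    pm_data$PC3 <- pc$vectors[, min(axes[length(axes)], ncol(pc$vectors))]
    need <- c("PC2", "PC3", "ASP", "CC", "SR", "LT", "BA", "DEN")
    if (all(need %in% names(pm_data))) {
      responses <- data.frame(overall = as.numeric(rich_overall))
      for (g in c("generalist", "specialist", "neutral")) {
        if (length(sub_ids[[g]]) > 0)
          responses[[g]] <- as.numeric(sample_richness(tab, sub_ids[[g]]))
      }
      pmr <- stage("plspm", fit_per_subcommunity(responses, pm_data,
                                                 default_path_spec()))
      res$pathmodel <- pmr
      emit(pmr$comparison, "path_effects")
    }
  }

  # --- report -------------------------------------------------------------
  report <- list(
    package_version = as.character(utils::packageVersion("nicheassembly")),
    seed = seed,
    parameters = config[c("n_perm", "n_null", "n_sim", "r_min", "p_max",
                          "min_prevalence", "alpha", "subcommunity_tree")],
    n_samples = nrow(tab), n_otus = ncol(tab),
    classification = as.list(attr(cls, "proportions")),
    kruskal_wallis_H = res$richness$statistic
  )
  if (!is.null(res$assembly)) report$assembly <- lapply(res$assembly, function(a)
    list(process_fractions = as.list(a$partition$process_fractions),
         stochastic_fraction = a$partition$stochastic_fraction,
         ncm = if (!is.null(a$ncm)) list(m = a$ncm$m, r_squared = a$ncm$r_squared),
         c_score_ses = a$c_score$ses))
  if (!is.null(res$network)) report$network <- res$network$topology
  if (!is.null(res$pathmodel)) {
    report$gof <- vapply(res$pathmodel$fits, function(f) f$gof, numeric(1))
    report$pcnm_selected <- res$pcnm$selection$names
  }
  res$report <- report
  if (!is.null(outd))
    jsonlite::write_json(report, file.path(outd, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(res) <- "pipeline_result"
  res
}

#' Write a miniature fixture scenario to disk
#'
#' A 24-sample (6 x 4 grid), 200-OTU scenario with planted generalists and
#' specialists, its phylogeny, metadata, and ground truth, plus the small
#' worked matrices used in unit tests. All files are plain text.
#'
#' @param out_dir directory (created).
#' @param seed integer seed.
#' @return invisibly, the list of written paths.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scen <- fixture_scenario(seed)
  sim <- simulate_structured_table(scen)
  ph <- simulate_phylogeny(scen$n_otus, 1, derive_seed(seed, "phylogeny"))
  tree <- ape::keep.tip(ph$tree, colnames(sim$table))
  paths <- c(
    table = write_otu_table(sim$table, file.path(out_dir, "otu_table.tsv")),
    metadata = write_metadata(sim$metadata, file.path(out_dir, "metadata.tsv")),
    truth = write_metadata(sim$truth, file.path(out_dir, "ground_truth.tsv")))
  ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
  paths["tree"] <- file.path(out_dir, "tree.nwk")
  toy <- matrix(c(5L, 3L, 2L, 0L, 0L, 10L), nrow = 3,
                dimnames = list(paste0("S", 1:3), c("OTU_even", "OTU_point")))
  paths["toy"] <- write_otu_table(otu_table(toy), file.path(out_dir, "toy_levins.tsv"))
  invisible(paths)
}

#' The standard small test scenario (24 samples, 200 OTUs)
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_scenario()].
#' @return a [synthetic_scenario()].
#' @export
fixture_scenario <- function(seed = 1L, ...) {
  args <- list(n_otus = 200, n_generalists = 20, n_specialists = 60,
               grid_shape = c(6L, 4L), community_size = 2000, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_scenario, args)
}
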