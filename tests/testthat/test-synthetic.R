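test_that("every simulated sample sums exactly to the community size", {
  sim <- small_sim(1)
  expect_true(all(unclass(sim$table) >= 0))
  expect_identical(typeof(unclass(sim$table)), "integer")
  expect_equal(unname(rowSums(sim$table)), rep(2000, 24))

  scen <- fixture_scenario(3)
  nt <- suppressWarnings(simulate_neutral_table(scen))
  expect_equal(unname(rowSums(nt)), rep(2000, 24))
})

test_that("structured tables are reproducible from the seed", {
  a <- suppressWarnings(simulate_structured_table(fixture_scenario(7)))
  b <- suppressWarnings(simulate_structured_table(fixture_scenario(7)))
  c <- suppressWarnings(simulate_structured_table(fixture_scenario(8)))
  expect_identical(unclass(a$table), unclass(b$table))
  expect_false(identical(unclass(a$table), unclass(c$table)))
})

test_that("an all-generalist community occupies essentially every sample", {
  scen <- synthetic_scenario(n_otus = 50, n_generalists = 50, n_specialists = 0,
                             grid_shape = c(6L, 4L), community_size = 10000,
                             seed = 2)
  sim <- simulate_structured_table(scen)
  occ <- colMeans(unclass(sim$table) > 0)
  # multinomial oracle: detection probability per cell at the smallest
  # expected share (~0.2/50 of 1e4 reads) is 1 - (1 - p)^N, essentially 1
  p_min <- min(rel_abund(sim$table, "sample")[unclass(sim$table) > 0])
  expect_gt(1 - (1 - p_min)^10000, 0.999)
  expect_true(all(occ >= 0.95))
})

test_that("a point-kernel specialist collapses to one sample and off-grid optima go extinct", {
  scen <- synthetic_scenario(n_otus = 20, n_generalists = 5, n_specialists = 15,
                             grid_shape = c(5L, 4L), community_size = 5000,
                             sigma_niche = 0, seed = 4)
  sim <- suppressWarnings(simulate_structured_table(scen))
  # sigma = 0 makes the kernel a point mass: a specialist can only occur in
  # quadrats whose gradient value equals its optimum exactly
  g <- sim$metadata$gradient
  spec <- sim$truth[sim$truth$true_category == "specialist" & !sim$truth$extinct, ]
  for (k in seq_len(nrow(spec))) {
    hits <- which(unclass(sim$table)[, spec$otu_id[k]] > 0)
    expect_true(all(g[hits] == spec$optimum[k]))
  }
  # an off-grid optimum under a point kernel is flagged extinct
  opt <- sim$truth$optimum
  opt[6] <- 99 # a gradient value that occurs nowhere
  sim2 <- suppressWarnings(simulate_structured_table(scen, optima = opt,
                                                     scale_optima = FALSE))
  expect_true(sim2$truth$extinct[6])
})

test_that("zero community size is rejected", {
  expect_error(synthetic_scenario(community_size = 0), "positive")
})

test_that("planted generalists have wider niche breadth than planted specialists across seeds", {
  for (s in 1:5) {
    sim <- small_sim(s)
    b <- levins_niche_breadth(sim$table)
    tr <- sim$truth[sim$truth$otu_id %in% colnames(sim$table), ]
    expect_gt(mean(b[tr$otu_id[tr$true_category == "generalist"]]),
              mean(b[tr$otu_id[tr$true_category == "specialist"]]))
  }
})

test_that("two-tip phylogenies are a cherry with additive patristic distance", {
  ph <- simulate_phylogeny(2, 1, 1)
  expect_equal(ape::Ntip(ph$tree), 2)
  expect_equal(unname(cophenetic(ph$tree)[1, 2]),
               sum(ph$tree$edge.length[ph$tree$edge[, 2] <= 2]))
  expect_error(simulate_phylogeny(1, 1, 1), "at least 2")
})

test_that("full phylogenetic signal clusters optima within deep clades", {
  ph <- simulate_phylogeny(64, 1, 3)
  root_children <- ph$tree$edge[ph$tree$edge[, 1] == ape::Ntip(ph$tree) + 1, 2]
  clade1 <- ape::extract.clade(ph$tree, root_children[1])$tip.label
  o <- ph$optima
  within <- var(o[clade1]) + var(o[setdiff(names(o), clade1)])
  between <- var(o)
  expect_lt(within / 2, between)
  # reproducibility
  expect_identical(simulate_phylogeny(64, 1, 3)$optima, o)
})

test_that("environmental fields are spatially autocorrelated at the stated range", {
  co <- grid_coordinates(c(10L, 8L), 20)
  env <- simulate_environment(co, autocorr_range = 60, seed = 2)
  expect_gt(morans_i(env$CC, co, 20), 0)
  # range much larger than the grid extent gives a near-constant field
  flat <- simulate_environment(co, autocorr_range = 1e5, seed = 2)
  expect_lt(var(flat$CC), 0.05)
  expect_warning(simulate_environment(co, autocorr_range = 0, seed = 2),
                 "white noise")
  expect_identical(simulate_environment(co, seed = 9)$SR,
                   simulate_environment(co, seed = 9)$SR)
})

test_that("neutral tables converge to the metacommunity as migration grows", {
  p <- rep(1 / 20, 20)
  tv <- sapply(c(0.1, 100), function(m) {
    scen <- synthetic_scenario(n_otus = 20, n_generalists = 0,
                               n_specialists = 0, grid_shape = c(4L, 3L),
                               community_size = 5000, migration_rate_m = m,
                               seed = 6)
    nt <- simulate_neutral_table(scen, p)
    mean(apply(rel_abund(nt, "sample"), 1, function(f) sum(abs(f - p)) / 2))
  })
  expect_lt(tv[2], tv[1])
  expect_lt(tv[2], 0.05)
})

test_that("neutral occurrence frequencies track the Sloan prediction", {
  scen <- synthetic_scenario(n_otus = 500, n_generalists = 0,
                             n_specialists = 0, grid_shape = c(8L, 5L),
                             community_size = 1000, migration_rate_m = 0.2,
                             seed = 9)
  nt <- suppressWarnings(simulate_neutral_table(scen))
  fit <- fit_sloan_ncm(nt)
  expect_gte(cor(fit$otu$freq_obs, fit$otu$freq_pred), 0.9)
})

test_that("zero-frequency metacommunity OTUs are dropped with a warning", {
  p <- c(0.5, 0.5, 0)
  scen <- synthetic_scenario(n_otus = 3, n_generalists = 0, n_specialists = 0,
                             grid_shape = c(2L, 2L), community_size = 100,
                             seed = 1)
  expect_warning(nt <- simulate_neutral_table(scen, p), "zero metacommunity")
  expect_equal(ncol(nt), 2)
})
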