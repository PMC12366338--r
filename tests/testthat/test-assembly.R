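two_tip_tree <- function() ape::read.tree(text = "(A:1,B:1);")

test_that("betaMNTD matches its closed forms and symmetry contract", {
  # two singleton communities at patristic distance 2
  tab <- otu_table(matrix(c(5L, 0L, 0L, 3L), 2,
                          dimnames = list(c("k", "l"), c("A", "B"))))
  bm <- beta_mntd(tab, two_tip_tree())
  expect_equal(unname(bm["k", "l"]), 2)
  # identical communities
  tab2 <- otu_table(matrix(c(5L, 5L, 3L, 3L), 2,
                           dimnames = list(c("k", "l"), c("A", "B"))))
  expect_equal(unname(beta_mntd(tab2, two_tip_tree())["k", "l"]), 0)
  # symmetry / zero diagonal on a real community
  sim <- small_sim(1)
  tr <- ape::keep.tip(small_tree(1)$tree, colnames(sim$table))
  b <- beta_mntd(sim$table, tr)
  expect_equal(b, t(b))
  expect_equal(unname(diag(b)), rep(0, nrow(b)))
})

test_that("abundance-weighted betaMNTD agrees with picante's comdistnt", {
  skip_if_not_installed("picante")
  sim <- small_sim(2)
  tr <- ape::keep.tip(small_tree(2)$tree, colnames(sim$table))
  ours <- beta_mntd(sim$table, tr)
  theirs <- as.matrix(picante::comdistnt(unclass(sim$table), cophenetic(tr),
                                         abundance.weighted = TRUE))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)], tolerance = 1e-10)
})

test_that("betaNTI is invariant to branch-length scaling and sample relabeling", {
  sim <- small_sim(1)
  sub <- suppressWarnings(otu_table(unclass(sim$table)[1:8, 1:80]))
  tr <- ape::keep.tip(small_tree(1)$tree, colnames(sub))
  nti <- suppressWarnings(beta_nti(sub, tr, n_null = 49, seed = 5))
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 7
  nti2 <- suppressWarnings(beta_nti(sub, tr2, n_null = 49, seed = 5))
  expect_equal(nti, nti2, tolerance = 1e-8, ignore_attr = TRUE)
  # betaMNTD itself scales linearly
  expect_equal(attr(nti2, "bmntd_obs"), 7 * attr(nti, "bmntd_obs"),
               tolerance = 1e-10)
  # relabeling samples permutes the matrix
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  subp <- suppressWarnings(otu_table(unclass(sub)[perm, ]))
  ntip <- suppressWarnings(beta_nti(subp, tr, n_null = 49, seed = 5))
  expect_equal(ntip, nti[rownames(ntip), colnames(ntip)], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a star phylogeny makes every betaNTI pair degenerate", {
  n <- 12
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- paste0("t", 1:n)
  set.seed(2)
  x <- matrix(rpois(5 * n, 3) + 1L, 5, n,
              dimnames = list(paste0("s", 1:5), star$tip.label))
  expect_warning(nti <- beta_nti(otu_table(x), star, n_null = 29, seed = 1),
                 "degenerate")
  expect_true(all(is.na(nti[upper.tri(nti)])))
})

test_that("RC-Bray is bounded, deterministic, and flags near-identical pairs", {
  sim <- small_sim(1)
  x <- unclass(sim$table)[1:10, ]
  x[2, ] <- x[1, ]
  tb <- suppressWarnings(otu_table(x))
  rc <- raup_crick_bray(tb, n_null = 99, seed = 4)
  expect_true(all(rc >= -1 & rc <= 1))
  expect_equal(rc, t(rc))
  expect_equal(unname(rc[1, 2]), -1)
  expect_identical(rc, raup_crick_bray(tb, n_null = 99, seed = 4))
})

test_that("process partitioning book-keeps its five fractions", {
  n <- 6
  mk <- function(v) matrix(v, n, n, dimnames = NULL) * (1 - diag(n))
  all3 <- partition_processes(mk(3), mk(0))
  expect_equal(all3$process_fractions[["heterogeneous_selection"]], 1)
  expect_equal(all3$deterministic_fraction, 1)
  drift <- partition_processes(mk(0), mk(0))
  expect_equal(drift$process_fractions[["drift"]], 1)
  expect_equal(drift$stochastic_fraction, 1)

  set.seed(1)
  b <- matrix(rnorm(n * n, 0, 3), n); b <- (b + t(b)) / 2; diag(b) <- 0
  r <- matrix(runif(n * n, -1, 1), n); r <- (r + t(r)) / 2; diag(r) <- 0
  pp <- partition_processes(b, r)
  expect_equal(sum(pp$process_fractions), 1, tolerance = 1e-12)
  expect_equal(pp$deterministic_fraction + pp$stochastic_fraction, 1)
  # raising the selection cutoff cannot increase the deterministic fraction
  pp2 <- partition_processes(b, r, bnti_cut = 3)
  expect_lte(pp2$deterministic_fraction, pp$deterministic_fraction)
  # undefined pairs are excluded and counted
  b2 <- b; b2[1, 2] <- b2[2, 1] <- NA
  pp3 <- partition_processes(b2, r)
  expect_equal(pp3$n_excluded, 1)
  expect_equal(pp3$n_pairs, choose(n, 2) - 1)
})

test_that("the Sloan curve is monotone in abundance and migration", {
  p <- 10^seq(-6, -3, length.out = 40) # below the saturation region f = 1
  f1 <- pbeta(log(2) / 1e4, 1e4 * 0.1 * p, 1e4 * 0.1 * (1 - p), lower.tail = FALSE)
  expect_true(all(diff(f1) > 0))
  for (pp in c(1e-4, 1e-3)) {
    fm <- sapply(c(0.01, 0.05, 0.2, 1), function(m)
      pbeta(log(2) / 1e4, 1e4 * m * pp, 1e4 * m * (1 - pp), lower.tail = FALSE))
    expect_true(all(diff(fm) > 0))
  }
})

test_that("noiseless Sloan input refits its migration rate almost exactly", {
  n_reads <- 1e4; d <- log(2) / n_reads; m_true <- 0.1
  p <- 10^seq(-6, -1.5, length.out = 200)
  f <- pbeta(d, n_reads * m_true * p, n_reads * m_true * (1 - p),
             lower.tail = FALSE)
  cf <- fit_sloan_curve(p, f, n_reads, d)
  expect_equal(cf$m, m_true, tolerance = 1e-4)
  expect_gte(cf$r_squared, 0.999)
})

test_that("environmental filtering lowers the neutral fit relative to a matched neutral table", {
  for (s in 1:3) {
    scen <- fixture_scenario(s, n_generalists = 0, n_specialists = 150,
                             community_size = 1000)
    filt <- suppressWarnings(simulate_structured_table(scen))
    neut <- suppressWarnings(simulate_neutral_table(scen))
    r2_f <- fit_sloan_ncm(filt$table)$r_squared
    r2_n <- fit_sloan_ncm(neut)$r_squared
    expect_lt(r2_f, r2_n)
  }
})

test_that("degenerate neutral-model inputs are refused", {
  x <- matrix(rep(c(3L, 4L), 50), 10, 10,
              dimnames = list(paste0("s", 1:10), paste0("o", 1:10)))
  expect_error(fit_sloan_ncm(otu_table(x)), "identical occurrence")
  expect_error(fit_sloan_ncm(otu_table(x[1:5, 1:5] + diag(5L))), "at least 10")
})
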