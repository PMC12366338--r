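#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For each pair of samples (k, l):
#' `betaMNTD = 0.5 * [ sum_j f_jk min_{j' in l} d(j, j') +
#'                     sum_j f_jl min_{j' in k} d(j, j') ]`
#' with `f` the relative abundances (or `1/richness` when unweighted) and
#' `d` the patristic distance on the phylogeny. Identical communities give 0;
#' the matrix is symmetric with zero diagonal.
#'
#' @param table an [otu_table()]; every OTU must be a tree tip.
#' @param tree an ape `phylo` with nonnegative branch lengths.
#' @param weighted abundance-weighted (default) or presence-based.
#' @return symmetric numeric matrix over samples.
#' @export
beta_mntd <- function(table, tree, weighted = TRUE) {
  check_tree_tips(tree, table)
  tree <- ape::keep.tip(tree, colnames(table))
  d <- cophenetic(tree)[colnames(table), colnames(table)]
  bmntd_from_dist(unclass_table(table), d, weighted = weighted)
}

# core: table (samples x taxa), d aligned taxa distance matrix
bmntd_from_dist <- function(x, d, weighted = TRUE, perm = seq_len(ncol(x))) {
  presence <- apply(x > 0, 1L, which, simplify = FALSE)
  bad <- lengths(presence) == 0
  assert_that(!any(bad), "samples with no OTUs on the tree")
  f <- t(x / rowSums(x)) # taxa x samples
  if (!weighted) { f <- t((x > 0) / rowSums(x > 0)) }
  m <- .min_taxon_dist(d, presence, as.integer(perm))
  a <- crossprod(f, m)
  out <- 0.5 * (a + t(a))
  dimnames(out) <- list(rownames(x), rownames(x))
  out
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardizes the observed betaMNTD of every sample pair against a null
#' distribution obtained by shuffling the taxa across the tips of the
#' phylogeny (`n_null` randomizations):
#' `betaNTI = (betaMNTD_obs - mean_null) / sd_null`.
#' `|betaNTI| > 2` is conventionally read as deterministic selection
#' (heterogeneous if positive, homogeneous if negative). Pairs whose null
#' distribution is degenerate (`sd = 0`, e.g. on a star tree with equal
#' branch lengths) are reported `NA` with a warning.
#'
#' @inheritParams beta_mntd
#' @param n_null number of tip shuffles (default 999).
#' @param seed integer seed.
#' @return symmetric matrix of betaNTI values with attribute `bmntd_obs`.
#' @export
beta_nti <- function(table, tree, n_null = 999, seed = 1L, weighted = TRUE) {
  check_tree_tips(tree, table)
  tree <- ape::keep.tip(tree, colnames(table))
  d <- cophenetic(tree)[colnames(table), colnames(table)]
  x <- unclass_table(table)
  obs <- bmntd_from_dist(x, d, weighted = weighted)
  n <- ncol(x)
  set.seed(as.integer(seed))
  s1 <- matrix(0, nrow(x), nrow(x)); s2 <- s1
  for (b in seq_len(n_null)) {
    nb <- bmntd_from_dist(x, d, weighted = weighted, perm = sample.int(n))
    s1 <- s1 + nb
    s2 <- s2 + nb^2
  }
  mu <- s1 / n_null
  sdv <- sqrt(pmax(s2 / n_null - mu^2, 0) * n_null / (n_null - 1))
  nti <- (obs - mu) / sdv
  degen <- sdv < 1e-12
  diag(degen) <- FALSE
  if (any(degen)) {
    warning(sprintf("betaNTI undefined for %d pair(s): degenerate null (sd = 0)",
                    sum(degen) / 2), call. = FALSE)
    nti[degen] <- NA_real_
  }
  diag(nti) <- 0
  attr(nti, "bmntd_obs") <- obs
  nti
}

bray_curtis <- function(x) {
  # x: samples x taxa counts
  n <- nrow(x)
  out <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  tot <- rowSums(x)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    out[a, b] <- out[b, a] <- sum(abs(x[a, ] - x[b, ])) / (tot[a] + tot[b])
  }
  out
}

#' Abundance-based Raup-Crick dissimilarity (RC-Bray)
#'
#' For each pair of samples, `n_null` pairs of null communities are
#' assembled: each null community keeps its sample's observed richness and
#' read depth, species are drawn without replacement with probability
#' proportional to their occurrence frequency across samples, each drawn
#' species receives one individual, and the remaining reads are assigned
#' multinomially in proportion to the species' total relative abundances.
#' Bray-Curtis dissimilarity is computed for every null pair and the
#' observed value is located in that distribution:
#' `RC = [(# null < obs) + 0.5 (# null = obs)] / n_null`, rescaled to
#' `2 (RC - 0.5)` in `[-1, 1]`. Values near -1 mean the two communities are
#' far more similar than expected by chance, near +1 far less similar.
#'
#' @param table an [otu_table()].
#' @param n_null number of null draws (default 999).
#' @param seed integer seed.
#' @return symmetric matrix in `[-1, 1]`.
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = 1L) {
  x <- unclass_table(table)
  assert_that(all(rowSums(x > 0) > 0), "samples with zero richness")
  set.seed(as.integer(seed))
  n_s <- nrow(x); n_o <- ncol(x)
  occ <- colSums(x > 0)              # occurrence frequency weights
  abw <- colSums(x) / sum(x)         # abundance weights
  rich <- rowSums(x > 0)
  depth <- rowSums(x)
  obs_bc <- bray_curtis(x)
  stacks <- vector("list", n_s)
  for (i in seq_len(n_s)) {
    st <- matrix(0L, n_o, n_null)
    for (k in seq_len(n_null)) {
      sp <- sample.int(n_o, rich[i], prob = occ)
      cnt <- rep.int(1L, rich[i])
      extra <- depth[i] - rich[i]
      if (extra > 0) cnt <- cnt + rmultinom(1, extra, abw[sp])[, 1]
      st[sp, k] <- cnt
    }
    stacks[[i]] <- st
  }
  cmp <- .rc_null_counts(stacks, obs_bc, 1e-12)
  rc <- 2 * ((cmp$n_less + 0.5 * cmp$n_equal) / n_null - 0.5)
  diag(rc) <- 0
  dimnames(rc) <- dimnames(obs_bc)
  rc
}

#' Partition community turnover into five assembly processes
#'
#' Per sample pair: `betaNTI > +cut` heterogeneous selection;
#' `betaNTI < -cut` homogeneous selection; `|betaNTI| <= cut` with
#' `RC > +rc_cut` dispersal limitation, with `RC < -rc_cut` homogenizing
#' dispersal, otherwise drift. Fractions are category counts over all pairs
#' with defined betaNTI; the deterministic fraction is the two selection
#' processes, the stochastic fraction the rest, and the two sum to 1.
#'
#' @param bnti betaNTI matrix from [beta_nti()].
#' @param rc_bray RC-Bray matrix from [raup_crick_bray()], same samples.
#' @param bnti_cut selection threshold (default 2).
#' @param rc_cut dispersal threshold (default 0.95).
#' @return an `assembly_result` list: `process_fractions` (5-vector summing
#'   to 1), `deterministic_fraction`, `stochastic_fraction`, `n_pairs`,
#'   `n_excluded`.
#' @export
partition_processes <- function(bnti, rc_bray, bnti_cut = 2, rc_cut = 0.95) {
  assert_that(all(dim(bnti) == dim(rc_bray)), "matrices must be aligned")
  iu <- upper.tri(bnti)
  b <- bnti[iu]; r <- rc_bray[iu]
  keep <- is.finite(b)
  n_excluded <- sum(!keep)
  b <- b[keep]; r <- r[keep]
  proc <- ifelse(b > bnti_cut, "heterogeneous_selection",
          ifelse(b < -bnti_cut, "homogeneous_selection",
          ifelse(r > rc_cut, "dispersal_limitation",
          ifelse(r < -rc_cut, "homogenizing_dispersal", "drift"))))
  lv <- c("heterogeneous_selection", "homogeneous_selection",
          "dispersal_limitation", "homogenizing_dispersal", "drift")
  frac <- base::table(factor(proc, lv)) / length(proc)
  frac <- setNames(as.numeric(frac), lv)
  det <- frac[["heterogeneous_selection"]] + frac[["homogeneous_selection"]]
  structure(list(process_fractions = frac,
                 deterministic_fraction = det,
                 stochastic_fraction = 1 - det,
                 n_pairs = length(proc), n_excluded = n_excluded,
                 bnti_cut = bnti_cut, rc_cut = rc_cut),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("assembly over %d pairs: %.1f%% deterministic, %.1f%% stochastic\n",
              x$n_pairs, 100 * x$deterministic_fraction,
              100 * x$stochastic_fraction))
  for (p in names(x$process_fractions))
    cat(sprintf("  %-24s %6.1f%%\n", p, 100 * x$process_fractions[[p]]))
  invisible(x)
}
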