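#' Levins niche breadth per OTU
#'
#' `B_j = 1 / sum_i P_ij^2` where `P_ij` is the proportion of OTU `j`'s reads
#' found in sample `i` (each sample treated as a "habitat"), so
#' `sum_i P_ij = 1` and `B` ranges from 1 (all reads in one sample) to the
#' number of samples (perfectly even spread). The per-OTU normalization is
#' the standard Levins convention; a per-sample normalization (which breaks
#' the `B <= n_samples` bound) is available for comparison.
#'
#' @param table an [otu_table()].
#' @param normalization `"otu"` (default, Levins) or `"sample"`.
#' @return named numeric vector of `B_j` over OTUs.
#' @export
levins_niche_breadth <- function(table, normalization = c("otu", "sample")) {
  normalization <- match.arg(normalization)
  p <- rel_abund(table, margin = if (normalization == "otu") "otu" else "sample")
  if (normalization == "sample") p <- sweep(p, 2L, colSums(p), "/")
  1 / colSums(p^2)
}

#' Quasiswap permutation nulls of a count table
#'
#' Null tables preserve the observed row sums and column sums exactly (and,
#' by the quasiswap count algorithm, the matrix fill): each is produced by an
#' r2dtable-style random fill followed by marginal-preserving 2x2 submatrix
#' updates, via `vegan`'s `quasiswap_count` null model. Draws are mutually
#' independent re-randomizations and the stream is seed-deterministic.
#'
#' @param table an [otu_table()] (>= 2 samples and >= 2 OTUs).
#' @param n_perm number of null tables (>= 1).
#' @param seed integer seed.
#' @return 3-d integer array `samples x OTUs x n_perm`.
#' @export
quasiswap_nulls <- function(table, n_perm = 1000, seed = 1L) {
  assert_that(n_perm >= 1, "n_perm must be >= 1")
  assert_that(nrow(table) >= 2 && ncol(table) >= 2,
              "quasiswap needs at least a 2 x 2 table")
  nm <- vegan::nullmodel(unclass_table(table), "quasiswap_count")
  sims <- stats::simulate(nm, nsim = n_perm, seed = as.integer(seed))
  array(sims, dim = dim(sims), dimnames = dimnames(sims))
}

#' Classify OTUs into habitat generalists, specialists, and neutral taxa
#'
#' The observed Levins niche breadth of each OTU is compared with the
#' empirical (alpha/2, 1 - alpha/2) quantiles of its own null distribution
#' across `n_perm` quasiswap permutation tables: above the upper quantile =
#' generalist (wider breadth than the marginal-preserving null), below the
#' lower = specialist, otherwise neutral. Ties at a quantile boundary
#' resolve to neutral (conservative). `measure = "occurrence"` classifies on
#' the number of occupied samples instead of breadth.
#'
#' @param table an [otu_table()].
#' @param n_perm number of quasiswap permutations (default 1000).
#' @param alpha two-sided significance level (default 0.05).
#' @param seed integer seed.
#' @param measure `"breadth"` (default) or `"occurrence"`.
#' @return a `niche_classification` data.frame: `otu_id`, `levins_B`,
#'   `occurrence`, `null_low`, `null_high`, `category`; attributes carry the
#'   per-category counts and proportions.
#' @export
classify_taxa <- function(table, n_perm = 1000, alpha = 0.05, seed = 1L,
                          measure = c("breadth", "occurrence")) {
  measure <- match.arg(measure)
  if (n_perm < 2 / alpha)
    warning(sprintf("n_perm = %d is small for alpha = %g quantiles", n_perm, alpha),
            call. = FALSE)
  x <- unclass_table(table)
  obs_b <- levins_niche_breadth(table)
  occ <- colSums(x > 0)
  obs <- if (measure == "breadth") obs_b else occ

  sims <- quasiswap_nulls(table, n_perm = n_perm, seed = seed)
  cs <- colSums(x) # preserved by the null
  null_stat <- matrix(NA_real_, n_perm, ncol(x))
  for (k in seq_len(n_perm)) {
    s <- sims[, , k]
    null_stat[k, ] <- if (measure == "breadth") {
      1 / colSums(sweep(s, 2L, cs, "/")^2)
    } else colSums(s > 0)
  }
  q <- apply(null_stat, 2L, quantile, probs = c(alpha / 2, 1 - alpha / 2),
             names = FALSE)
  category <- ifelse(obs > q[2, ], "generalist",
                     ifelse(obs < q[1, ], "specialist", "neutral"))
  out <- data.frame(otu_id = colnames(x), levins_B = obs_b, occurrence = occ,
                    null_low = q[1, ], null_high = q[2, ], category = category,
                    stringsAsFactors = FALSE, row.names = NULL)
  counts <- base::table(factor(out$category, c("generalist", "specialist", "neutral")))
  attr(out, "counts") <- counts
  attr(out, "proportions") <- counts / sum(counts)
  attr(out, "params") <- list(n_perm = n_perm, alpha = alpha, seed = seed,
                              measure = measure)
  class(out) <- c("niche_classification", class(out))
  out
}

#' @export
print.niche_classification <- function(x, ...) {
  pr <- attr(x, "proportions")
  cat(sprintf("niche classification of %d OTUs: %.1f%% generalists, %.1f%% specialists, %.1f%% neutral\n",
              nrow(x), 100 * pr[["generalist"]], 100 * pr[["specialist"]],
              100 * pr[["neutral"]]))
  invisible(x)
}

#' Richness by niche category with a Kruskal-Wallis test
#'
#' Per-sample observed richness within each classified subcommunity
#' (generalists, specialists, neutral) plus the overall community, compared
#' across the four groups with the Kruskal-Wallis rank-sum test. Categories
#' with zero OTUs are omitted with a warning.
#'
#' @param table an [otu_table()].
#' @param classification a [classify_taxa()] result.
#' @return list with `richness` (data.frame sample x group, long format),
#'   `statistic` (KW H), `p_value`, `df`.
#' @export
group_richness_test <- function(table, classification) {
  groups <- list(overall = classification$otu_id)
  for (cl in c("generalist", "specialist", "neutral")) {
    ids <- classification$otu_id[classification$category == cl]
    if (length(ids) == 0) {
      warning(sprintf("category '%s' has zero OTUs; omitted", cl), call. = FALSE)
    } else groups[[cl]] <- ids
  }
  rich <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(sample_id = rownames(table), group = g,
               richness = sample_richness(table, groups[[g]]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (var(rich$richness) == 0) {
    # total ties: no rank variation, H is 0 by convention
    return(list(richness = rich, statistic = 0, p_value = 1,
                df = length(groups) - 1L))
  }
  kw <- kruskal.test(richness ~ factor(group), data = rich)
  list(richness = rich, statistic = unname(kw$statistic),
       p_value = kw$p.value, df = unname(kw$parameter))
}
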