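# Shared fixtures, built in code and cached for the test run.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# standard small structured community (24 samples, 200 OTUs)
small_sim <- function(seed = 1) {
  memo(paste0("sim", seed),
       suppressWarnings(simulate_structured_table(fixture_scenario(seed))))
}

small_tree <- function(seed = 1, signal = 1, n = 200) {
  memo(paste0("tree", seed, "_", signal, "_", n),
       simulate_phylogeny(n, signal, seed))
}

# tiny hand-checkable table
toy_table <- function() {
  otu_table(matrix(c(5L, 3L, 2L, 0L, 0L, 10L, 4L, 4L, 4L), nrow = 3,
                   dimnames = list(paste0("S", 1:3),
                                   c("OTU_spread", "OTU_point", "OTU_even"))))
}

# exhaustive C-score oracle: direct pairwise checkerboard-unit enumeration
c_score_bruteforce <- function(pa) {
  n <- nrow(pa)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sum(pa[i, ] & pa[j, ])
    tot <- tot + (sum(pa[i, ]) - s) * (sum(pa[j, ]) - s)
  }
  tot / choose(n, 2)
}
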