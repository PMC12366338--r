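#' PCNM spatial eigenvectors from quadrat coordinates
#'
#' Principal coordinates of neighbour matrices: the Euclidean distance
#' matrix is truncated (distances beyond the threshold replaced by 4x the
#' threshold), double-centred, and eigendecomposed; axes with positive
#' eigenvalues are retained and scaled by the square root of their
#' eigenvalue. The default truncation threshold is the longest edge of the
#' minimum spanning tree of the points, which keeps the neighbour graph
#' connected; on a regular grid this equals the grid spacing.
#'
#' @param coords data.frame or matrix with `x`, `y` columns (>= 3 distinct
#'   points).
#' @param truncation optional truncation distance in metres.
#' @return a `pcnm_result` list: `vectors` (samples x axes, columns
#'   `PCNM1`...), `values` (positive eigenvalues), `threshold`.
#' @export
pcnm_eigenvectors <- function(coords, truncation = NULL) {
  xy <- as.matrix(as.data.frame(coords)[, c("x", "y")])
  assert_that(nrow(xy) >= 3, "need at least 3 points")
  assert_that(!anyDuplicated(xy), "duplicate coordinates")
  d <- dist(xy)
  res <- if (is.null(truncation)) vegan::pcnm(d) else vegan::pcnm(d, threshold = truncation)
  v <- sweep(res$vectors, 2L, sqrt(res$values[seq_len(ncol(res$vectors))]), "*")
  rownames(v) <- if (!is.null(rownames(coords))) rownames(coords) else
    as.character(seq_len(nrow(xy)))
  structure(list(vectors = v,
                 values = res$values[res$values > 0],
                 threshold = res$threshold),
            class = "pcnm_result")
}

#' Forward selection of spatial (or other) predictors
#'
#' Greedy forward selection on linear-model R^2, guarded by a global test
#' and the double stopping rule. Selection only starts if the full-candidate
#' model itself passes a permutation test of its R^2 (otherwise the result
#' is an empty, valid selection); at each step the candidate with the
#' largest R^2 increase is tested by permuting the response (`n_perm`
#' permutations), and the procedure stops when that p-value exceeds `alpha`
#' or when the cumulative adjusted R^2 exceeds the adjusted R^2 of the
#' full-candidate model. Ties between candidates break by column index, so
#' the selection does not depend on candidate ordering.
#'
#' @param vectors numeric matrix of candidate predictors (e.g.
#'   `pcnm_result$vectors`).
#' @param response numeric response aligned to the rows.
#' @param alpha per-step significance level (default 0.05).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return a `forward_selection` list: `selected` (column indices, in
#'   selection order), `names`, `steps` (data.frame with R2, cumulative R2,
#'   adjusted R2, p), `global_p`, `full_adj_r2`, `r_squared` of the
#'   selected set.
#' @export
forward_select <- function(vectors, response, alpha = 0.05, n_perm = 999,
                           seed = 1L) {
  v <- as.matrix(vectors)
  y <- as.numeric(response)
  assert_that(nrow(v) == length(y), "vectors and response must be aligned")
  n <- length(y)
  set.seed(as.integer(seed))
  adj <- function(r2, k) 1 - (1 - r2) * (n - 1) / (n - k - 1)
  r2_of <- function(cols, yy) {
    fit <- lm.fit(cbind(1, v[, cols, drop = FALSE]), yy)
    1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
  }
  full_r2 <- r2_of(seq_len(ncol(v)), y)
  full_adj <- adj(full_r2, ncol(v))
  null_full <- vapply(seq_len(n_perm), function(b)
    r2_of(seq_len(ncol(v)), y[sample.int(n)]), numeric(1))
  global_p <- (sum(null_full >= full_r2) + 1) / (n_perm + 1)
  selected <- integer(0)
  steps <- NULL
  while (global_p <= alpha) {
    remaining <- setdiff(seq_len(ncol(v)), selected)
    if (length(remaining) == 0) break
    base_r2 <- if (length(selected)) r2_of(selected, y) else 0
    gains <- vapply(remaining, function(j) r2_of(c(selected, j), y) - base_r2,
                    numeric(1))
    best <- remaining[which.max(gains)] # which.max takes the first = lowest index
    gain <- max(gains)
    null_gain <- vapply(seq_len(n_perm), function(b) {
      yp <- y[sample.int(n)]
      bb <- if (length(selected)) r2_of(selected, yp) else 0
      r2_of(c(selected, best), yp) - bb
    }, numeric(1))
    p <- (sum(null_gain >= gain) + 1) / (n_perm + 1)
    if (p > alpha) break
    cand <- c(selected, best)
    cum_r2 <- r2_of(cand, y)
    cum_adj <- adj(cum_r2, length(cand))
    selected <- cand
    steps <- rbind(steps, data.frame(axis = best, r2_gain = gain,
                                     cum_r2 = cum_r2, cum_adj_r2 = cum_adj,
                                     p_value = p))
    # second stopping rule: once the selected model's adjusted R2 reaches the
    # full-candidate ceiling, further axes can only fit noise
    if (cum_adj > full_adj) break
  }
  structure(list(selected = selected,
                 names = colnames(v)[selected],
                 steps = steps, global_p = global_p, full_adj_r2 = full_adj,
                 r_squared = if (length(selected)) r2_of(selected, y) else 0),
            class = "forward_selection")
}

#' Moran's I spatial autocorrelation (binary neighbour weights)
#'
#' Utility used to verify that simulated environmental fields are spatially
#' structured: Moran's I of `z` with neighbours defined as points within
#' `neighbour_dist`.
#'
#' @param z numeric values per point.
#' @param coords data.frame with `x`, `y`.
#' @param neighbour_dist neighbourhood radius.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(z, coords, neighbour_dist) {
  d <- as.matrix(dist(as.data.frame(coords)[, c("x", "y")]))
  w <- (d > 0 & d <= neighbour_dist) * 1
  zc <- z - mean(z)
  n <- length(z)
  (n / sum(w)) * sum(w * outer(zc, zc)) / sum(zc^2)
}
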