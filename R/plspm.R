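#' Specify a PLS path model
#'
#' A model is a set of named indicator blocks (each measured reflectively by
#' one or more observed variables) and a directed acyclic inner path graph
#' among the latent variables, ending at the response. The default mirrors a
#' forest-plot richness model: spatial eigenvectors (`pcnm` = PC2, PC3),
#' `plant` (BA, DEN), `light` (CC, SR, LT) and `topography` (ASP) blocks,
#' with light and plant also mediating the spatial and topographic effects
#' on richness.
#'
#' @param blocks named list: indicator column names per latent variable. The
#'   response latent must be included (typically single-indicator).
#' @param paths data.frame with `from`, `to` latent names (a DAG).
#' @param response name of the response latent (default last block).
#' @return a `path_model_spec` list.
#' @export
path_model_spec <- function(blocks, paths, response = names(blocks)[length(blocks)]) {
  assert_that(all(c(paths$from, paths$to) %in% names(blocks)),
              "paths refer to unknown blocks")
  lat <- names(blocks)
  b <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  for (k in seq_len(nrow(paths))) b[paths$to[k], paths$from[k]] <- 1
  # acyclicity: nilpotence of the adjacency
  p <- b; for (i in seq_along(lat)) p <- p %*% b
  assert_that(all(p == 0), "inner path graph must be acyclic")
  reach <- b
  for (i in seq_along(lat)) reach <- (reach + reach %*% b) > 0
  exo <- setdiff(lat, c(response, paths$to))
  assert_that(all(reach[response, exo] > 0 | b[response, exo] > 0),
              "response must be reachable from every exogenous block")
  structure(list(blocks = blocks, paths = paths, response = response,
                 adjacency = b), class = "path_model_spec")
}

#' @rdname path_model_spec
#' @export
default_path_spec <- function() {
  path_model_spec(
    blocks = list(pcnm = c("PC2", "PC3"), topography = "ASP",
                  light = c("CC", "SR", "LT"), plant = c("BA", "DEN"),
                  richness = "richness"),
    paths = data.frame(
      from = c("pcnm", "topography", "pcnm", "topography",
               "pcnm", "topography", "light", "plant"),
      to = c("light", "light", "plant", "plant",
             "richness", "richness", "richness", "richness"),
      stringsAsFactors = FALSE))
}

#' Fit a PLS path model (Lohmoeller algorithm)
#'
#' Indicators are standardized; outer weights start equal and are iterated:
#' latent scores are formed from the current weights, inner estimates from
#' the chosen scheme (`"path"`: regression coefficients on predecessors and
#' correlations with successors; `"centroid"`: correlation signs), and
#' outer weights updated in mode A (correlation of each indicator with its
#' block's inner estimate), until the largest weight change falls below
#' `tol`. Path coefficients are then ordinary least squares of each
#' endogenous latent on its predecessors; effects are decomposed along all
#' directed paths (total = direct + indirect), and the goodness of fit is
#' `GoF = sqrt(mean communality x mean R^2)` over all indicators and
#' endogenous latents.
#'
#' @param data data.frame containing every indicator column.
#' @param spec a [path_model_spec()].
#' @param scheme inner estimation scheme, `"path"` (default) or
#'   `"centroid"`.
#' @param tol convergence tolerance on outer weights (default 1e-6).
#' @param max_iter maximum iterations (default 300).
#' @param n_boot bootstrap resamples for path-coefficient intervals
#'   (default 0 = none).
#' @param seed seed for the bootstrap.
#' @return a `path_model_result` list: `outer_weights`, `loadings`,
#'   `scores`, `path_coefficients` (matrix to x from), `r_squared`,
#'   `effects` (data.frame from, to, direct, indirect, total), `gof`,
#'   `iterations`, and optionally `boot` (percentile intervals).
#' @export
fit_plspm <- function(data, spec, scheme = c("path", "centroid"),
                      tol = 1e-6, max_iter = 300, n_boot = 0, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(spec, "path_model_spec"))
  ind <- unlist(spec$blocks, use.names = FALSE)
  assert_that(all(ind %in% names(data)),
              paste("missing indicators:", paste(setdiff(ind, names(data)), collapse = ", ")))
  df <- as.data.frame(data)[, ind, drop = FALSE]
  ok <- complete.cases(df)
  if (!all(ok)) {
    warning(sprintf("dropping %d row(s) with missing indicators", sum(!ok)),
            call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  core <- plspm_core(df, spec, scheme, tol, max_iter)
  out <- c(core, list(spec = spec, scheme = scheme))
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    lat <- names(spec$blocks)
    n_paths <- sum(spec$adjacency > 0)
    bstat <- replicate(n_boot, {
      i <- sample.int(nrow(df), replace = TRUE)
      b <- tryCatch(plspm_core(df[i, , drop = FALSE], spec, scheme, tol, max_iter),
                    error = function(e) NULL)
      if (is.null(b)) rep(NA_real_, n_paths) else
        b$path_coefficients[spec$adjacency > 0]
    })
    bstat <- matrix(bstat, nrow = n_paths)
    ci <- apply(bstat, 1L, quantile, c(0.025, 0.975), na.rm = TRUE)
    ci <- matrix(ci, nrow = 2)
    idx <- which(spec$adjacency > 0, arr.ind = TRUE)
    out$boot <- data.frame(from = lat[idx[, 2]], to = lat[idx[, 1]],
                           estimate = core$path_coefficients[spec$adjacency > 0],
                           lower = ci[1, ], upper = ci[2, ],
                           stringsAsFactors = FALSE)
  }
  class(out) <- "path_model_result"
  out
}

plspm_core <- function(df, spec, scheme, tol, max_iter) {
  blocks <- spec$blocks
  lat <- names(blocks)
  n <- nrow(df)
  x <- lapply(blocks, function(cols) {
    m <- scale(as.matrix(df[, cols, drop = FALSE]))
    assert_that(all(is.finite(m)), "constant indicator (zero variance)")
    m
  })
  adj <- spec$adjacency                 # adj[to, from] = 1
  conn <- (adj + t(adj)) > 0
  w <- lapply(x, function(m) rep(1, ncol(m)))
  score_of <- function(w) {
    y <- vapply(lat, function(b) as.numeric(x[[b]] %*% w[[b]]), numeric(n))
    scale(y)
  }
  y <- score_of(w)
  iter <- 0
  repeat {
    iter <- iter + 1
    # inner estimation
    e <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
    if (scheme == "centroid") {
      r <- cor(y)
      e[conn] <- sign(r[conn])
    } else {
      for (b in lat) {
        pred <- lat[adj[b, ] > 0]
        succ <- lat[adj[, b] > 0]
        if (length(pred))
          e[b, pred] <- coef(lm.fit(cbind(1, y[, pred, drop = FALSE]), y[, b]))[-1]
        if (length(succ)) e[b, succ] <- cor(y[, succ, drop = FALSE], y[, b])
      }
    }
    z <- scale(y %*% t(e))
    # outer mode A update
    w_new <- lapply(lat, function(b) as.numeric(cor(x[[b]], z[, b])))
    names(w_new) <- lat
    y_new <- score_of(w_new)
    # resolve sign indeterminacy: align each score with its block mean indicator
    for (b in lat) {
      s <- sign(sum(cor(x[[b]], y_new[, b])))
      if (s < 0) { w_new[[b]] <- -w_new[[b]]; y_new[, b] <- -y_new[, b] }
    }
    delta <- max(abs(unlist(w_new) / sqrt(sum(unlist(w_new)^2)) -
                     unlist(w) / sqrt(sum(unlist(w)^2))))
    w <- w_new; y <- y_new
    if (delta < tol) break
    assert_that(iter < max_iter,
                sprintf("no convergence in %d iterations (last weight change %.3g)",
                        max_iter, delta))
  }
  # path coefficients by OLS of endogenous latents on predecessors
  bmat <- matrix(0, length(lat), length(lat), dimnames = list(lat, lat))
  r2 <- setNames(rep(NA_real_, length(lat)), lat)
  for (b in lat) {
    pred <- lat[adj[b, ] > 0]
    if (length(pred) == 0) next
    fit <- lm.fit(cbind(1, y[, pred, drop = FALSE]), y[, b])
    bmat[b, pred] <- coef(fit)[-1]
    r2[b] <- 1 - sum(fit$residuals^2) / sum((y[, b] - mean(y[, b]))^2)
  }
  loadings <- lapply(lat, function(b) as.numeric(cor(x[[b]], y[, b])))
  names(loadings) <- lat
  communality <- unlist(loadings)^2
  gof <- sqrt(mean(communality) * mean(r2, na.rm = TRUE))
  # effects: total = sum of coefficient products over all directed paths
  total <- solve(diag(length(lat)) - bmat) - diag(length(lat))
  dimnames(total) <- dimnames(bmat)
  resp <- spec$response
  eff <- data.frame(from = setdiff(lat, resp), to = resp,
                    stringsAsFactors = FALSE)
  eff$direct <- bmat[resp, eff$from]
  eff$total <- total[resp, eff$from]
  eff$indirect <- eff$total - eff$direct
  eff <- eff[, c("from", "to", "direct", "indirect", "total")]
  list(outer_weights = w, loadings = loadings, scores = y,
       path_coefficients = bmat, r_squared = r2[!is.na(r2)],
       effects = eff, gof = gof, iterations = iter)
}

#' @export
print.path_model_result <- function(x, ...) {
  cat(sprintf("PLS path model (%s scheme), %d iterations, GoF = %.3f\n",
              x$scheme, x$iterations, x$gof))
  print(x$effects, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Percentage effect shares per block
#'
#' Each block's absolute direct and total effect on the response expressed
#' as a percentage of the sum of absolute total effects, with signs
#' reported separately.
#'
#' @param result a [fit_plspm()] result.
#' @return data.frame: `from`, `direct_share`, `total_share` (percent),
#'   `direct_sign`, `total_sign`.
#' @export
effect_shares <- function(result) {
  eff <- result$effects
  denom <- sum(abs(eff$total))
  assert_that(denom > 0, "all total effects are zero; shares undefined")
  data.frame(from = eff$from,
             direct_share = 100 * abs(eff$direct) / denom,
             total_share = 100 * abs(eff$total) / denom,
             direct_sign = sign(eff$direct), total_sign = sign(eff$total),
             stringsAsFactors = FALSE)
}

#' Fit the path model separately per subcommunity richness
#'
#' One fit per response column (e.g. generalist, specialist, neutral
#' richness); responses with zero variance are skipped with a warning. The
#' comparison table holds one row per successful fit and block.
#'
#' @param responses data.frame of response columns (rows aligned to `data`).
#' @param data data.frame of indicators.
#' @param spec a [path_model_spec()] whose response block has a single
#'   indicator; that indicator is replaced by each response in turn.
#' @param ... passed to [fit_plspm()].
#' @return list with `fits` (named list of results) and `comparison`
#'   (data.frame response x block effects and GoF).
#' @export
fit_per_subcommunity <- function(responses, data, spec, ...) {
  fits <- list()
  rows <- NULL
  for (nm in names(responses)) {
    y <- responses[[nm]]
    if (var(y, na.rm = TRUE) == 0) {
      warning(sprintf("response '%s' is constant; skipped", nm), call. = FALSE)
      next
    }
    d <- data
    d[[spec$blocks[[spec$response]][1]]] <- y
    fit <- fit_plspm(d, spec, ...)
    fits[[nm]] <- fit
    eff <- fit$effects
    rows <- rbind(rows, data.frame(response = nm, from = eff$from,
                                   direct = eff$direct, indirect = eff$indirect,
                                   total = eff$total, gof = fit$gof,
                                   stringsAsFactors = FALSE))
  }
  list(fits = fits, comparison = rows)
}

#' Simulate indicator data with known path effects on richness
#'
#' Generates standardized latent variables per block on a spatial grid (one
#' spatially autocorrelated factor per block, shared by its indicators with
#' loading 0.9) and a response built as the stated linear combination of the
#' block latents plus noise. Used to verify that [fit_plspm()] recovers
#' planted path coefficients.
#'
#' @param coords data.frame from [grid_coordinates()].
#' @param effects named vector of true block -> response coefficients, names
#'   among `pcnm`, `topography`, `light`, `plant`.
#' @param noise_sd residual standard deviation of the response.
#' @param seed integer seed.
#' @return data.frame of indicators (`PC2`, `PC3`, `ASP`, `CC`, `SR`, `LT`,
#'   `BA`, `DEN`) plus `richness`, with attribute `latents`.
#' @export
simulate_path_data <- function(coords, effects = c(light = -0.4, pcnm = 0.4,
                                                   plant = 0.15, topography = 0.1),
                               noise_sd = 0.6, seed = 1L) {
  set.seed(as.integer(seed))
  blocks <- list(pcnm = c("PC2", "PC3"), topography = "ASP",
                 light = c("CC", "SR", "LT"), plant = c("BA", "DEN"))
  n <- nrow(coords)
  lv <- vapply(names(blocks), function(b) {
    as.numeric(scale(gaussian_field(coords, 60)))
  }, numeric(n))
  out <- coords
  for (b in names(blocks)) for (v in blocks[[b]])
    out[[v]] <- 0.9 * lv[, b] + sqrt(1 - 0.81) * rnorm(n)
  yy <- as.numeric(lv %*% effects[colnames(lv)]) + rnorm(n, 0, noise_sd)
  out$richness <- as.numeric(scale(yy))
  attr(out, "latents") <- lv
  out
}
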