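#' Fit the Sloan neutral community model
#'
#' Relates each OTU's occurrence frequency (fraction of samples where it is
#' detected) to its mean relative abundance `p`. Under neutral immigration
#' with migration rate `m` and local community size `N`, the predicted
#' frequency is `f_pred(p) = 1 - I_d(N m p, N m (1 - p))`, the upper tail of
#' a Beta distribution at the detection limit `d`. The default is
#' `log(2)/N`: under multinomial sampling at depth `N` an OTU with true
#' relative abundance `a` is detected with probability `1 - (1 - a)^N`, and
#' `log(2)/N` is the abundance at which that probability crosses one half -
#' the effective hard detection limit of count data (`1/N`, the smallest
#' observable relative abundance, is available via `detection_limit`). The single free parameter `m` is
#' estimated by nonlinear least squares; fit quality is the
#' coefficient of determination `R^2 = 1 - SSE / SST` (which may be negative
#' on strongly non-neutral data). A 95% envelope around the fitted curve
#' uses Wilson binomial intervals with `n = n_samples`, and each OTU is
#' placed above / within / below it.
#'
#' @param table an [otu_table()] with >= 10 OTUs.
#' @param detection_limit relative-abundance detection limit `d`;
#'   default `log(2)/N` with `N` the mean read depth.
#' @return an `ncm_fit` list: `m`, `N`, `Nm`, `r_squared`, `detection_limit`,
#'   and `otu` (per-OTU `p`, `freq_obs`, `freq_pred`, `lower`, `upper`,
#'   `position`).
#' @export
fit_sloan_ncm <- function(table, detection_limit = NULL) {
  x <- unclass_table(table)
  assert_that(ncol(x) >= 10, "need at least 10 OTUs to fit the neutral model")
  n_samples <- nrow(x)
  n_reads <- mean(rowSums(x))
  p <- colMeans(x / rowSums(x))
  f_obs <- colMeans(x > 0)
  d <- detection_limit %||% (log(2) / n_reads)
  sst <- sum((f_obs - mean(f_obs))^2)
  assert_that(sst > 0, "all OTUs have identical occurrence frequency; R^2 undefined")

  cf <- fit_sloan_curve(p, f_obs, n_reads, d)
  m <- cf$m
  f_pred <- cf$freq_pred
  r2 <- cf$r_squared
  # Wilson score interval around the predicted frequency, n = sample count
  z <- 1.959964
  centre <- (f_pred + z^2 / (2 * n_samples)) / (1 + z^2 / n_samples)
  half <- z * sqrt(f_pred * (1 - f_pred) / n_samples + z^2 / (4 * n_samples^2)) /
    (1 + z^2 / n_samples)
  lower <- pmax(0, centre - half)
  upper <- pmin(1, centre + half)
  position <- ifelse(f_obs > upper, "above",
                     ifelse(f_obs < lower, "below", "within"))
  structure(list(
    m = m, N = n_reads, Nm = n_reads * m, r_squared = r2, detection_limit = d,
    otu = data.frame(otu_id = colnames(x), p = p, freq_obs = f_obs,
                     freq_pred = f_pred, lower = lower, upper = upper,
                     position = position, row.names = NULL,
                     stringsAsFactors = FALSE)
  ), class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral community model: m = %.4g, Nm = %.4g, R^2 = %.3f\n",
              x$m, x$Nm, x$r_squared))
  cat(sprintf("  %.1f%% of OTUs within the 95%% envelope\n",
              100 * mean(x$otu$position == "within")))
  invisible(x)
}


#' Fit the Sloan occurrence-frequency curve to (abundance, frequency) pairs
#'
#' The curve-level workhorse behind [fit_sloan_ncm()], usable directly on
#' mean relative abundances `p` and occurrence frequencies `freq` (e.g. for
#' self-consistency checks on noiseless input). Estimates `m` by nonlinear
#' least squares with a log-spaced grid start.
#'
#' @param p mean relative abundances.
#' @param freq occurrence frequencies in `[0, 1]`.
#' @param n_reads community size `N`.
#' @param detection_limit detection threshold `d`.
#' @return list with `m`, `freq_pred`, `r_squared`.
#' @export
fit_sloan_curve <- function(p, freq, n_reads, detection_limit) {
  d <- detection_limit
  pred <- function(m) pbeta(d, n_reads * m * p, n_reads * m * (1 - p),
                            lower.tail = FALSE)
  sse_of <- function(m) sum((freq - pred(m))^2)
  grid <- 10^seq(-4, 2, length.out = 25)
  m0 <- grid[which.min(vapply(grid, sse_of, numeric(1)))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      freq ~ pbeta(d, n_reads * m * p, n_reads * m * (1 - p), lower.tail = FALSE),
      start = list(m = m0), lower = 1e-9, upper = 1e6,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      prof <- data.frame(m = grid, sse = vapply(grid, sse_of, numeric(1)))
      stop(paste0("neutral model fit did not converge; SSE profile:\n",
                  paste(sprintf("  m = %.2e  SSE = %.4g", prof$m, prof$sse),
                        collapse = "\n")), call. = FALSE)
    })
  m <- coef(fit)[["m"]]
  sst <- sum((freq - mean(freq))^2)
  list(m = m, freq_pred = pred(m),
       r_squared = if (sst > 0) 1 - sse_of(m) / sst else NA_real_)
}
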