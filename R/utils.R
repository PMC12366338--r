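#' @useDynLib nicheassembly, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cophenetic kruskal.test lm p.adjust pbeta pt quantile
#'   rbinom rlnorm rmultinom rnorm runif sd var rbeta setNames complete.cases
#'   coef resid dist
#' @importFrom utils read.delim write.table head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the master seed and the stage name, so that stages can be re-run in
#' isolation and still reproduce the pipeline run bit-for-bit.
#'
#' @param seed master integer seed.
#' @param stage character stage tag.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
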