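#' Define a synthetic community scenario
#'
#' Bundles the design of a simulated survey: a regular quadrat grid, a read
#' depth, and the numbers of planted habitat generalists and specialists.
#' Defaults emulate a 120-quadrat forest plot survey (12 x 10 quadrats at
#' 20 m spacing) sequenced to 10^4 reads per sample, with 1000 OTUs of which
#' 100 are planted generalists and 300 planted specialists.
#'
#' @param n_otus number of OTUs.
#' @param n_generalists,n_specialists planted class sizes; the remainder are
#'   background taxa with intermediate environmental filtering.
#' @param grid_shape integer pair, quadrat grid dimensions.
#' @param grid_spacing quadrat spacing in metres.
#' @param community_size reads per sample.
#' @param migration_rate_m Sloan migration rate for neutral scenarios.
#' @param sigma_niche Gaussian niche width of specialists on the standardized
#'   latent gradient; the default gives specialists ~10-20% occupancy.
#' @param sigma_background niche width of background taxa.
#' @param env_effect_sizes named numeric vector of true path coefficients
#'   used by [simulate_environment()]-driven responses (see
#'   [simulate_path_data()]).
#' @param seed integer master seed; all randomness flows from it.
#' @return a `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_otus = 1000, n_generalists = 100,
                               n_specialists = 300,
                               grid_shape = c(12L, 10L), grid_spacing = 20,
                               community_size = 10000,
                               migration_rate_m = 0.1,
                               sigma_niche = 0.10, sigma_background = 1.2,
                               env_effect_sizes = c(light = -0.4, pcnm = 0.4,
                                                    plant = 0.15, topography = 0.1),
                               seed = 1L) {
  n_samples <- prod(grid_shape)
  assert_that(n_generalists + n_specialists <= n_otus,
              "n_generalists + n_specialists exceeds n_otus")
  assert_that(community_size > 0, "community_size must be a positive integer")
  assert_that(n_samples > 0, "grid_shape must have positive product")
  structure(list(
    n_otus = as.integer(n_otus), n_generalists = as.integer(n_generalists),
    n_specialists = as.integer(n_specialists),
    grid_shape = as.integer(grid_shape), grid_spacing = grid_spacing,
    n_samples = as.integer(n_samples), community_size = as.integer(community_size),
    migration_rate_m = migration_rate_m, sigma_niche = sigma_niche,
    sigma_background = sigma_background,
    env_effect_sizes = env_effect_sizes, seed = as.integer(seed)
  ), class = "synthetic_scenario")
}

#' Quadrat grid coordinates
#' @param shape integer pair (columns, rows).
#' @param spacing spacing in metres.
#' @return data.frame with `sample_id`, `x`, `y`.
#' @export
grid_coordinates <- function(shape = c(12L, 10L), spacing = 20) {
  g <- expand.grid(ix = seq_len(shape[1]), iy = seq_len(shape[2]))
  data.frame(sample_id = sprintf("S%03d", seq_len(nrow(g))),
             x = (g$ix - 1) * spacing, y = (g$iy - 1) * spacing)
}

# One Gaussian random field with exponential covariance on given coordinates.
gaussian_field <- function(coords, range, jitter = 1e-8) {
  d <- as.matrix(dist(coords[, c("x", "y")]))
  if (range <= 0) return(rnorm(nrow(d)))
  sigma <- exp(-d / range)
  l <- chol(sigma + diag(jitter, nrow(sigma)))
  as.numeric(crossprod(l, rnorm(nrow(d))))
}

#' Simulate spatially autocorrelated environmental covariates
#'
#' One Gaussian random field per indicator with exponential covariance
#' (`exp(-d / autocorr_range)`). Default indicators mirror a forest-plot
#' survey: a light block (canopy cover CC, scattered radiation SR, light
#' transmittance LT), a plant block (basal area BA, stand density DEN), and a
#' topography block (aspect ASP). With `autocorr_range <= 0` the fields are
#' white noise (with a warning).
#'
#' @param coords data.frame with `sample_id`, `x`, `y` (see
#'   [grid_coordinates()]).
#' @param blocks named list of character vectors: indicator names per block.
#' @param autocorr_range correlation range in metres.
#' @param seed integer seed.
#' @return a metadata data.frame (`sample_id`, `x`, `y`, indicators) with a
#'   `blocks` attribute.
#' @export
simulate_environment <- function(coords,
                                 blocks = list(light = c("CC", "SR", "LT"),
                                               plant = c("BA", "DEN"),
                                               topography = "ASP"),
                                 autocorr_range = 60, seed = 1L) {
  assert_that(!anyDuplicated(coords[, c("x", "y")]), "coordinates must be distinct")
  if (autocorr_range <= 0) warning("autocorr_range <= 0: fields are white noise",
                                   call. = FALSE)
  set.seed(seed)
  out <- coords
  for (b in names(blocks)) {
    for (v in blocks[[b]]) out[[v]] <- gaussian_field(coords, autocorr_range)
  }
  attr(out, "blocks") <- blocks
  out
}

#' Simulate a phylogeny with tunable phylogenetic signal in habitat optima
#'
#' A Yule (pure-birth) topology with branch lengths; environmental optima
#' evolve by Brownian motion along the branches. `signal_strength` blends the
#' Brownian values with a random shuffle of themselves: at 1 the optima carry
#' full phylogenetic signal, at 0 they are independent of the tree (while
#' keeping the same marginal distribution).
#'
#' @param n_otus number of tips (>= 2).
#' @param signal_strength real in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `tree` (ape `phylo`, tip labels `OTU0001`...) and
#'   `optima` (named numeric).
#' @export
simulate_phylogeny <- function(n_otus, signal_strength = 1, seed = 1L) {
  assert_that(n_otus >= 2, "a phylogeny needs at least 2 tips")
  assert_that(signal_strength >= 0 && signal_strength <= 1,
              "signal_strength must lie in [0, 1]")
  set.seed(seed)
  tree <- ape::rphylo(n_otus, birth = 1, death = 0)
  tree$tip.label <- sprintf("OTU%04d", seq_len(n_otus))
  bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  optima <- signal_strength * bm + (1 - signal_strength) * sample(bm)
  names(optima) <- tree$tip.label
  list(tree = tree, optima = optima)
}

#' Simulate an environmentally structured community with known ground truth
#'
#' Builds a sample-by-OTU count table on the scenario's quadrat grid.
#' Specialists are filtered by a Gaussian kernel
#' `exp(-(g - optimum)^2 / (2 sigma^2))` on a spatially autocorrelated latent
#' gradient `g` (standardized to unit variance), so they occupy a patchy
#' subset of quadrats. Background taxa feel the same kernel with a much
#' wider `sigma`. Planted generalists hold a constant expected share in every
#' sample with sub-multinomial (buffered) variance, i.e. their across-sample
#' evenness exceeds what random placement of the same number of reads would
#' give - which is precisely the signature a marginal-preserving permutation
#' test can detect. Per-sample counts are completed multinomially so that
#' every row sums exactly to `community_size`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param optima optional numeric vector of environmental optima for all
#'   OTUs, e.g. from [simulate_phylogeny()]; when supplied it overrides the
#'   random optima and its names (if any) must cover the planted OTUs.
#' @param scale_optima standardize supplied optima onto the gradient scale
#'   (default); set `FALSE` when they are already expressed as gradient
#'   values.
#' @param gradient_range autocorrelation range of the latent gradient, in
#'   metres.
#' @param generalist_cv coefficient of variation of the planted generalists'
#'   per-sample share (the "buffering" noise).
#' @param overdispersion_sd lognormal standard deviation of multiplicative
#'   per-cell noise on the filtered (specialist and background) taxa,
#'   emulating the strong overdispersion of real amplicon counts.
#' @return list with `table` ([otu_table()]), `truth` (data.frame `otu_id`,
#'   `true_category`, `optimum`, `sigma`, `extinct`), and `metadata`
#'   (coordinates, the latent `gradient`, and environmental covariates).
#' @export
simulate_structured_table <- function(scenario, optima = NULL,
                                      scale_optima = TRUE,
                                      gradient_range = 60,
                                      generalist_cv = 0.05,
                                      overdispersion_sd = 0.8) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  assert_that(scenario$community_size > 0, "community_size must be positive")
  set.seed(derive_seed(scenario$seed, "structured"))
  n_s <- scenario$n_samples; n_o <- scenario$n_otus
  n_gen <- scenario$n_generalists; n_spec <- scenario$n_specialists
  n_bg <- n_o - n_gen - n_spec
  coords <- grid_coordinates(scenario$grid_shape, scenario$grid_spacing)

  g <- gaussian_field(coords, gradient_range)
  g <- as.numeric(scale(g))

  otu_ids <- sprintf("OTU%04d", seq_len(n_o))
  category <- rep(c("generalist", "specialist", "background"),
                  c(n_gen, n_spec, n_bg))
  sigma <- c(rep(Inf, n_gen), rep(scenario$sigma_niche, n_spec),
             rep(scenario$sigma_background, n_bg))

  if (is.null(optima)) {
    opt <- rep(NA_real_, n_o)
    # spread specialist optima across the realized gradient so each has support
    # type-1 quantiles are realized gradient values, so a point kernel
    # (sigma = 0) always has at least one matching quadrat
    if (n_spec > 0) opt[category == "specialist"] <-
      quantile(g, runif(n_spec, 0.02, 0.98), names = FALSE, type = 1)
    if (n_bg > 0) opt[category == "background"] <-
      quantile(g, runif(n_bg, 0.02, 0.98), names = FALSE, type = 1)
  } else {
    assert_that(length(optima) == n_o || !is.null(names(optima)),
                "optima must cover all OTUs")
    opt <- if (!is.null(names(optima))) unname(optima[otu_ids]) else optima
    if (scale_optima) opt <- as.numeric(scale(opt)) # map onto the gradient scale
  }

  # base abundances: planted classes moderately even lognormal, background a
  # long-tailed lognormal SAD; class budget shares of the community
  base <- numeric(n_o)
  base[category == "generalist"] <- rlnorm(n_gen, 0, 0.7)
  base[category == "specialist"] <- rlnorm(n_spec, 0, 0.7)
  base[category == "background"] <- rlnorm(n_bg, 0, 2)
  share <- c(generalist = 0.20, specialist = 0.40, background = 0.40)
  present <- c(generalist = n_gen, specialist = n_spec, background = n_bg) > 0
  share <- share[present] / sum(share[present])
  for (cl in names(share)) {
    idx <- category == cl
    base[idx] <- share[[cl]] * base[idx] / sum(base[idx])
  }

  # expected per-sample weights: Gaussian filtering for finite-sigma taxa
  w <- matrix(rep(base, each = n_s), n_s, n_o)
  filt <- which(is.finite(sigma))
  for (j in filt) {
    if (sigma[j] == 0) {
      k <- as.numeric(g == opt[j]) # point kernel; off-grid optimum -> all zero
    } else {
      k <- exp(-(g - opt[j])^2 / (2 * sigma[j]^2))
    }
    w[, j] <- w[, j] * k
  }
  if (overdispersion_sd > 0 && length(filt))
    w[, filt] <- w[, filt] *
      matrix(rlnorm(n_s * length(filt), 0, overdispersion_sd), n_s)

  depth <- scenario$community_size
  counts <- matrix(0L, n_s, n_o, dimnames = list(coords$sample_id, otu_ids))
  gen_idx <- which(category == "generalist")
  if (length(gen_idx)) {
    # buffered generalists: near-constant share, CV below multinomial noise
    gshare <- matrix(rep(base[gen_idx], each = n_s), n_s, length(gen_idx)) *
      exp(matrix(rnorm(n_s * length(gen_idx), 0, generalist_cv), n_s))
    counts[, gen_idx] <- round(depth * gshare)
  }
  rest <- setdiff(seq_len(n_o), gen_idx)
  for (i in seq_len(n_s)) {
    n_left <- depth - sum(counts[i, gen_idx])
    if (n_left < 0) { # buffering overshoot: trim the largest generalist
      jmax <- gen_idx[which.max(counts[i, gen_idx])]
      counts[i, jmax] <- counts[i, jmax] + n_left
      n_left <- 0
    }
    wi <- w[i, rest]
    if (sum(wi) > 0 && n_left > 0)
      counts[i, rest] <- rmultinom(1, n_left, wi)[, 1]
  }

  truth <- data.frame(otu_id = otu_ids, true_category = category,
                      optimum = opt, sigma = sigma,
                      extinct = colSums(counts) == 0,
                      stringsAsFactors = FALSE)
  metadata <- simulate_environment(coords, autocorr_range = gradient_range,
                                   seed = derive_seed(scenario$seed, "environment"))
  metadata$gradient <- g
  list(table = otu_table(counts), truth = truth, metadata = metadata)
}

#' Simulate a Sloan-neutral community table
#'
#' For each OTU with metacommunity relative abundance `p`, the local relative
#' abundance in each sample is drawn from the Sloan stationary approximation
#' `Beta(N m p, N m (1 - p))` with `N = community_size` and migration rate
#' `m`; the draws are renormalized within each sample and `N` reads are then
#' sampled multinomially. The resulting occurrence-frequency curve follows
#' the Sloan prediction with parameter `m`, which makes migration-rate
#' recovery by [fit_sloan_ncm()] a clean self-consistency check.
#'
#' @param scenario a [synthetic_scenario()]; uses `community_size`,
#'   `n_samples`, `migration_rate_m`, `seed`.
#' @param metacommunity_abundances probability vector over OTUs (sums to 1);
#'   default a lognormal(0, 2) species-abundance distribution over
#'   `scenario$n_otus` OTUs.
#' @return an [otu_table()] (OTUs with `p = 0` are absent everywhere and
#'   dropped with a warning).
#' @export
simulate_neutral_table <- function(scenario, metacommunity_abundances = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  assert_that(scenario$migration_rate_m > 0, "migration_rate_m must be > 0")
  set.seed(derive_seed(scenario$seed, "neutral"))
  n_o <- scenario$n_otus
  p <- metacommunity_abundances
  if (is.null(p)) { p <- rlnorm(n_o, 0, 2); p <- p / sum(p) }
  assert_that(abs(sum(p) - 1) < 1e-8, "metacommunity_abundances must sum to 1")
  zero <- p == 0
  if (any(zero)) warning(sprintf("%d OTU(s) with zero metacommunity frequency dropped",
                                 sum(zero)), call. = FALSE)
  n_s <- scenario$n_samples; depth <- scenario$community_size
  nm <- depth * scenario$migration_rate_m
  keep <- which(!zero)
  counts <- matrix(0L, n_s, length(p))
  for (i in seq_len(n_s)) {
    a <- rbeta(length(keep), nm * p[keep], nm * (1 - p[keep]))
    if (sum(a) == 0) a[] <- p[keep]
    counts[i, keep] <- rmultinom(1, depth, a)[, 1]
  }
  dimnames(counts) <- list(sprintf("S%03d", seq_len(n_s)),
                           sprintf("OTU%04d", seq_along(p)))
  otu_table(counts[, keep, drop = FALSE])
}
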