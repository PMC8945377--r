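# Synthetic partially coupled multi-omics generator.
#
# Linear-Gaussian factor model: modalities are linked through shared latent
# factors so that a present modality is informative about an absent one, and
# each modality carries its own class-dependent mean shift so that one
# modality can dominate predictiveness. This is the simplest generative model
# exhibiting both phenomena, and it admits closed-form oracles (see
# population_canonical_correlation()).

#' Configuration for the multi-omics simulator
#'
#' Samples are generated as `x_i = a_i * A_i u + y * beta_i + eps_i` where
#' `u ~ N(0, I_k)` are per-sample shared latent factors, `A_i` are fixed
#' loading matrices with unit-norm columns, `y` is the binary class label,
#' `beta_i` is a class mean-shift of norm `class_effect[i]`, and
#' `eps_i ~ N(0, noise_sd[i]^2 I)`.
#'
#' @param n_samples Number of samples.
#' @param dims Integer vector of per-modality feature counts (named, or named
#'   `m1...` by position).
#' @param latent_dim Number of shared latent factors `k`.
#' @param loadings_scale Per-modality coupling strength `a_i >= 0`: how strongly
#'   the shared factors drive the modality (0 = uncoupled).
#' @param noise_sd Per-modality Gaussian noise standard deviation (> 0).
#' @param class_effect Per-modality norm of the class mean-shift (>= 0); the
#'   per-feature shift direction is drawn once per seed.
#' @param prevalence Positive-class fraction in (0, 1). Exactly
#'   `round(prevalence * n_samples)` samples are positive (deterministic
#'   allocation, so imbalance scenarios are exactly reproducible).
#' @param seed Integer seed controlling loadings, shift directions, factors,
#'   noise and label placement.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_samples, dims, latent_dim = 1L,
                              loadings_scale = rep(1, length(dims)),
                              noise_sd = rep(1, length(dims)),
                              class_effect = rep(0, length(dims)),
                              prevalence = 0.5, seed = 1L) {
  if (any(dims < 1L)) stopf("all modality dims must be >= 1")
  if (latent_dim < 1L) stopf("`latent_dim` must be >= 1")
  if (length(loadings_scale) != length(dims) ||
      length(noise_sd) != length(dims) ||
      length(class_effect) != length(dims)) {
    stopf("loadings_scale, noise_sd and class_effect must match length(dims)")
  }
  if (any(loadings_scale < 0)) stopf("`loadings_scale` must be >= 0")
  if (any(noise_sd <= 0)) stopf("`noise_sd` must be > 0")
  if (any(class_effect < 0)) stopf("`class_effect` must be >= 0")
  assert_scalar_number(prevalence, "prevalence", 0, 1, strict = TRUE)
  if (is.null(names(dims))) names(dims) <- paste0("m", seq_along(dims))
  structure(
    list(n_samples = as.integer(n_samples), dims = dims,
         latent_dim = as.integer(latent_dim),
         loadings_scale = loadings_scale, noise_sd = noise_sd,
         class_effect = class_effect, prevalence = prevalence,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Shipped desk-scale simulation scenario
#'
#' A preset mimicking the structure of the motivating cancer cohorts at desk
#' scale: three modalities with the middle one widest (as DNA methylation is
#' in the TCGA matrices), strong m1–m2 coupling through four shared factors,
#' and the dominant class signal placed in m2 — the modality that the target
#' source is missing — so that inferring its latent representation from m1 is
#' exactly what pays off.
#'
#' @param n_samples Number of samples (default 400).
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
sim_preset <- function(n_samples = 400L, seed = 1L) {
  simulation_config(
    n_samples = n_samples,
    dims = c(m1 = 500L, m2 = 800L, m3 = 50L),
    latent_dim = 4L,
    loadings_scale = c(1, 1, 0.5),
    noise_sd = c(1, 1, 1),
    class_effect = c(0.5, 2.0, 0.5),
    prevalence = 0.5,
    seed = seed
  )
}

# Draw a d x k loading matrix with unit-norm columns.
draw_loadings <- function(d, k) {
  A <- matrix(stats::rnorm(d * k), d, k)
  sweep(A, 2L, sqrt(colSums(A^2)), "/")
}

#' Simulate a partially coupled multi-omics dataset
#'
#' Generates modalities from the linear-Gaussian factor model described in
#' [simulation_config()], with exactly `round(prevalence * n)` positive labels
#' placed at seeded random positions. Bitwise reproducible given the seed.
#'
#' @param config A [simulation_config()].
#' @return A list with `dataset` (a labeled [multiomics()]) and `truth`
#'   (loadings `A`, class shifts `beta`, latent scores `u`, labels `y`).
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  k <- config$latent_dim
  with_seed(config$seed, {
    n_pos <- round(config$prevalence * n)
    y <- integer(n)
    y[sample(n, n_pos)] <- 1L
    u <- matrix(stats::rnorm(n * k), n, k)
    ids <- sprintf("s%04d", seq_len(n))
    A <- list(); beta <- list(); mods <- list()
    for (i in seq_along(config$dims)) {
      d <- config$dims[[i]]
      nm <- names(config$dims)[i]
      A[[nm]] <- draw_loadings(d, k)
      dir <- stats::rnorm(d)
      beta[[nm]] <- dir / sqrt(sum(dir^2)) * config$class_effect[i]
      X <- config$loadings_scale[i] * (u %*% t(A[[nm]])) +
        outer(y, beta[[nm]]) +
        config$noise_sd[i] * matrix(stats::rnorm(n * d), n, d)
      dimnames(X) <- list(ids, sprintf("%s_f%04d", nm, seq_len(d)))
      mods[[nm]] <- modality_matrix(nm, X)
    }
    names(y) <- ids
    rownames(u) <- ids
    list(
      dataset = multiomics(mods, labels = y),
      truth = list(loadings = A, class_shift = beta, latent_scores = u,
                   labels = y)
    )
  })
}

#' Population canonical correlation of the generative model
#'
#' Closed-form first canonical correlation between two simulated modalities
#' under a single shared factor (`latent_dim = 1`) and no class effect:
#' the cross-covariance of `x_i` and `x_j` is the rank-one matrix
#' `a_i a_j A_i A_j'`, whose optimal directions are the loading vectors, giving
#' `r = a_i a_j / sqrt((a_i^2 + s_i^2)(a_j^2 + s_j^2))`. This is the analytic
#' oracle against which the empirical PLS diagnostic is checked.
#'
#' @param config A [simulation_config()] with `latent_dim = 1`.
#' @param i,j Modality names or indices.
#' @return The population first canonical correlation, in `[0, 1]`.
#' @export
population_canonical_correlation <- function(config, i = 1L, j = 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$latent_dim != 1L) {
    stopf("closed form implemented for latent_dim = 1 only; use the empirical PLS estimate for k > 1")
  }
  if (is.character(i)) i <- match(i, names(config$dims))
  if (is.character(j)) j <- match(j, names(config$dims))
  a_i <- config$loadings_scale[i]; a_j <- config$loadings_scale[j]
  s_i <- config$noise_sd[i]; s_j <- config$noise_sd[j]
  (a_i * a_j) / sqrt((a_i^2 + s_i^2) * (a_j^2 + s_j^2))
}
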