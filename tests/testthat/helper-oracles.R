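# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# study-like 5-taxon tree and a generic replicate layout
fix_tree <- function() fixture_tree()

fix_reps <- function(n = 8L) {
  tr <- fix_tree()
  stats::setNames(rep(as.integer(n), ape::Ntip(tr)), tr$tip.label)
}

fix_delta2 <- function(value = 0.4) {
  tr <- fix_tree()
  stats::setNames(rep(value, ape::Ntip(tr)), tr$tip.label)
}

# shortened MCMC schedules for simulation experiments
short_settings <- function(seed, iterations = 600L, burnin = 200L, thin = 6L) {
  mcmc_settings(burnin = burnin, tune_interval = 50L, iterations = iterations,
                thin = thin, seed = seed)
}

tiny_settings <- function(seed) {
  mcmc_settings(burnin = 100L, tune_interval = 50L, iterations = 300L,
                thin = 3L, seed = seed)
}

# Dense per-individual multivariate-normal oracle for the model likelihoods.
# Builds the full N x N covariance (phylogenetic block expanded to individuals
# plus the diagonal within-species variances) and evaluates the joint normal
# density directly: the full density for the means and OU-family models, the
# density of orthonormal within-tree contrasts (perpendicular to the ones
# vector) for the root-free BM family. Entirely independent of the compiled
# likelihood path.
dense_loglik_oracle <- function(spec, params, gene, tree) {
  species <- if (is.null(tree)) sort(names(gene$values)) else tree$tip.label
  vals <- gene$values[species]
  n <- vapply(vals, length, integer(1L))
  N <- sum(n)
  A <- matrix(0, N, length(species))
  idx <- rep(seq_along(species), n)
  for (i in seq_len(N)) A[i, idx[i]] <- 1
  z <- unlist(vals, use.names = FALSE)
  d <- params$delta2
  if (!is.null(names(d))) d <- d[species]
  Dz <- diag(rep(d, n), N)

  dmvn <- function(r, S, contrasts = FALSE) {
    if (contrasts) {
      K <- t(qr.Q(qr(matrix(1, length(r), 1)), complete = TRUE)[, -1])
      r <- K %*% r
      S <- K %*% S %*% t(K)
    }
    L <- chol((S + t(S)) / 2)
    -0.5 * length(r) * log(2 * pi) - sum(log(diag(L))) -
      0.5 * sum(backsolve(L, r, transpose = TRUE)^2)
  }

  mod <- spec$model
  if (mod %in% c("EQUAL_MEANS", "UNEQUAL_MEANS")) {
    mu <- if (mod == "EQUAL_MEANS") rep(params$mu, length(species))
          else { m <- params$mu_i; if (!is.null(names(m))) m <- m[species]; m }
    return(dmvn(z - A %*% mu, Dz))
  }
  if (mod %in% c("BM", "BM_SHIFT")) {
    rates <- rep(params$sigma2_B %||% params$sigma2, nrow(tree$edge))
    if (!is.null(spec$foreground)) {
      fgn <- match(spec$foreground, tree$tip.label)
      rates[tree$edge[, 2] == fgn] <- params$sigma2_F
    }
    V <- bm_tip_covariance(tree, rates)
    return(dmvn(z, A %*% V %*% t(A) + Dz, contrasts = TRUE))
  }
  mm <- ou_tip_moments(tree, params$sigma2 %||% params$sigma2_B, params$alpha,
                       params$theta %||% params$theta_B,
                       foreground = spec$foreground,
                       sigma2_F = params$sigma2_F, theta_F = params$theta_F)
  dmvn(z - A %*% mm$mean, A %*% mm$cov %*% t(A) + Dz)
}

# random parameter draw matching a model spec (for oracle sweeps)
random_params <- function(model, species, rng_scale = 1) {
  d2 <- stats::setNames(exp(stats::runif(length(species), -1.5, 0.5)), species)
  switch(model,
    EQUAL_MEANS   = model_params(mu = stats::rnorm(1, 3, 2), delta2 = d2),
    UNEQUAL_MEANS = model_params(mu_i = stats::setNames(stats::rnorm(length(species), 3, 2), species),
                                 delta2 = d2),
    BM            = model_params(sigma2 = exp(stats::runif(1, -2, 1)), delta2 = d2),
    BM_SHIFT      = model_params(sigma2_B = exp(stats::runif(1, -2, 1)),
                                 sigma2_F = exp(stats::runif(1, -2, 2)), delta2 = d2),
    OU            = model_params(sigma2 = exp(stats::runif(1, -1, 1)),
                                 alpha = exp(stats::runif(1, -2, 0.5)),
                                 theta = stats::rnorm(1, 3, 2), delta2 = d2),
    OU_SHIFT      = model_params(sigma2_B = exp(stats::runif(1, -1, 1)),
                                 sigma2_F = exp(stats::runif(1, -1, 1)),
                                 alpha = exp(stats::runif(1, -2, 0.5)),
                                 theta_B = stats::rnorm(1, 3, 2),
                                 theta_F = stats::rnorm(1, 3, 2), delta2 = d2))
}

# crude effective sample size from the initial positive autocorrelation sequence
ess <- function(x) {
  n <- length(x)
  ac <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)[1]
  if (!is.na(pos)) ac <- ac[seq_len(pos - 1)]
  max(1, n / (1 + 2 * sum(ac)))
}
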