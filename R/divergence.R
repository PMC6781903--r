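# Expected divergence-versus-time analytics, the corresponding simulations,
# and the OU estimation-bias study across phylogeny sizes.

#' Expected absolute expression divergence under Brownian drift
#'
#' Two species diverged for time T under drift with rate sigma^2 have a
#' normally distributed expression difference with mean zero and variance
#' 2 * sigma^2 * T; the expected absolute difference (the mean of the
#' half-normal, i.e. of the truncated normal folded at zero) is
#' `2 * sigma * sqrt(T / pi)`.
#'
#' @param sigma2 drift rate (>= 0).
#' @param T divergence time, million years (>= 0); time since the most recent
#'   common ancestor.
#' @return expected absolute difference in log2 expression.
#' @export
expected_abs_divergence_bm <- function(sigma2, T) {
  stopifnot(all(sigma2 >= 0), all(T >= 0))
  2 * sqrt(sigma2) * sqrt(T / pi)
}

# pairwise divergence times (time since MRCA) between tips, tip.label order
pairwise_divergence_times <- function(tree) {
  pre <- tree_precompute(tree)
  Tm <- matrix(pre$H - pre$height[pre$mrcapos], pre$S, pre$S,
               dimnames = list(pre$tips, pre$tips))
  diag(Tm) <- 0
  Tm
}

#' Sum-of-squares estimator of the drift rate
#'
#' Moment estimator of sigma^2 from species sample means: for each gene, the
#' mean over species pairs of `(xbar_i - xbar_j)^2 / (2 * T_ij)` with `T_ij`
#' the pair's divergence time; the pooled value is the mean over genes.
#' Invariant to adding a constant to all expression values.
#'
#' @param dataset an [expression_dataset()].
#' @param tree a rooted ultrametric `phylo` whose tips match the data set's
#'   species.
#' @return list with `per_gene` (named vector) and `pooled` (scalar).
#' @export
estimate_sigma2_ss <- function(dataset, tree) {
  stopifnot(inherits(dataset, "expression_dataset"))
  sp <- tree$tip.label
  if (!setequal(unique(dataset$species), sp))
    stop_("data set species do not match the tree tips")
  Tm <- pairwise_divergence_times(tree)
  pairs <- which(upper.tri(Tm), arr.ind = TRUE)
  Tp <- Tm[pairs]
  if (any(Tp == 0)) stop_("zero divergence time between distinct species")
  means <- vapply(sp, function(s)
    rowMeans(dataset$mat[, dataset$species == s, drop = FALSE]),
    numeric(nrow(dataset$mat)))
  means <- matrix(means, nrow = nrow(dataset$mat),
                  dimnames = list(rownames(dataset$mat), sp))
  contrib <- vapply(seq_len(nrow(pairs)), function(k) {
    (means[, pairs[k, 1L]] - means[, pairs[k, 2L]])^2 / (2 * Tp[k])
  }, numeric(nrow(dataset$mat)))
  per_gene <- rowMeans(matrix(contrib, nrow = nrow(dataset$mat)))
  names(per_gene) <- rownames(dataset$mat)
  list(per_gene = per_gene, pooled = mean(per_gene))
}

#' Mean pairwise expression divergence versus divergence time
#'
#' Simulates species-mean expression for `n_genes` genes along the tree under
#' Brownian drift (per sigma value) or a stationary Ornstein-Uhlenbeck
#' process (per sigma x alpha combination), computes the Monte-Carlo mean
#' absolute difference for every species pair, and overlays the analytic
#' expectation (for OU the stationary cross-covariance gives a difference
#' variance of `2 * (sigma^2 / (2 alpha)) * (1 - exp(-alpha * d_ij))`). One
#' value per tip (no within-species noise).
#'
#' @param tree a rooted ultrametric `phylo`.
#' @param family `"BM"` or `"OU"`.
#' @param sigma vector of sigma values (standard-deviation scale, as plotted).
#' @param alpha vector of attraction strengths (OU only).
#' @param n_genes simulated genes per parameter combination (default 10,000).
#' @param seed optional integer seed.
#' @return data frame with columns `pair`, `T`, `sigma`, `alpha` (NA for BM),
#'   `mc_mean`, `analytic_mean`.
#' @export
divergence_curve <- function(tree, family = c("BM", "OU"), sigma,
                             alpha = NULL, n_genes = 10000L, seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  if (family == "OU" && is.null(alpha)) stop_("OU curves need alpha values")
  Tm <- pairwise_divergence_times(tree)
  pairs <- which(upper.tri(Tm), arr.ind = TRUE)
  sp <- tree$tip.label
  grid <- if (family == "BM") data.frame(sigma = sigma, alpha = NA_real_)
          else expand.grid(sigma = sigma, alpha = alpha)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    s2 <- grid$sigma[g]^2
    a <- grid$alpha[g]
    if (family == "BM") {
      V <- bm_tip_covariance(tree, s2)
    } else {
      V <- ou_tip_moments(tree, s2, a, theta = 0)$cov
    }
    L <- chol(V + diag(1e-12, nrow(V)))
    X <- matrix(stats::rnorm(n_genes * length(sp)), n_genes) %*% L
    data.frame(
      pair = apply(pairs, 1L, function(ij) paste(sp[ij], collapse = "-")),
      T = Tm[pairs],
      sigma = grid$sigma[g], alpha = a,
      mc_mean = vapply(seq_len(nrow(pairs)), function(k)
        mean(abs(X[, pairs[k, 1L]] - X[, pairs[k, 2L]])), numeric(1L)),
      analytic_mean = vapply(seq_len(nrow(pairs)), function(k) {
        vdiff <- if (family == "BM") 2 * s2 * Tm[pairs][k]
                 else 2 * (s2 / (2 * a)) * (1 - exp(-a * 2 * Tm[pairs][k]))
        sqrt(2 * vdiff / pi)
      }, numeric(1L)))
  })
  do.call(rbind, out)
}

#' Maximum-likelihood fit of a stationary OU model to tip values
#'
#' Profile likelihood: given alpha, the tip correlation matrix is
#' `exp(-alpha * D)` (D = pairwise tree distances), the optimum is the GLS
#' mean and the stationary variance its profile estimate; alpha is then found
#' by one-dimensional optimization of the profile log likelihood on a log
#' grid.
#'
#' @param x numeric vector of tip values (tree tip order).
#' @param D pairwise tree-distance matrix between tips.
#' @param alpha_bounds search interval for alpha.
#' @return list with `alpha`, `sigma2`, `theta`, `loglik`.
#' @export
fit_ou_ml <- function(x, D, alpha_bounds = c(1e-4, 1e4)) {
  n <- length(x)
  prof <- function(la) {
    R <- exp(-exp(la) * D)
    Lc <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(Lc)) return(list(ll = -Inf))
    Ri1 <- backsolve(Lc, forwardsolve(t(Lc), rep(1, n)))
    Rix <- backsolve(Lc, forwardsolve(t(Lc), x))
    theta <- sum(Rix) / sum(Ri1)
    r <- x - theta
    q <- sum(r * backsolve(Lc, forwardsolve(t(Lc), r)))
    v <- q / n
    if (v <= 0) return(list(ll = -Inf))
    ll <- -0.5 * n * (log(2 * pi * v) + 1) - sum(log(diag(Lc)))
    list(ll = ll, v = v, theta = theta)
  }
  opt <- stats::optimize(function(la) -prof(la)$ll,
                         interval = log(alpha_bounds), tol = 1e-6)
  la <- opt$minimum
  pr <- prof(la)
  alpha <- exp(la)
  list(alpha = alpha, sigma2 = 2 * alpha * pr$v, theta = pr$theta,
       loglik = pr$ll)
}

#' Configuration for the OU estimation-bias study
#'
#' @param taxa phylogeny sizes (subset of 5..1000).
#' @param sigma sigma grid (within 0.1..10).
#' @param alpha alpha grid (within 0.01..10).
#' @param n_sim simulations per cell (default 1000).
#' @param alpha_bounds search bounds for the ML estimator.
#' @param seed integer seed.
#' @return an object of class `bias_study_config`.
#' @export
bias_study_config <- function(taxa = c(5, 10, 50, 100), sigma = 1,
                              alpha = 0.1, n_sim = 1000L,
                              alpha_bounds = c(1e-4, 1e4), seed = 1L) {
  stopifnot(length(taxa) >= 1L, all(taxa >= 3),
            length(sigma) >= 1L, all(sigma > 0),
            length(alpha) >= 1L, all(alpha > 0), n_sim >= 1L)
  structure(list(taxa = taxa, sigma = sigma, alpha = alpha,
                 n_sim = as.integer(n_sim), alpha_bounds = alpha_bounds,
                 seed = as.integer(seed)),
            class = "bias_study_config")
}

#' OU parameter-estimation bias across phylogeny sizes
#'
#' For every (taxa, sigma, alpha) cell: simulate a pure-birth (Yule) tree of
#' the given size rescaled to unit root height, simulate one tip value per
#' species under the stationary OU process, estimate (alpha, sigma^2) by
#' maximum likelihood ([fit_ou_ml()]), and repeat. Relative bias is
#' `(mean(estimate) - truth) / truth`. Replicates whose optimizer fails are
#' dropped and counted (`n_ok`), never imputed.
#'
#' @param config a [bias_study_config()].
#' @return data frame with columns `taxa`, `sigma`, `alpha`, `n_ok`,
#'   `rel_bias_alpha`, `rel_bias_sigma2`, `sd_alpha_hat`.
#' @export
ou_bias_study <- function(config) {
  stopifnot(inherits(config, "bias_study_config"))
  set.seed(config$seed)
  grid <- expand.grid(taxa = config$taxa, sigma = config$sigma,
                      alpha = config$alpha)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    n <- grid$taxa[g]; s <- grid$sigma[g]; a <- grid$alpha[g]
    v <- s^2 / (2 * a)
    ah <- rep(NA_real_, config$n_sim); s2h <- ah
    for (r in seq_len(config$n_sim)) {
      phy <- ape::rphylo(n, birth = 1, death = 0)
      phy$edge.length <- phy$edge.length / tree_height(phy)
      D <- ape::cophenetic.phylo(phy)
      Lc <- tryCatch(chol(v * exp(-a * D) + diag(1e-12, n)),
                     error = function(e) NULL)
      if (is.null(Lc)) next
      x <- as.vector(stats::rnorm(n) %*% Lc)
      fit <- tryCatch(fit_ou_ml(x, D, config$alpha_bounds),
                      error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$loglik)) next
      ah[r] <- fit$alpha; s2h[r] <- fit$sigma2
    }
    ok <- is.finite(ah)
    data.frame(taxa = n, sigma = s, alpha = a, n_ok = sum(ok),
               rel_bias_alpha = (mean(ah[ok]) - a) / a,
               rel_bias_sigma2 = (mean(s2h[ok]) - s^2) / s^2,
               sd_alpha_hat = stats::sd(ah[ok]))
  })
  do.call(rbind, rows)
}
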