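# The six models of species-mean expression evolution, their likelihoods
# (with the within-species variance layer) and exact simulators.
#
# Model identities:
#   EQUAL_MEANS    one global mean mu, no evolution
#   UNEQUAL_MEANS  independent per-species means mu_i, no phylogeny
#   BM             Brownian drift of the species mean, rate sigma2
#   BM_SHIFT       Brownian drift, foreground branch has its own rate sigma2_F
#   OU             Ornstein-Uhlenbeck: drift sigma2, attraction alpha,
#                  optimum theta; stationary variance sigma2 / (2 alpha)
#   OU_SHIFT       OU with foreground-branch rate sigma2_F and optimum theta_F
#                  (single shared alpha)
#
# Every model additionally carries per-species within-species variances
# delta2_i: replicate values X_ij ~ Normal(mu_i, delta2_i) around the (possibly
# latent) species mean. For the phylogenetic models the latent species means
# are integrated out analytically, and for the BM family the unknown root
# state is removed by REML (the likelihood of translation-invariant
# contrasts). OU-family models use the full likelihood under a stationary
# root, so the root state is not a free parameter.

MODEL_NAMES <- c("EQUAL_MEANS", "UNEQUAL_MEANS", "BM", "BM_SHIFT", "OU", "OU_SHIFT")

model_code <- function(model) match(model, MODEL_NAMES)

is_shift_model <- function(model) model %in% c("BM_SHIFT", "OU_SHIFT")

#' Specify one of the six evolutionary models
#'
#' @param model one of `"EQUAL_MEANS"`, `"UNEQUAL_MEANS"`, `"BM"`,
#'   `"BM_SHIFT"`, `"OU"`, `"OU_SHIFT"`.
#' @param foreground foreground branch key (tip label, or the child-node id of
#'   an edge); required iff `model` is a shift model. In the study design the
#'   foreground is always a tip branch.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model, foreground = NULL) {
  model <- match.arg(model, MODEL_NAMES)
  if (is_shift_model(model) && is.null(foreground))
    stop_("%s requires a foreground branch", model)
  if (!is_shift_model(model) && !is.null(foreground))
    stop_("%s does not take a foreground branch", model)
  structure(list(model = model, foreground = foreground), class = "model_spec")
}

# names of the free model parameters (delta2 nuisances appended per species)
param_names <- function(spec, species) {
  core <- switch(spec$model,
    EQUAL_MEANS   = "mu",
    UNEQUAL_MEANS = paste0("mu_", species),
    BM            = "sigma2",
    BM_SHIFT      = c("sigma2_B", "sigma2_F"),
    OU            = c("sigma2", "alpha", "theta"),
    OU_SHIFT      = c("sigma2_B", "sigma2_F", "alpha", "theta_B", "theta_F"))
  c(core, paste0("delta2_", species))
}

#' Parameter block for a model
#'
#' Collects exactly the parameters a [model_spec()] demands. Expression
#' means/optima are in log2 units, drift rates in log2^2 per million years,
#' `alpha` in 1/million years, `delta2` in log2^2.
#'
#' @param mu global mean (EQUAL_MEANS).
#' @param mu_i named per-species means (UNEQUAL_MEANS).
#' @param sigma2 rate of drift (BM, OU).
#' @param sigma2_B,sigma2_F background/foreground drift rates (shift models).
#' @param alpha strength of selection (OU family), > 0.
#' @param theta optimal expression level (OU).
#' @param theta_B,theta_F background/foreground optima (OU_SHIFT).
#' @param delta2 named per-species within-species variances, all > 0.
#' @param root root state used by the BM-family simulator (the BM likelihood
#'   is root-free by REML); defaults to 0.
#' @return an object of class `model_params` (a validated list).
#' @export
model_params <- function(mu = NULL, mu_i = NULL, sigma2 = NULL,
                         sigma2_B = NULL, sigma2_F = NULL, alpha = NULL,
                         theta = NULL, theta_B = NULL, theta_F = NULL,
                         delta2 = NULL, root = 0) {
  out <- list(mu = mu, mu_i = mu_i, sigma2 = sigma2, sigma2_B = sigma2_B,
              sigma2_F = sigma2_F, alpha = alpha, theta = theta,
              theta_B = theta_B, theta_F = theta_F, delta2 = delta2,
              root = root)
  structure(out[!vapply(out, is.null, logical(1L))], class = "model_params")
}

# flatten a model_params into the positional vector the C++ core expects;
# the likelihood requires strictly positive rates/variances, the simulator
# additionally admits the degenerate zero-rate / zero-noise cases
params_to_vector <- function(spec, params, species, strict_positive = TRUE) {
  need <- function(x, nm) {
    if (is.null(x)) stop_("model %s requires parameter '%s'", spec$model, nm)
    x
  }
  lim <- if (strict_positive) 0 else -1e-300
  d <- need(params$delta2, "delta2")
  if (!is.null(names(d))) d <- d[species]
  if (length(d) != length(species) || anyNA(d))
    stop_("delta2 must provide one value per species (%s)",
          paste(species, collapse = ", "))
  if (any(d <= lim)) stop_("delta2 must be positive")
  pos <- function(x, nm) { x <- need(x, nm); if (any(x <= lim)) stop_("%s must be positive", nm); x }
  core <- switch(spec$model,
    EQUAL_MEANS   = need(params$mu, "mu"),
    UNEQUAL_MEANS = {
      m <- need(params$mu_i, "mu_i")
      if (!is.null(names(m))) m <- m[species]
      if (length(m) != length(species) || anyNA(m))
        stop_("mu_i must provide one value per species")
      m
    },
    BM            = pos(params$sigma2, "sigma2"),
    BM_SHIFT      = c(pos(params$sigma2_B, "sigma2_B"), pos(params$sigma2_F, "sigma2_F")),
    OU            = c(pos(params$sigma2, "sigma2"), pos(params$alpha, "alpha"),
                      need(params$theta, "theta")),
    OU_SHIFT      = c(pos(params$sigma2_B, "sigma2_B"), pos(params$sigma2_F, "sigma2_F"),
                      pos(params$alpha, "alpha"), need(params$theta_B, "theta_B"),
                      need(params$theta_F, "theta_F")))
  stats::setNames(c(core, d), param_names(spec, species))
}

vector_to_params <- function(spec, p, species) {
  d <- stats::setNames(p[paste0("delta2_", species)], species)
  switch(spec$model,
    EQUAL_MEANS   = model_params(mu = unname(p["mu"]), delta2 = d),
    UNEQUAL_MEANS = model_params(mu_i = stats::setNames(p[paste0("mu_", species)], species),
                                 delta2 = d),
    BM            = model_params(sigma2 = unname(p["sigma2"]), delta2 = d),
    BM_SHIFT      = model_params(sigma2_B = unname(p["sigma2_B"]),
                                 sigma2_F = unname(p["sigma2_F"]), delta2 = d),
    OU            = model_params(sigma2 = unname(p["sigma2"]), alpha = unname(p["alpha"]),
                                 theta = unname(p["theta"]), delta2 = d),
    OU_SHIFT      = model_params(sigma2_B = unname(p["sigma2_B"]),
                                 sigma2_F = unname(p["sigma2_F"]),
                                 alpha = unname(p["alpha"]),
                                 theta_B = unname(p["theta_B"]),
                                 theta_F = unname(p["theta_F"]), delta2 = d))
}

#' Serialize a model specification and parameters to JSON
#' @param spec a `model_spec`.
#' @param params a `model_params`.
#' @return a JSON string.
#' @export
params_to_json <- function(spec, params) {
  pr <- unclass(params)
  for (nm in c("delta2", "mu_i"))
    if (!is.null(pr[[nm]])) pr[[nm]] <- as.list(pr[[nm]])
  jsonlite::toJSON(list(model = spec$model,
                        foreground = spec$foreground,
                        params = pr),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname params_to_json
#' @param json a JSON string produced by `params_to_json()`.
#' @return a list with elements `spec` and `params`.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  pr <- x$params
  if (!is.null(pr$delta2)) pr$delta2 <- unlist(pr$delta2)
  if (!is.null(pr$mu_i)) pr$mu_i <- unlist(pr$mu_i)
  list(spec = model_spec(x$model, foreground = x$foreground),
       params = do.call(model_params, pr))
}

#' Brownian-motion covariance of tip species means
#'
#' Entry (i, j) is the accumulated variance over the shared root-to-MRCA path:
#' the sum over shared edges of rate x branch length.
#'
#' @param tree a rooted `phylo` object.
#' @param branch_rates either a single rate applied to all edges or a numeric
#'   vector of per-edge rates in `tree$edge` order; all > 0.
#' @return symmetric positive-semidefinite species x species matrix, rows and
#'   columns in `tree$tip.label` order.
#' @export
bm_tip_covariance <- function(tree, branch_rates) {
  validate_phylogeny(tree, ultrametric = FALSE)
  ne <- nrow(tree$edge)
  if (length(branch_rates) == 1L) branch_rates <- rep(branch_rates, ne)
  if (length(branch_rates) != ne) stop_("need one rate per edge (%d)", ne)
  if (any(branch_rates <= 0)) stop_("branch rates must be positive")
  S <- ape::Ntip(tree)
  nn <- S + tree$Nnode
  acc <- numeric(nn)                      # accumulated rate*length root->node
  cw <- ape::reorder.phylo(tree, "cladewise")
  rate_cw <- branch_rates[match(cw$edge[, 2L], tree$edge[, 2L])]
  for (k in seq_len(ne))
    acc[cw$edge[k, 2L]] <- acc[cw$edge[k, 1L]] + rate_cw[k] * cw$edge.length[k]
  m <- ape::mrca(tree)
  V <- matrix(acc[m], S, S, dimnames = list(tree$tip.label, tree$tip.label))
  V
}

#' Ornstein-Uhlenbeck moments of tip species means
#'
#' First two moments of the tip species means under an OU process with shared
#' attraction strength `alpha` and piecewise-constant drift rate and optimum
#' (background everywhere; foreground edge, if any, gets its own values). The
#' root state is drawn from the stationary distribution
#' Normal(theta background, sigma2/(2 alpha)), which makes the tip variance
#' exactly sigma2/(2 alpha) in the constant-parameter case and the covariance
#' between tips i and j equal to (sigma2/(2 alpha)) * exp(-alpha * d_ij) with
#' d_ij the tree distance between the tips.
#'
#' As alpha -> 0 the mean-centered (contrast) structure converges to the
#' Brownian-motion covariance; the raw stationary variance grows like
#' 1/(2 alpha), so `alpha` below 1e-12 is an error and callers wanting the
#' Brownian limit must use [bm_tip_covariance()].
#'
#' @param tree a rooted ultrametric `phylo` object.
#' @param sigma2 drift rate (> 0); background rate if `foreground` is given.
#' @param alpha attraction strength (>= 1e-12).
#' @param theta optimum (background optimum if `foreground` is given).
#' @param foreground optional foreground branch key (see [model_spec()]).
#' @param sigma2_F,theta_F foreground drift rate and optimum (defaults: the
#'   background values).
#' @return list with `mean` (length-S vector) and `cov` (S x S matrix) in
#'   `tree$tip.label` order.
#' @export
ou_tip_moments <- function(tree, sigma2, alpha, theta, foreground = NULL,
                           sigma2_F = NULL, theta_F = NULL) {
  stopifnot(sigma2 > 0)
  if (alpha < 1e-12)
    stop_("alpha = %g is below 1e-12; use bm_tip_covariance() for the Brownian limit",
          alpha)
  pre <- tree_precompute(tree, foreground = foreground)
  raw <- cpp_ou_moments(pre, sigma2, sigma2_F %||% sigma2, alpha,
                        theta, theta_F %||% theta)
  S <- pre$S
  list(mean = stats::setNames(raw[seq_len(S)], pre$tips),
       cov = matrix(raw[-seq_len(S)], S, S, byrow = TRUE,
                    dimnames = list(pre$tips, pre$tips)))
}

# per-gene sufficient statistics + replicate-weighted orthonormal contrast
# matrix, aligned to the tree tip order, as consumed by the C++ core
gene_stats <- function(gene, tree) {
  species <- tree$tip.label
  if (!setequal(names(gene$values), species))
    stop_("gene '%s' species set does not match the tree tips", gene$gene_id)
  vals <- gene$values[species]
  n <- vapply(vals, length, integer(1L))
  xbar <- vapply(vals, mean, numeric(1L))
  ss <- vapply(vals, function(v) sum((v - mean(v))^2), numeric(1L))
  u <- sqrt(n)
  Q <- qr.Q(qr(matrix(u, ncol = 1L)), complete = TRUE)   # cols 2..S span u-perp
  Bt <- t(Q[, -1L, drop = FALSE]) %*% diag(sqrt(n), length(n))
  list(xbar = unname(xbar), ss = unname(ss), n = unname(as.numeric(n)), Bt = Bt)
}

#' Model log likelihood
#'
#' Joint log likelihood of all replicate observations of a gene under one of
#' the six models. Species means are integrated out analytically (the
#' observations are jointly multivariate normal); BM-family models use the
#' REML (contrast) likelihood, which is invariant to adding a constant to all
#' observations, while OU-family models use the full likelihood under the
#' stationary root.
#'
#' @param spec a [model_spec()].
#' @param params a [model_params()] matching `spec`.
#' @param gene a [gene_observations()] whose species set equals the tree tips.
#' @param tree a rooted ultrametric `phylo`; may be `NULL` for the two
#'   non-phylogenetic models.
#' @return the log likelihood (scalar).
#' @export
model_loglik <- function(spec, params, gene, tree = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(gene, "gene_observations"))
  phylo_model <- !spec$model %in% c("EQUAL_MEANS", "UNEQUAL_MEANS")
  if (phylo_model && is.null(tree)) stop_("%s requires a tree", spec$model)
  if (is.null(tree)) {
    species <- sort(names(gene$values))
    pre <- .dummy_tree_precompute(species)
  } else {
    species <- tree$tip.label
    pre <- tree_precompute(tree, foreground = spec$foreground)
  }
  p <- params_to_vector(spec, params, species)
  gs <- gene_stats_for(gene, species)
  ll <- cpp_model_loglik(model_code(spec$model), pre, gs, unname(p))
  if (!is.finite(ll) && phylo_model)
    stop_("assembled covariance not positive definite for %s at %s",
          spec$model, paste(sprintf("%s=%g", names(p), p), collapse = ", "))
  ll
}

# gene stats when species order is given directly (no tree)
gene_stats_for <- function(gene, species) {
  fake <- list(tip.label = species)
  if (!setequal(names(gene$values), species))
    stop_("gene '%s' species set mismatch", gene$gene_id)
  gene_stats(gene, fake)
}

# minimal precompute for the non-phylogenetic models (tree never touched)
.dummy_tree_precompute <- function(species) {
  S <- length(species)
  Z <- matrix(0, S, S)
  list(S = S, Sb = Z, Sf = Z, parent = 0L, elen = 0, isfg = 0L,
       tippos = rep(1L, S), mrcapos = matrix(1L, S, S), height = 0,
       tips = species, H = 0)
}

#' Simulate one gene under a model
#'
#' Exact recursive simulation down the tree: each child node's species mean is
#' drawn from a normal distribution around the parent value propagated under
#' the model, with the model-specific branch variance; replicates are then
#' drawn around each tip mean with the per-species within-species variance
#' delta2_i. For the BM family the root state is `params$root`; for the OU
#' family the root is drawn from the stationary distribution.
#'
#' @inheritParams model_loglik
#' @param tree a rooted ultrametric `phylo` (may be `NULL` for the
#'   non-phylogenetic models).
#' @param replicates named integer vector of replicate counts per species
#'   (all >= 1).
#' @param seed optional integer seed for reproducibility.
#' @return a [gene_observations()] object (attribute `species_means` carries
#'   the simulated latent means).
#' @export
simulate_gene <- function(spec, params, tree, replicates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "model_spec"))
  if (any(replicates < 1L)) stop_("replicate counts must be >= 1")
  species <- if (is.null(tree)) names(replicates) else tree$tip.label
  if (!setequal(names(replicates), species))
    stop_("replicate names must match the species set")
  p <- params_to_vector(spec, params, species, strict_positive = FALSE)
  d <- stats::setNames(p[paste0("delta2_", species)], species)

  means <- switch(spec$model,
    EQUAL_MEANS   = stats::setNames(rep(params$mu, length(species)), species),
    UNEQUAL_MEANS = {
      m <- params$mu_i; if (!is.null(names(m))) m <- m[species]
      stats::setNames(m, species)
    },
    .simulate_tree_means(spec, params, tree))

  vals <- lapply(species, function(s)
    stats::rnorm(replicates[[s]], mean = means[[s]], sd = sqrt(d[[s]])))
  names(vals) <- species
  out <- gene_observations("sim", vals, min_replicates = 1L)
  attr(out, "species_means") <- means
  out
}

# recursive node-by-node simulation of the latent species means
.simulate_tree_means <- function(spec, params, tree) {
  if (is.null(tree)) stop_("%s requires a tree", spec$model)
  pre <- tree_precompute(tree, foreground = spec$foreground)
  nn <- length(pre$parent)
  is_ou <- spec$model %in% c("OU", "OU_SHIFT")
  s2B <- params$sigma2_B %||% params$sigma2
  s2F <- params$sigma2_F %||% s2B
  thB <- params$theta_B %||% params$theta
  thF <- params$theta_F %||% thB
  alpha <- params$alpha
  if (is_ou && (is.null(alpha) || alpha <= 0)) stop_("OU simulation needs alpha > 0")

  x <- numeric(nn)
  x[1L] <- if (is_ou) {
    stats::rnorm(1L, thB, sqrt(s2B / (2 * alpha)))
  } else {
    params$root %||% 0
  }
  for (k in 2:nn) {
    L <- pre$elen[k]
    s2 <- if (pre$isfg[k]) s2F else s2B
    if (is_ou) {
      th <- if (pre$isfg[k]) thF else thB
      e1 <- exp(-alpha * L)
      v <- -expm1(-2 * alpha * L) * s2 / (2 * alpha)
      x[k] <- stats::rnorm(1L, th + (x[pre$parent[k]] - th) * e1, sqrt(v))
    } else {
      x[k] <- stats::rnorm(1L, x[pre$parent[k]], sqrt(s2 * L))
    }
  }
  stats::setNames(x[pre$tippos], pre$tips)
}
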