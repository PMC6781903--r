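# Metropolis-Hastings sampling, stepping-stone marginal likelihoods, Bayes
# factors and model probabilities. The chain itself runs in compiled code
# (see src/core.cpp); this file owns priors, initialization, schedules and
# the estimator algebra.

#' Prior bounds for all model parameters
#'
#' Means and optima get uniform priors; rates, `alpha` and the within-species
#' variances get log-uniform priors (flat on the log scale). Defaults:
#' means/optima Uniform(-20, 20); `sigma2` (all variants), `alpha` and
#' `delta2` log-uniform(1e-5, 1e5).
#'
#' @param mean_bounds bounds for `mu`, `mu_i`, `theta`, `theta_B`, `theta_F`.
#' @param rate_bounds bounds for `sigma2`, `sigma2_B`, `sigma2_F`.
#' @param alpha_bounds bounds for `alpha`.
#' @param delta2_bounds bounds for the `delta2_i` nuisances.
#' @return an object of class `prior_config`.
#' @export
prior_config <- function(mean_bounds = c(-20, 20),
                         rate_bounds = c(1e-5, 1e5),
                         alpha_bounds = c(1e-5, 1e5),
                         delta2_bounds = c(1e-5, 1e5)) {
  chk <- function(b, nm, positive) {
    if (length(b) != 2L || b[2L] <= b[1L]) stop_("invalid bounds for %s", nm)
    if (positive && b[1L] <= 0) stop_("%s bounds must be positive", nm)
    b
  }
  structure(list(mean_bounds = chk(mean_bounds, "mean", FALSE),
                 rate_bounds = chk(rate_bounds, "rate", TRUE),
                 alpha_bounds = chk(alpha_bounds, "alpha", TRUE),
                 delta2_bounds = chk(delta2_bounds, "delta2", TRUE)),
            class = "prior_config")
}

#' @rdname prior_config
#' @export
default_priors <- function() prior_config()

#' MCMC schedule
#'
#' Defaults follow the study protocol: a burn-in of 2000 iterations with
#' proposal auto-tuning every 100 iterations, a main phase of 50,000
#' iterations thinned by 10 (5000 retained samples), and every parameter
#' updated twice per iteration in random order. Tuning is frozen after
#' burn-in so the main chain is a valid Markov chain.
#'
#' @param burnin burn-in iterations.
#' @param tune_interval auto-tuning interval during burn-in.
#' @param iterations main-phase iterations; must be a multiple of `thin`.
#' @param thin thinning interval.
#' @param updates_per_param proposals per parameter per iteration.
#' @param target_accept per-proposal acceptance rate targeted by auto-tuning.
#' @param seed integer seed; every run is bit-reproducible given the seed.
#' @return an object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(burnin = 2000L, tune_interval = 100L,
                          iterations = 50000L, thin = 10L,
                          updates_per_param = 2L, target_accept = 0.44,
                          seed = 1L) {
  if (iterations %% thin != 0L) stop_("iterations must be a multiple of thin")
  structure(list(burnin = as.integer(burnin),
                 tune_interval = as.integer(tune_interval),
                 iterations = as.integer(iterations), thin = as.integer(thin),
                 updates_per_param = as.integer(updates_per_param),
                 target_accept = target_accept, seed = as.integer(seed)),
            class = "mcmc_settings")
}

# per-parameter prior table (bounds + type) in positional order
prior_table <- function(spec, priors, species) {
  nm <- param_names(spec, species)
  typ <- integer(length(nm))   # 0 uniform, 1 log-uniform
  lo <- numeric(length(nm)); hi <- numeric(length(nm))
  for (k in seq_along(nm)) {
    b <- if (grepl("^(mu|theta)", nm[k])) {
      typ[k] <- 0L; priors$mean_bounds
    } else if (grepl("^sigma2", nm[k])) {
      typ[k] <- 1L; priors$rate_bounds
    } else if (nm[k] == "alpha") {
      typ[k] <- 1L; priors$alpha_bounds
    } else {
      typ[k] <- 1L; priors$delta2_bounds
    }
    lo[k] <- b[1L]; hi[k] <- b[2L]
  }
  list(names = nm, lo = lo, hi = hi, type = typ)
}

# draw a starting point from the priors (optionally pinning the mean-type
# parameters at the grand sample mean) and insist on a finite likelihood
draw_init <- function(model, pre, gs, pt, fixed, init_at_mean, max_tries = 100L) {
  grand <- sum(gs$xbar * gs$n) / sum(gs$n)
  for (try in seq_len(max_tries)) {
    p <- numeric(length(pt$lo))
    isl <- pt$type == 1L
    p[isl] <- exp(stats::runif(sum(isl), log(pt$lo[isl]), log(pt$hi[isl])))
    p[!isl] <- stats::runif(sum(!isl), pt$lo[!isl], pt$hi[!isl])
    if (init_at_mean) {
      is_mean <- grepl("^(mu|theta)", pt$names)
      p[is_mean] <- min(max(grand, pt$lo[is_mean][1L]), pt$hi[is_mean][1L])
    }
    if (length(fixed)) p[match(names(fixed), pt$names)] <- unlist(fixed)
    if (is.finite(cpp_model_loglik(model, pre, gs, p))) return(p)
  }
  stop_("could not find a starting point with finite likelihood after %d tries",
        max_tries)
}

#' Run a Metropolis-Hastings MCMC analysis for one gene and model
#'
#' Proposals are sliding windows with reflection at the prior bounds:
#' interval-bounded parameters (means, optima) on the natural scale, positive
#' parameters (rates, `alpha`, `delta2`) on the log scale where their
#' log-uniform prior is flat (a multiplicative scaling proposal). Proposal
#' widths are auto-tuned toward `target_accept` during burn-in only.
#'
#' @param spec a [model_spec()].
#' @param gene a [gene_observations()].
#' @param tree a rooted ultrametric `phylo` (`NULL` allowed for the
#'   non-phylogenetic models).
#' @param priors a [prior_config()].
#' @param settings an [mcmc_settings()].
#' @param fixed optional named list of parameters to hold fixed (excluded
#'   from sampling).
#' @param beta power on the likelihood (used by stepping-stone tempering;
#'   1 = posterior).
#' @param init_at_mean start mean/optimum parameters at the grand sample mean
#'   instead of a prior draw.
#' @param init,scales optional full start vector (natural scale) and proposal
#'   widths, used for warm starts.
#' @return an object of class `posterior_trace`: `samples` (retained draws,
#'   natural scale, named columns), `loglik` (untempered log likelihood per
#'   retained draw), `accept` (per-parameter acceptance rates, main phase),
#'   `scales` (final tuned proposal widths), `last`/`last_loglik` (chain
#'   state), plus the spec/settings used.
#' @export
run_mcmc <- function(spec, gene, tree = NULL, priors = default_priors(),
                     settings = mcmc_settings(), fixed = NULL, beta = 1,
                     init_at_mean = FALSE, init = NULL, scales = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(settings, "mcmc_settings"))
  phylo_model <- !spec$model %in% c("EQUAL_MEANS", "UNEQUAL_MEANS")
  if (phylo_model && is.null(tree)) stop_("%s requires a tree", spec$model)
  species <- if (is.null(tree)) sort(names(gene$values)) else tree$tip.label
  pre <- if (is.null(tree)) .dummy_tree_precompute(species)
         else tree_precompute(tree, foreground = spec$foreground)
  gs <- gene_stats_for(gene, species)
  pt <- prior_table(spec, priors, species)
  set.seed(settings$seed)
  res <- .run_chain(spec, pre, gs, pt, settings, fixed, beta, init_at_mean,
                    init, scales)
  res$spec <- spec
  res$settings <- settings
  res
}

# chain runner shared by run_mcmc and stepping_stone (no reseeding here)
.run_chain <- function(spec, pre, gs, pt, settings, fixed, beta,
                       init_at_mean, init = NULL, scales = NULL) {
  model <- model_code(spec$model)
  if (length(fixed) && !all(names(fixed) %in% pt$names))
    stop_("unknown fixed parameter(s): %s",
          paste(setdiff(names(fixed), pt$names), collapse = ", "))
  is_free <- !(pt$names %in% names(fixed))
  if (is.null(init))
    init <- draw_init(model, pre, gs, pt, fixed, init_at_mean)
  if (is.null(scales)) {
    zr <- pt$hi - pt$lo
    zr[pt$type == 1L] <- log(pt$hi[pt$type == 1L]) - log(pt$lo[pt$type == 1L])
    scales <- zr / 10
  }
  out <- cpp_mh_chain(model, pre, gs, pt$lo, pt$hi, pt$type, is_free, init,
                      settings$burnin, settings$tune_interval,
                      settings$iterations, settings$thin,
                      settings$updates_per_param, beta,
                      settings$target_accept, scales)
  colnames(out$samples) <- pt$names
  names(out$accept) <- pt$names
  names(out$scales) <- pt$names
  names(out$last) <- pt$names
  out$accept <- out$accept[is_free]
  structure(out, class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat(sprintf("posterior_trace: %d retained samples of %d parameters (%s)\n",
              nrow(x$samples), ncol(x$samples), x$spec$model))
  invisible(x)
}

#' Write a posterior trace to TSV
#'
#' One row per retained sample, first column the retained-sample iteration
#' index, then one column per parameter.
#'
#' @param trace a `posterior_trace`.
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(iteration = seq_len(nrow(trace$samples)) *
                     trace$settings$thin,
                   trace$samples, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stepping-stone estimate of the log marginal likelihood
#'
#' Runs one power-posterior chain per stone with the likelihood raised to a
#' power beta. The powers are quantiles of a Beta(0.3, 1) distribution at
#' equally spaced probabilities k/K (k = 1..K, so the last power is 1), which
#' concentrates stones near beta = 0 where the integrand varies fastest. The
#' K sampling chains run at powers `{0, beta_1, ..., beta_{K-1}}`, each
#' warm-started at the previous stone's final state, and the per-stone
#' importance ratios are combined in log space with the standard
#' stepping-stone estimator. A model with no free parameters integrates over
#' an empty space: its log marginal likelihood is the log likelihood exactly.
#'
#' @inheritParams run_mcmc
#' @param stones number of stones (>= 2); the study protocol used 128.
#' @param beta_shape first shape parameter of the Beta distribution whose
#'   quantiles place the stones.
#' @return an object of class `marginal_likelihood`: `model`, `logml`,
#'   `stones`, `betas` (strictly increasing in (0, 1], last = 1), and
#'   `posterior` (the chain from the last, highest-power stone).
#' @export
stepping_stone <- function(spec, gene, tree = NULL, priors = default_priors(),
                           settings = mcmc_settings(), stones = 128L,
                           fixed = NULL, beta_shape = 0.3,
                           init_at_mean = FALSE) {
  stopifnot(stones >= 2L)
  phylo_model <- !spec$model %in% c("EQUAL_MEANS", "UNEQUAL_MEANS")
  if (phylo_model && is.null(tree)) stop_("%s requires a tree", spec$model)
  species <- if (is.null(tree)) sort(names(gene$values)) else tree$tip.label
  pre <- if (is.null(tree)) .dummy_tree_precompute(species)
         else tree_precompute(tree, foreground = spec$foreground)
  gs <- gene_stats_for(gene, species)
  pt <- prior_table(spec, priors, species)
  set.seed(settings$seed)

  betas <- stats::qbeta(seq_len(stones) / stones, beta_shape, 1)
  betas[stones] <- 1

  if (all(pt$names %in% names(fixed))) {
    p <- unlist(fixed)[pt$names]
    logml <- cpp_model_loglik(model_code(spec$model), pre, gs, unname(p))
    return(structure(list(model = spec$model, logml = logml, stones = stones,
                          betas = betas, posterior = NULL),
                     class = "marginal_likelihood"))
  }

  powers <- c(0, betas[-stones])        # sampling powers, one chain per stone
  log_ratios <- numeric(stones)
  init <- NULL; scales <- NULL; chain <- NULL
  for (k in seq_len(stones)) {
    chain <- .run_chain(spec, pre, gs, pt, settings, fixed, powers[k],
                        init_at_mean, init = init, scales = scales)
    ll <- chain$loglik
    if (!all(is.finite(ll)))
      stop_("non-finite likelihood samples at stone %d (power %g)", k, powers[k])
    dbeta_k <- betas[k] - powers[k]
    log_ratios[k] <- logsumexp(dbeta_k * ll) - log(length(ll))
    if (!is.finite(log_ratios[k]))
      stop_("non-finite stepping-stone ratio at stone %d", k)
    init <- chain$last
    scales <- chain$scales
  }
  chain$spec <- spec; chain$settings <- settings
  structure(list(model = spec$model, logml = sum(log_ratios), stones = stones,
                 betas = betas, posterior = chain),
            class = "marginal_likelihood")
}

#' @export
print.marginal_likelihood <- function(x, ...) {
  cat(sprintf("marginal_likelihood: %s logML = %.4f (%d stones)\n",
              x$model, x$logml, x$stones))
  invisible(x)
}

as_logml <- function(x) {
  if (inherits(x, "marginal_likelihood")) x$logml else as.numeric(x)
}

#' Bayes factor between two models
#'
#' @param mlA,mlB `marginal_likelihood` objects (or raw log marginal
#'   likelihoods); the Bayes factor is `exp(logML_A - logML_B)`.
#' @return the Bayes factor of A over B.
#' @export
bayes_factor <- function(mlA, mlB) exp(as_logml(mlA) - as_logml(mlB))

#' Model probabilities from marginal likelihoods
#'
#' Posterior model probabilities under equal prior model weights:
#' proportional to `exp(logML)`; invariant to adding a constant to all log
#' marginal likelihoods.
#'
#' @param mls list of `marginal_likelihood` objects (or a numeric vector of
#'   log marginal likelihoods, optionally named).
#' @return named probability vector summing to 1.
#' @export
model_probabilities <- function(mls) {
  if (is.list(mls)) {
    lm <- vapply(mls, as_logml, numeric(1L))
    nm <- vapply(mls, function(m) if (inherits(m, "marginal_likelihood")) m$model else "", character(1L))
    if (all(nzchar(nm))) names(lm) <- nm
  } else lm <- mls
  p <- exp(lm - logsumexp(lm))
  p / sum(p)
}

#' Convert a two-model probability to a Bayes factor
#'
#' `p / (1 - p)`: a model probability of 0.75 corresponds to a Bayes factor
#' of 3 (positive support), 0.95 to 19 (strong support).
#'
#' @param p model probability, strictly inside (0, 1).
#' @return the Bayes factor.
#' @export
prob_to_bf <- function(p) {
  if (any(p <= 0 | p >= 1)) stop_("p must lie strictly in (0, 1)")
  p / (1 - p)
}

#' Compare models by marginal likelihood
#'
#' @param mls list of `marginal_likelihood` objects for the same gene.
#' @return an object of class `model_comparison` with log marginal
#'   likelihoods, model probabilities (equal prior weights) and the pairwise
#'   Bayes-factor matrix.
#' @export
model_comparison <- function(mls) {
  stopifnot(is.list(mls), length(mls) >= 2L)
  lm <- vapply(mls, as_logml, numeric(1L))
  names(lm) <- vapply(mls, function(m) m$model, character(1L))
  probs <- model_probabilities(mls)
  bf <- outer(lm, lm, function(a, b) exp(a - b))
  structure(list(logml = lm, probabilities = probs, bayes_factors = bf),
            class = "model_comparison")
}

#' Write a model comparison to TSV
#'
#' Columns: model, log marginal likelihood, model probability, and the
#' support call at probability thresholds 0.75 ("positive", Bayes factor > 3)
#' and 0.95 ("strong", Bayes factor > 20).
#'
#' @param cmp a `model_comparison`.
#' @param path output file.
#' @export
write_comparison <- function(cmp, path) {
  support <- ifelse(cmp$probabilities > 0.95, "strong",
                    ifelse(cmp$probabilities > 0.75, "positive", "none"))
  df <- data.frame(model = names(cmp$logml), log_marginal = cmp$logml,
                   probability = cmp$probabilities, support = support)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
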