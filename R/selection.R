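# Per-gene decision procedures: phylogenetic-signal test, conserved-gene
# Monte-Carlo test, tip-branch shift detection with direction calls, and the
# follow-up sign and rank-sum tests.

#' Test for a phylogenetic signal in a gene's expression levels
#'
#' Estimates stepping-stone marginal likelihoods for the two non-phylogenetic
#' models (identical species means; independent species means) and the
#' Brownian-motion model, and reports the pairwise model probabilities: BM
#' against each non-phylogenetic model, and the two non-phylogenetic models
#' against each other.
#'
#' @inheritParams stepping_stone
#' @return a list with `logml` (named, three models), `pairwise` (named
#'   probabilities `bm_vs_unequal`, `bm_vs_equal`, `unequal_vs_equal`, each
#'   the probability of the first-named model) and `probabilities` (joint,
#'   all three models).
#' @export
test_phylo_signal <- function(gene, tree, priors = default_priors(),
                              settings = mcmc_settings(), stones = 128L) {
  mls <- list(
    stepping_stone(model_spec("EQUAL_MEANS"), gene, tree, priors, settings, stones),
    stepping_stone(model_spec("UNEQUAL_MEANS"), gene, tree, priors, settings, stones),
    stepping_stone(model_spec("BM"), gene, tree, priors, settings, stones))
  lm <- stats::setNames(vapply(mls, as_logml, numeric(1L)),
                        c("EQUAL_MEANS", "UNEQUAL_MEANS", "BM"))
  pair <- function(a, b) unname(model_probabilities(lm[c(a, b)])[1L])
  list(logml = lm,
       pairwise = c(bm_vs_unequal = pair("BM", "UNEQUAL_MEANS"),
                    bm_vs_equal = pair("BM", "EQUAL_MEANS"),
                    unequal_vs_equal = pair("UNEQUAL_MEANS", "EQUAL_MEANS")),
       probabilities = model_probabilities(lm))
}

#' Monte-Carlo test for conserved gene expression (sigma^2 = 0)
#'
#' Marginal-likelihood comparisons are sensitive to the prior, so conservation
#' is tested by simulation instead: (1) fit the identical-species-means model
#' (parameters: the per-species within-species variances plus the global
#' mean); (2) draw `n_sim` parameter vectors from that posterior; (3) simulate
#' one data set per draw with the gene's replicate layout; (4) estimate the
#' posterior-mean Brownian drift rate sigma^2 for every simulated data set and
#' for the empirical gene; (5) call the gene conserved iff its empirical
#' posterior-mean sigma^2 does not exceed the 95th percentile of the simulated
#' ones.
#'
#' @inheritParams run_mcmc
#' @param n_sim number of simulated data sets (>= 100; the study used 1000).
#' @param sim_settings MCMC schedule for the per-data-set Brownian fits
#'   (defaults to `settings`); shorten it for calibration experiments.
#' @param level quantile defining the threshold (default 0.95).
#' @return an object of class `conserved_result`: `gene_id`,
#'   `empirical_sigma2` (posterior mean), `threshold` (the `level` quantile of
#'   the simulated posterior means), `conserved` flag, and the simulated
#'   posterior means (`sim_sigma2`).
#' @export
conserved_gene_test <- function(gene, tree, priors = default_priors(),
                                settings = mcmc_settings(), n_sim = 1000L,
                                sim_settings = NULL, level = 0.95) {
  if (n_sim < 100L) stop_("n_sim must be at least 100")
  sim_settings <- sim_settings %||% settings
  species <- tree$tip.label
  replicates <- vapply(gene$values, length, integer(1L))[species]

  eq_fit <- run_mcmc(model_spec("EQUAL_MEANS"), gene, tree, priors, settings)
  draws <- eq_fit$samples[sample.int(nrow(eq_fit$samples), n_sim, replace = TRUE), ,
                          drop = FALSE]

  bm_mean_sigma2 <- function(g, seed) {
    st <- sim_settings; st$seed <- seed
    fit <- run_mcmc(model_spec("BM"), g, tree, priors, st)
    mean(fit$samples[, "sigma2"])
  }
  seeds <- sample.int(.Machine$integer.max, n_sim + 1L)
  sim_sigma2 <- vapply(seq_len(n_sim), function(i) {
    pars <- vector_to_params(model_spec("EQUAL_MEANS"), draws[i, ], species)
    g <- simulate_gene(model_spec("EQUAL_MEANS"), pars, tree = NULL,
                       replicates = replicates)
    bm_mean_sigma2(g, seeds[i])
  }, numeric(1L))
  empirical <- bm_mean_sigma2(gene, seeds[n_sim + 1L])

  threshold <- unname(stats::quantile(sim_sigma2, level))
  structure(list(gene_id = gene$gene_id, empirical_sigma2 = empirical,
                 threshold = threshold,
                 conserved = empirical <= threshold,
                 sim_sigma2 = sim_sigma2),
            class = "conserved_result")
}

#' Number of MCMC analyses performed by the conserved-gene screen
#'
#' Each gene requires one analysis of the empirical data set plus one per
#' simulated data set; the study's screen of 2393 genes with 1000 simulations
#' each amounted to 2,395,393 analyses.
#'
#' @param n_genes number of genes screened.
#' @param n_sim simulated data sets per gene.
#' @return total analysis count `n_genes * (n_sim + 1)`.
#' @export
conserved_test_workload <- function(n_genes, n_sim = 1000L) {
  n_genes * (n_sim + 1)
}

#' Test for a branch-specific shift in expression evolution
#'
#' Compares a shift model against its no-shift base model for a chosen
#' foreground tip branch: `BM_SHIFT` vs `BM` (rate shift: directional
#' selection under drift) or `OU_SHIFT` vs `OU` (optimum and rate shift).
#' Significance is a model probability above `threshold` (default 0.75, i.e.
#' Bayes factor > 3; set 0.95 for strong support). For significant shifts the
#' direction is classified by [classify_shift_direction()]: from the sample
#' means for the BM family, from the posterior mean of `theta_F - theta_B`
#' for the OU family.
#'
#' @inheritParams stepping_stone
#' @param foreground foreground tip label.
#' @param family `"BM"` or `"OU"`.
#' @param threshold model-probability significance threshold.
#' @return an object of class `shift_result`: `gene_id`, `foreground`,
#'   `family`, `logml` (shift and base), `probability` (of the shift model),
#'   `significant`, `direction` (`"up"`/`"down"`, `NA` unless significant)
#'   and `tie` flag.
#' @export
branch_shift_test <- function(gene, tree, foreground, family = c("BM", "OU"),
                              priors = default_priors(),
                              settings = mcmc_settings(), stones = 128L,
                              threshold = 0.75) {
  family <- match.arg(family)
  if (!foreground %in% tree$tip.label)
    stop_("foreground '%s' must be a tip of the tree", foreground)
  base <- model_spec(family)
  shift <- model_spec(paste0(family, "_SHIFT"), foreground = foreground)
  ml_base <- stepping_stone(base, gene, tree, priors, settings, stones)
  ml_shift <- stepping_stone(shift, gene, tree, priors, settings, stones)
  prob <- unname(model_probabilities(c(shift = ml_shift$logml,
                                       base = ml_base$logml))[1L])
  significant <- prob > threshold
  direction <- NA_character_; tie <- FALSE
  if (significant) {
    fit <- list(family = family, foreground = foreground)
    if (family == "OU") {
      post <- ml_shift$posterior$samples
      fit$theta_F <- mean(post[, "theta_F"])
      fit$theta_B <- mean(post[, "theta_B"])
    }
    dir <- classify_shift_direction(gene, fit)
    direction <- dir$direction; tie <- dir$tie
  }
  structure(list(gene_id = gene$gene_id, foreground = foreground,
                 family = family,
                 logml = c(shift = ml_shift$logml, base = ml_base$logml),
                 probability = prob, threshold = threshold,
                 significant = significant, direction = direction, tie = tie),
            class = "shift_result")
}

#' Direction of a significant expression shift
#'
#' BM family: sign of (foreground species sample mean - mean of the
#' background species sample means). OU family: sign of the posterior mean of
#' `theta_F - theta_B`. An exact zero difference is broken toward `"down"`
#' and flagged as a tie.
#'
#' @param gene a [gene_observations()].
#' @param fit a list with `family` (`"BM"` or `"OU"`), `foreground` (tip
#'   label) and, for the OU family, posterior means `theta_F` and `theta_B`.
#' @return list with `direction` (`"up"` or `"down"`) and `tie` flag.
#' @export
classify_shift_direction <- function(gene, fit) {
  diff <- if (identical(fit$family, "OU")) {
    fit$theta_F - fit$theta_B
  } else {
    fg <- mean(gene$values[[fit$foreground]])
    bg <- vapply(gene$values[setdiff(names(gene$values), fit$foreground)],
                 mean, numeric(1L))
    fg - mean(bg)
  }
  list(direction = if (diff > 0) "up" else "down", tie = diff == 0)
}

#' Exact sign test for the up/down balance of shifts
#'
#' Two-sided exact binomial test of equal probability for up- and
#' downregulated shifts.
#'
#' @param n_up,n_down counts of up- and downregulated genes (sum >= 1).
#' @return the two-sided exact p-value.
#' @export
sign_test <- function(n_up, n_down) {
  stopifnot(n_up >= 0, n_down >= 0, n_up + n_down >= 1)
  stats::binom.test(n_up, n_up + n_down, p = 0.5,
                    alternative = "two.sided")$p.value
}

#' Compare expression variances of up- vs downregulated shift genes
#'
#' Two-sided Wilcoxon rank-sum test (exact for small samples without ties,
#' normal approximation with tie correction otherwise) of the per-gene
#' expression variances of the genes shifted up against those shifted down.
#'
#' @param up_variances,down_variances non-empty numeric vectors of per-gene
#'   variances.
#' @return the two-sided p-value.
#' @export
variance_shift_comparison <- function(up_variances, down_variances) {
  if (!length(up_variances) || !length(down_variances))
    stop_("both variance sets must be non-empty")
  suppressWarnings(stats::wilcox.test(up_variances, down_variances,
                                      alternative = "two.sided"))$p.value
}

#' Summarize shift results per species, family and direction
#'
#' Mirrors the study's bar-plot accounting: counts of significant shifts per
#' foreground species for each model family and direction.
#'
#' @param results a list of `shift_result` objects.
#' @return a data frame with columns `foreground`, `family`, `direction`,
#'   `count`.
#' @export
summarize_shifts <- function(results) {
  sig <- Filter(function(r) isTRUE(r$significant), results)
  if (!length(sig))
    return(data.frame(foreground = character(), family = character(),
                      direction = character(), count = integer()))
  df <- data.frame(foreground = vapply(sig, `[[`, "", "foreground"),
                   family = vapply(sig, `[[`, "", "family"),
                   direction = vapply(sig, `[[`, "", "direction"))
  out <- as.data.frame(table(df), stringsAsFactors = FALSE)
  names(out) <- c("foreground", "family", "direction", "count")
  out[out$count > 0, , drop = FALSE]
}
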