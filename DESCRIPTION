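Package: expevo
Title: Phylogenetic Models of Gene Expression Evolution with Within-Species Variance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian comparative analysis of gene expression evolution across a
    species phylogeny. Fits six competing models of species-mean expression
    evolution (equal means, independent means, Brownian motion, Brownian motion
    with a branch-specific rate shift, Ornstein-Uhlenbeck, and
    Ornstein-Uhlenbeck with a branch-specific optimum and rate shift), each with
    heterogeneous within-species replicate variances, by Metropolis-Hastings
    MCMC. Models are compared with stepping-stone marginal likelihoods, Bayes
    factors and model probabilities. Includes a Monte-Carlo test for conserved
    expression (sigma^2 = 0), tip-branch shift detection with direction calls,
    divergence-versus-time analytics, an Ornstein-Uhlenbeck estimation-bias
    simulation study across phylogeny sizes, and a synthetic-data generator
    emulating a five-species butterfly expression data set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
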