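# brute-force accumulation of rate x length over explicit root-to-tip edge
# sets, independent of the production path-matrix code
bm_cov_path_oracle <- function(tree, rates) {
  S <- ape::Ntip(tree)
  root <- S + 1L
  edge_of_child <- function(node) which(tree$edge[, 2] == node)
  paths <- lapply(seq_len(S), function(tip) {
    nodes <- ape::nodepath(tree, root, tip)
    vapply(nodes[-1], edge_of_child, integer(1L))
  })
  V <- matrix(0, S, S, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(rates[shared] * tree$edge.length[shared])
  }
  V
}

test_that("BM tip covariance accumulates shared-path variance", {
  t2 <- parse_newick("(A:1,B:1):0;")
  expect_equal(bm_tip_covariance(t2, 1),
               diag(2), ignore_attr = TRUE)

  t3 <- parse_newick("((A:1,B:1):1,C:2):0;")
  V <- bm_tip_covariance(t3, 2)
  expect_equal(unname(diag(V)), c(4, 4, 4))
  expect_equal(unname(V["A", "B"]), 2)
  expect_equal(unname(V["A", "C"]), 0)

  set.seed(5)
  tr <- fix_tree()
  rates <- exp(runif(nrow(tr$edge), -1, 1))
  expect_equal(bm_tip_covariance(tr, rates), bm_cov_path_oracle(tr, rates),
               tolerance = 1e-12)
})

test_that("OU tip moments have the stationary variance and exponential decay", {
  t3 <- parse_newick("((A:1,B:1):1,C:2):0;")
  m <- ou_tip_moments(t3, sigma2 = 2, alpha = 1, theta = 0)
  expect_equal(unname(diag(m$cov)), rep(1, 3))   # sigma^2 / (2 alpha)
  d <- ape::cophenetic.phylo(t3)
  expect_equal(m$cov, 1 * exp(-1 * d[rownames(m$cov), colnames(m$cov)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(m$mean), rep(0, 3))
  expect_error(ou_tip_moments(t3, 1, 1e-13, 0), "1e-12")
})

test_that("the mean-centered OU covariance approaches the BM covariance as alpha -> 0", {
  tr <- fix_tree()
  S <- ape::Ntip(tr)
  P <- diag(S) - 1 / S
  co <- ou_tip_moments(tr, sigma2 = 1, alpha = 1e-8, theta = 0)$cov
  cb <- bm_tip_covariance(tr, 1)
  num <- P %*% co %*% P
  den <- P %*% cb %*% P
  expect_lt(max(abs(num - den)) / max(abs(den)), 1e-5)
})

test_that("OU covariance matches an Euler-Maruyama simulation oracle", {
  # 3-taxon tree, constant optimum; simulate the SDE forward in small steps
  set.seed(8)
  alpha <- 0.5; sigma2 <- 1.5; theta <- 2
  n <- 50000; dt <- 0.004
  step <- function(x, t_len) {
    for (k in seq_len(round(t_len / dt)))
      x <- x + alpha * (theta - x) * dt + sqrt(sigma2 * dt) * rnorm(n)
    x
  }
  root <- rnorm(n, theta, sqrt(sigma2 / (2 * alpha)))   # stationary root
  anc_ab <- step(root, 1)                               # internal node at depth 1
  tipA <- step(anc_ab, 1); tipB <- step(anc_ab, 1); tipC <- step(root, 2)
  sim <- cbind(A = tipA, B = tipB, C = tipC)

  t3 <- parse_newick("((A:1,B:1):1,C:2):0;")
  m <- ou_tip_moments(t3, sigma2, alpha, theta)
  for (i in 1:3) for (j in i:3) {
    mc <- cov(sim[, i], sim[, j])
    se <- sd(sim[, i] * sim[, j]) / sqrt(n)  # rough SE of the cross-moment
    expect_lt(abs(mc - m$cov[i, j]), 3 * se + 2 * alpha * dt * m$cov[i, i])
  }
  expect_lt(max(abs(colMeans(sim) - m$mean)), 4 * sqrt(m$cov[1, 1] / n))
})

test_that("all six model likelihoods match the dense per-individual oracle", {
  set.seed(13)
  tr <- fix_tree()
  reps <- fix_reps(3L)
  gene <- simulate_gene(model_spec("BM"),
                        model_params(sigma2 = 0.8, delta2 = fix_delta2(),
                                     root = 3),
                        tr, reps, seed = 99)
  for (model in c("EQUAL_MEANS", "UNEQUAL_MEANS", "BM", "BM_SHIFT", "OU",
                  "OU_SHIFT")) {
    for (r in 1:25) {
      spec <- if (grepl("SHIFT", model)) model_spec(model, foreground = "doris")
              else model_spec(model)
      params <- random_params(model, tr$tip.label)
      a <- model_loglik(spec, params, gene, tr)
      b <- dense_loglik_oracle(spec, params, gene, tr)
      expect_equal(a, b, tolerance = 1e-10)
    }
  }
})

test_that("likelihood identities: trivial case, translation invariance, shift reduction", {
  # single species, one replicate at its mean under unit noise
  g1 <- gene_observations("g", list(A = 0), min_replicates = 1L)
  ll <- model_loglik(model_spec("EQUAL_MEANS"),
                     model_params(mu = 0, delta2 = c(A = 1)), g1)
  expect_equal(ll, -0.5 * log(2 * pi))

  tr <- fix_tree()
  gene <- simulate_gene(model_spec("BM"),
                        model_params(sigma2 = 1, delta2 = fix_delta2(), root = 4),
                        tr, fix_reps(4L), seed = 3)
  shifted <- gene
  shifted$values <- lapply(gene$values, function(v) v + 7.3)
  p_bm <- model_params(sigma2 = 0.6, delta2 = fix_delta2())
  expect_equal(model_loglik(model_spec("BM"), p_bm, shifted, tr),
               model_loglik(model_spec("BM"), p_bm, gene, tr),
               tolerance = 1e-9)

  # equal foreground/background parameters reproduce the base models exactly
  expect_equal(
    model_loglik(model_spec("BM_SHIFT", "sara"),
                 model_params(sigma2_B = 0.6, sigma2_F = 0.6,
                              delta2 = fix_delta2()), gene, tr),
    model_loglik(model_spec("BM"), p_bm, gene, tr))
  p_ou <- model_params(sigma2 = 1.1, alpha = 0.3, theta = 4,
                       delta2 = fix_delta2())
  expect_equal(
    model_loglik(model_spec("OU_SHIFT", "sara"),
                 model_params(sigma2_B = 1.1, sigma2_F = 1.1, alpha = 0.3,
                              theta_B = 4, theta_F = 4,
                              delta2 = fix_delta2()), gene, tr),
    model_loglik(model_spec("OU"), p_ou, gene, tr))
})

test_that("the likelihood is a proper density (quadrature over a 2-replicate gene)", {
  grid <- seq(-6, 6, length.out = 121)
  h <- grid[2] - grid[1]
  spec <- model_spec("EQUAL_MEANS")
  params <- model_params(mu = 0, delta2 = c(A = 1))
  dens <- outer(grid, grid, Vectorize(function(x1, x2)
    exp(model_loglik(spec, params,
                     gene_observations("g", list(A = c(x1, x2))), NULL))))
  expect_equal(sum(dens) * h^2, 1, tolerance = 1e-3)
})

test_that("simulation matches the model moments", {
  tr2 <- parse_newick("(A:4,B:4):0;")
  reps1 <- c(A = 1L, B = 1L)
  tiny_d2 <- c(A = 1e-12, B = 1e-12)

  # sigma^2 = 0: species means collapse onto the root state
  g0 <- simulate_gene(model_spec("BM"),
                      model_params(sigma2 = 0, delta2 = tiny_d2, root = 2.5),
                      tr2, reps1, seed = 1)
  expect_equal(attr(g0, "species_means"), c(A = 2.5, B = 2.5))

  # divergence law: Var(meanA - meanB) = 2 sigma^2 T under drift
  set.seed(17)
  sims <- replicate(4000, {
    g <- simulate_gene(model_spec("BM"),
                       model_params(sigma2 = 1, delta2 = tiny_d2, root = 0),
                       tr2, reps1)
    m <- attr(g, "species_means"); m[["A"]] - m[["B"]]
  })
  v <- var(sims)
  expect_lt(abs(v - 8), 3 * 8 * sqrt(2 / (length(sims) - 1)))
  expect_lt(abs(mean(abs(sims)) - expected_abs_divergence_bm(1, 4)),
            3 * sd(abs(sims)) / sqrt(length(sims)))

  # OU at large alpha x depth: tip variance is the stationary value
  set.seed(18)
  tips <- replicate(4000, {
    g <- simulate_gene(model_spec("OU"),
                       model_params(sigma2 = 2, alpha = 1, theta = 5,
                                    delta2 = tiny_d2),
                       tr2, reps1)
    attr(g, "species_means")[["A"]]
  })
  expect_lt(abs(var(tips) - 1), 3 * 1 * sqrt(2 / (length(tips) - 1)))
})

test_that("simulated genes are most likely at their generating parameters", {
  set.seed(23)
  tr <- fix_tree()
  true_p <- model_params(sigma2 = 1, delta2 = fix_delta2(), root = 4)
  pert_p <- model_params(sigma2 = 5, delta2 = fix_delta2() * 3)
  spec <- model_spec("BM")
  diffs <- replicate(500, {
    g <- simulate_gene(spec, true_p, tr, fix_reps(4L))
    model_loglik(spec, true_p, g, tr) - model_loglik(spec, pert_p, g, tr)
  })
  expect_gt(mean(diffs), 0)
})

test_that("model specs and parameters serialize through JSON", {
  spec <- model_spec("OU_SHIFT", foreground = "erato")
  params <- model_params(sigma2_B = 1, sigma2_F = 2, alpha = 0.3, theta_B = 4,
                         theta_F = 6, delta2 = fix_delta2())
  rt <- params_from_json(params_to_json(spec, params))
  expect_equal(rt$spec$model, "OU_SHIFT")
  expect_equal(rt$spec$foreground, "erato")
  expect_equal(rt$params$delta2, params$delta2)
  expect_equal(rt$params$theta_F, 6)

  expect_error(model_spec("BM_SHIFT"), "foreground")
  expect_error(model_params(), NA)  # empty block is constructible...
  expect_error(                     # ...but unusable where parameters are needed
    model_loglik(model_spec("BM"), model_params(delta2 = fix_delta2()),
                 simulate_gene(model_spec("EQUAL_MEANS"),
                               model_params(mu = 0, delta2 = fix_delta2()),
                               NULL, fix_reps(2L), seed = 1),
                 fix_tree()),
    "sigma2")
})
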