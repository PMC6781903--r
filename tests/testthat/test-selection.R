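test_that("phylogenetic signal is recovered from drift-simulated genes", {
  tr <- fix_tree()
  wins <- vapply(1:10, function(i) {
    g <- simulate_gene(model_spec("BM"),
                       model_params(sigma2 = 1, delta2 = fix_delta2(), root = 4),
                       tr, fix_reps(8L), seed = 500 + i)
    ps <- test_phylo_signal(g, tr, settings = short_settings(i), stones = 16)
    ps$pairwise["bm_vs_unequal"] > 0.75
  }, logical(1))
  expect_gt(sum(wins), 5)
})

test_that("genes with identical species means favor the global-mean model", {
  tr <- fix_tree()
  wins <- vapply(1:10, function(i) {
    g <- simulate_gene(model_spec("EQUAL_MEANS"),
                       model_params(mu = 4, delta2 = fix_delta2()),
                       NULL, fix_reps(8L), seed = 600 + i)
    ps <- test_phylo_signal(g, tr, settings = short_settings(i), stones = 16)
    ps$pairwise["unequal_vs_equal"] < 0.5
  }, logical(1))
  expect_gt(sum(wins), 5)
})

test_that("anti-phylogenetic mean patterns erode the support for drift", {
  # Sister species pushed maximally apart while distant species stay equal:
  # the opposite of what the tree covariance predicts. With five species the
  # one-parameter drift model remains hard to beat outright (it absorbs any
  # mean pattern at a large enough rate), so the check is directional: drift
  # loses its positive support on such data, and its support is far below
  # what drift-simulated genes command.
  tr <- fix_tree()
  anti <- stats::setNames(c(0, 18, -18, 0, 0), tr$tip.label) # sara/charithonia split
  p_anti <- vapply(1:6, function(i) {
    g <- simulate_gene(model_spec("UNEQUAL_MEANS"),
                       model_params(mu_i = anti, delta2 = fix_delta2(0.1)),
                       NULL, fix_reps(8L), seed = 700 + i)
    ps <- test_phylo_signal(g, tr,
                            settings = short_settings(i, iterations = 2000,
                                                      burnin = 300, thin = 5),
                            stones = 32)
    ps$pairwise["bm_vs_unequal"]
  }, numeric(1))
  p_drift <- vapply(1:6, function(i) {
    g <- simulate_gene(model_spec("BM"),
                       model_params(sigma2 = 1, delta2 = fix_delta2(0.1),
                                    root = 4),
                       tr, fix_reps(8L), seed = 720 + i)
    ps <- test_phylo_signal(g, tr, settings = short_settings(i), stones = 16)
    ps$pairwise["bm_vs_unequal"]
  }, numeric(1))
  expect_lt(median(p_anti), 0.75)            # positive support for drift is gone
  expect_gt(median(p_drift), median(p_anti)) # and clearly lower than under drift
})

test_that("the conserved-gene test separates sigma2 = 0 from fast drift", {
  tr <- fix_tree()
  g0 <- simulate_gene(model_spec("EQUAL_MEANS"),
                      model_params(mu = 4, delta2 = fix_delta2()),
                      NULL, fix_reps(8L), seed = 801)
  r0 <- conserved_gene_test(g0, tr, settings = short_settings(1),
                            n_sim = 100, sim_settings = tiny_settings(1))
  expect_true(r0$conserved)
  expect_identical(r0$conserved, r0$empirical_sigma2 <= r0$threshold)

  g5 <- simulate_gene(model_spec("BM"),
                      model_params(sigma2 = 5, delta2 = fix_delta2(), root = 4),
                      tr, fix_reps(8L), seed = 802)
  r5 <- conserved_gene_test(g5, tr, settings = short_settings(2),
                            n_sim = 100, sim_settings = tiny_settings(2))
  expect_false(r5$conserved)

  expect_error(conserved_gene_test(g0, tr, n_sim = 50), "at least 100")
  # the study's screen: one empirical + n_sim analyses per gene
  expect_identical(conserved_test_workload(2393, 1000), 2395393)
})

test_that("a strong foreground rate shift is detected on the right tip only", {
  tr <- fix_tree()
  g <- simulate_gene(model_spec("BM_SHIFT", "erato"),
                     model_params(sigma2_B = 0.2, sigma2_F = 20,
                                  delta2 = fix_delta2(), root = 4),
                     tr, fix_reps(8L), seed = 904)
  res <- lapply(tr$tip.label, function(tip)
    branch_shift_test(g, tr, tip, "BM",
                      settings = short_settings(match(tip, tr$tip.label)),
                      stones = 16))
  names(res) <- tr$tip.label
  expect_true(res$erato$significant)
  expect_equal(res$erato$direction, "down")
  for (tip in setdiff(tr$tip.label, "erato"))
    expect_false(res[[tip]]$significant)
  # label-equivariance of the likelihood under consistent relabeling
  perm <- c(charithonia = "sara", sara = "charithonia", erato = "erato",
            doris = "melpomene", melpomene = "doris")
  tr_p <- tr; tr_p$tip.label <- unname(perm[tr$tip.label])
  g_p <- g; names(g_p$values) <- unname(perm[names(g$values)])
  spec <- model_spec("BM_SHIFT", "erato")
  params <- model_params(sigma2_B = 0.3, sigma2_F = 6, delta2 = fix_delta2())
  params$delta2 <- stats::setNames(params$delta2, unname(perm[names(params$delta2)]))
  expect_equal(model_loglik(spec, params, g_p, tr_p),
               model_loglik(spec, model_params(sigma2_B = 0.3, sigma2_F = 6,
                                               delta2 = fix_delta2()), g, tr))
})

test_that("plain drift rarely triggers a shift call", {
  tr <- fix_tree()
  fp <- vapply(1:8, function(i) {
    g <- simulate_gene(model_spec("BM"),
                       model_params(sigma2 = 0.5, delta2 = fix_delta2(), root = 4),
                       tr, fix_reps(8L), seed = 1000 + i)
    branch_shift_test(g, tr, "doris", "BM", settings = short_settings(i),
                      stones = 16)$significant
  }, logical(1))
  expect_lt(sum(fp), 4)
})

test_that("an optimum shift is detected by the OU family with the right direction", {
  tr <- fix_tree()
  res <- lapply(1:8, function(i) {
    g <- simulate_gene(model_spec("OU_SHIFT", "sara"),
                       model_params(sigma2_B = 0.5, sigma2_F = 0.5, alpha = 1,
                                    theta_B = 5, theta_F = 2,
                                    delta2 = fix_delta2(0.2)),
                       tr, fix_reps(8L), seed = 1100 + i)
    branch_shift_test(g, tr, "sara", "OU",
                      settings = short_settings(i, iterations = 900,
                                                burnin = 300),
                      stones = 16)
  })
  sig <- vapply(res, `[[`, logical(1), "significant")
  dirs <- vapply(res[sig], `[[`, character(1), "direction")
  expect_gt(sum(sig), 4)
  expect_true(all(dirs == "down"))
})

test_that("shift directions follow the documented conventions", {
  g <- gene_observations("g", list(A = c(2, 2), B = c(5, 5), C = c(5.2, 5.2),
                                   D = c(4.8, 4.8), E = c(5.1, 5.1)))
  d <- classify_shift_direction(g, list(family = "BM", foreground = "A"))
  expect_equal(d$direction, "down"); expect_false(d$tie)

  d2 <- classify_shift_direction(g, list(family = "OU", theta_F = 6, theta_B = 1))
  expect_equal(d2$direction, "up")

  gt <- gene_observations("g", list(A = c(5, 5), B = c(5, 5)))
  dt <- classify_shift_direction(gt, list(family = "BM", foreground = "A"))
  expect_equal(dt$direction, "down"); expect_true(dt$tie)
})

test_that("the sign test is exact, two-sided and symmetric", {
  expect_equal(sign_test(3, 3), 1)
  expect_equal(sign_test(0, 6), 2 * (1 / 2)^6)

  # brute-force two-sided binomial tail for (10, 30)
  n <- 40; k <- 10
  probs <- dbinom(0:n, n, 0.5)
  brute <- sum(probs[probs <= dbinom(k, n, 0.5) * (1 + 1e-7)])
  expect_equal(sign_test(10, 30), brute)

  for (ab in list(c(2, 9), c(0, 5), c(7, 7), c(12, 4)))
    expect_equal(sign_test(ab[1], ab[2]), sign_test(ab[2], ab[1]))
})

test_that("the rank-sum comparison of shift variances behaves as expected", {
  expect_equal(variance_shift_comparison(c(1, 2, 3), c(1, 2, 3)), 1,
               tolerance = 0.11)
  # complete separation at n = 3 vs 3: 2 * (1 / choose(6, 3))
  expect_equal(variance_shift_comparison(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_error(variance_shift_comparison(numeric(0), 1), "non-empty")

  set.seed(55)
  hits <- vapply(1:6, function(i) {
    up <- rlnorm(50, 0, 0.5)
    down <- rlnorm(50, log(4), 0.5)
    variance_shift_comparison(up, down) < 0.001
  }, logical(1))
  expect_gt(sum(hits), 3)
})

test_that("shift summaries count significant calls by species, family, direction", {
  mk <- function(fg, fam, dir, sig = TRUE)
    structure(list(gene_id = "g", foreground = fg, family = fam,
                   significant = sig, direction = dir),
              class = "shift_result")
  res <- list(mk("erato", "BM", "up"), mk("erato", "BM", "up"),
              mk("sara", "BM", "down"), mk("sara", "OU", "down"),
              mk("doris", "BM", "up", sig = FALSE))
  s <- summarize_shifts(res)
  expect_equal(s$count[s$foreground == "erato" & s$family == "BM" &
                         s$direction == "up"], 2L)
  expect_equal(sum(s$count), 4L)
})
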