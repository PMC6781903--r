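make_toy_table <- function(dir, fpkm) {
  path <- file.path(dir, "expr.tsv")
  df <- data.frame(gene = rownames(fpkm), fpkm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_map <- function(samples, species) {
  stats::setNames(species, samples)
}

test_that("expression loader applies the expressed-everywhere filter", {
  dir <- withr::local_tempdir()
  fpkm <- matrix(c(2, 4, 8, 1, 3, 9, 5, 6, 7, 2, 2, 2), nrow = 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  map <- toy_map(paste0("s", 1:4), c("A", "A", "B", "B"))
  ds <- load_expression_table(make_toy_table(dir, fpkm), map)
  expect_equal(nrow(ds$mat), 3L)
  expect_equal(ds$mat, log2(fpkm))

  # a zero FPKM anywhere drops the gene
  fpkm0 <- fpkm; fpkm0["g2", "s3"] <- 0
  expect_message(
    ds0 <- load_expression_table(make_toy_table(dir, fpkm0), map),
    "dropped 1")
  expect_equal(rownames(ds0$mat), c("g1", "g3"))
  expect_equal(attr(ds0, "n_dropped"), 1L)
})

test_that("loader errors name the offending coordinates", {
  dir <- withr::local_tempdir()
  fpkm <- matrix(c("2", "4", "oops", "1"), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  path <- file.path(dir, "bad.tsv")
  write.table(data.frame(gene = rownames(fpkm), fpkm, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_expression_table(path, toy_map(c("s1", "s2"), c("A", "A"))),
               "g1.*s2|s2.*g1")

  fpkm2 <- matrix(c(2, 4, 3, 1), nrow = 2,
                  dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(load_expression_table(make_toy_table(dir, fpkm2),
                                     toy_map("s1", "A")),
               "without a species assignment")
})

test_that("a study-scale synthetic table loads with the gene count preserved", {
  dir <- withr::local_tempdir()
  set.seed(4)
  n_genes <- 2373; reps <- default_replicates()
  fpkm <- matrix(rlnorm(n_genes * sum(reps), log(50), 1), n_genes,
                 dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                 paste0("s", seq_len(sum(reps)))))
  map <- toy_map(colnames(fpkm), rep(names(reps), reps))
  ds <- load_expression_table(make_toy_table(dir, fpkm), map)
  expect_equal(dim(ds$mat), c(2373L, 49L))
})

test_that("within-species variance uses the unbiased estimator and is shift-invariant", {
  g <- gene_observations("g", list(A = c(1, 1, 1), B = c(0, 2)))
  v <- within_species_variance(g)
  expect_equal(unname(v), c(0, 2))

  g2 <- gene_observations("g", list(A = c(1, 1, 1) + 5, B = c(0, 2) - 3))
  expect_equal(within_species_variance(g2), v)

  expect_error(gene_observations("g", list(A = 1, B = c(0, 2))), "fewer than 2")
})

test_that("variance estimates recover heterogeneous generating values", {
  set.seed(11)
  d2_true <- c(A = 0.2, B = 1.5)
  n_rep <- 8; n_genes <- 1000
  est <- replicate(n_genes, within_species_variance(gene_observations("g",
    list(A = rnorm(n_rep, 0, sqrt(d2_true["A"])),
         B = rnorm(n_rep, 5, sqrt(d2_true["B"]))))))
  # mean sample variance is unbiased; 4 SEs of the Monte-Carlo mean
  for (sp in c("A", "B")) {
    se <- d2_true[sp] * sqrt(2 / (n_rep - 1)) / sqrt(n_genes)
    expect_lt(abs(mean(est[sp, ]) - d2_true[sp]), 4 * se)
  }
})

test_that("variance correlation matrix behaves at its edge cases", {
  # two species with identical per-gene variance vectors correlate at 1
  set.seed(21)
  base <- matrix(rnorm(40 * 3, sd = rep(sqrt(exp(rnorm(40))), each = 3)),
                 nrow = 40, byrow = TRUE)
  mat <- cbind(base, base)  # species B duplicates species A's replicates
  dimnames(mat) <- list(sprintf("g%02d", 1:40), paste0("s", 1:6))
  ds <- expression_dataset(mat, toy_map(paste0("s", 1:6),
                                        rep(c("A", "B"), each = 3)))
  R <- variance_correlation_matrix(ds)
  expect_equal(R["A", "B"], 1)
  expect_equal(R, t(R))

  # gene reordering leaves the matrix unchanged
  perm <- sample(nrow(mat))
  dsp <- expression_dataset(mat[perm, ], ds$species)
  expect_equal(variance_correlation_matrix(dsp), R)

  # a constant variance vector yields NA, not zero
  matc <- mat
  matc[, 4:6] <- matrix(rep(c(0, 1, 2), nrow(mat)), ncol = 3, byrow = TRUE)
  dsc <- expression_dataset(matc, ds$species)
  Rc <- variance_correlation_matrix(dsc)
  expect_true(is.na(Rc["A", "B"]))
})

test_that("independently drawn variances decorrelate as the gene count grows", {
  set.seed(31)
  n_genes <- 10000
  mat <- cbind(
    matrix(rnorm(n_genes * 4, sd = rep(sqrt(rlnorm(n_genes, 0, 0.7)), each = 4)),
           nrow = n_genes, byrow = TRUE),
    matrix(rnorm(n_genes * 4, sd = rep(sqrt(rlnorm(n_genes, 0, 0.7)), each = 4)),
           nrow = n_genes, byrow = TRUE))
  dimnames(mat) <- list(sprintf("g%05d", seq_len(n_genes)), paste0("s", 1:8))
  ds <- expression_dataset(mat, toy_map(paste0("s", 1:8),
                                        rep(c("A", "B"), each = 4)))
  R <- variance_correlation_matrix(ds)
  expect_lt(abs(R["A", "B"]), 0.05)
})

test_that("study-regime synthetic data keep cross-species variance correlations small", {
  b <- generate_dataset(n_genes = 400, seed = 77)
  R <- variance_correlation_matrix(b$dataset)
  off <- R[upper.tri(R)]
  expect_true(all(abs(off) < 0.25))
  expect_lt(abs(mean(off)), 0.1)
})
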