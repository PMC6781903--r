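#!/usr/bin/env Rscript
# Phylogenetic-signal screen: for a subset of genes, compare the two
# non-phylogenetic models (identical / independent species means) against
# Brownian drift by stepping-stone marginal likelihoods, and count genes with
# positive support (model probability > 0.75, Bayes factor > 3) for drift.

suppressPackageStartupMessages(library(expevo))

tree <- fixture_tree()
ds <- load_expression_table("results/data/study_fpkm.tsv",
                            "results/data/study_species.tsv")
genes <- head(rownames(ds$mat), 40L)
settings <- function(s) mcmc_settings(burnin = 200, tune_interval = 50,
                                      iterations = 1000, thin = 5, seed = s)

rows <- lapply(seq_along(genes), function(i) {
  g <- get_gene(ds, genes[i])
  ps <- test_phylo_signal(g, tree, settings = settings(i), stones = 32)
  data.frame(gene = genes[i],
             logml_equal = ps$logml[["EQUAL_MEANS"]],
             logml_unequal = ps$logml[["UNEQUAL_MEANS"]],
             logml_bm = ps$logml[["BM"]],
             p_bm_vs_unequal = ps$pairwise[["bm_vs_unequal"]],
             p_bm_vs_equal = ps$pairwise[["bm_vs_equal"]],
             p_unequal_vs_equal = ps$pairwise[["unequal_vs_equal"]])
})
tab <- do.call(rbind, rows)
write.table(tab, "results/phylo_signal.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

signal <- tab$p_bm_vs_unequal > 0.75 & tab$p_bm_vs_equal > 0.75
cat(sprintf("%d / %d genes show positive support for a phylogenetic (drift) model\n",
            sum(signal), nrow(tab)))
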