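# Synthetic-data generator: datasets with the statistical structure the
# analysis assumes (five species, heterogeneous within-species variances,
# genes drawn from a mixture of evolutionary regimes) plus the ground truth
# needed for calibration and recovery experiments.

#' The five-species study tree
#'
#' A rooted ultrametric 5-taxon phylogeny patterned on the butterfly system
#' the analysis was designed around: root height 11.8 million years, youngest
#' split 5.5 MY, topology grouping erato with (sara, charithonia) against
#' (doris, melpomene). The published range endpoints fix the root and the
#' youngest node; the two remaining internal node ages default to 8.7 and 9.0
#' MY and are configurable.
#'
#' @param ages named numeric vector of node ages (million years): `root`,
#'   `erato_clade`, `sara_charithonia`, `doris_melpomene`.
#' @return a `phylo` object with tips `charithonia`, `sara`, `erato`,
#'   `doris`, `melpomene`.
#' @export
fixture_tree <- function(ages = c(root = 11.8, erato_clade = 8.7,
                                  sara_charithonia = 5.5,
                                  doris_melpomene = 9.0)) {
  stopifnot(all(c("root", "erato_clade", "sara_charithonia",
                  "doris_melpomene") %in% names(ages)))
  if (ages["sara_charithonia"] >= ages["erato_clade"] ||
      ages["erato_clade"] >= ages["root"] ||
      ages["doris_melpomene"] >= ages["root"])
    stop_("node ages must be nested: sara_charithonia < erato_clade < root, doris_melpomene < root")
  txt <- sprintf(
    "((erato:%g,(sara:%g,charithonia:%g):%g):%g,(doris:%g,melpomene:%g):%g);",
    ages["erato_clade"], ages["sara_charithonia"], ages["sara_charithonia"],
    ages["erato_clade"] - ages["sara_charithonia"],
    ages["root"] - ages["erato_clade"],
    ages["doris_melpomene"], ages["doris_melpomene"],
    ages["root"] - ages["doris_melpomene"])
  parse_newick(txt)
}

#' Study replicate layout
#'
#' Per-species replicate totals pooled over the two sexes (females + males):
#' charithonia 6+6, sara 5+6, erato 3+3, doris 6+6, melpomene 4+4 — 49
#' samples in all.
#'
#' @return named integer vector of replicates per species.
#' @export
default_replicates <- function() {
  c(charithonia = 12L, sara = 11L, erato = 6L, doris = 12L, melpomene = 8L)
}

# F/M split of a per-species total, mirroring the paired-sex sampling design
.sex_split <- function(n) c(F = ceiling(n / 2), M = floor(n / 2))

#' Generate a synthetic expression data set with known ground truth
#'
#' Each gene draws a regime from `mixture`, then parameters from the
#' configured ranges, and is simulated with [simulate_gene()]:
#' * `conserved`: all species means identical (sigma^2 = 0), only
#'   within-species noise;
#' * `drift`: Brownian motion with rate `sigma2` drawn log-uniformly from
#'   `sigma2_range`;
#' * `ou`: stationary Ornstein-Uhlenbeck (stabilizing selection);
#' * `shift_up` / `shift_down`: Brownian drift plus a directional expression
#'   shift of `shift_size` log2 units (sign per regime) on one uniformly
#'   chosen foreground tip.
#'
#' Within-species variances `delta2_i` are drawn log-normally, independently
#' for every gene and species — heterogeneous and uncorrelated across
#' species, reproducing the premise the variance-heterogeneity check tests.
#' Sample names carry an F/M group label so replicate counts mirror the
#' paired-sex sampling design; sex is not modeled.
#'
#' @param tree a rooted ultrametric `phylo` (default [fixture_tree()]).
#' @param n_genes number of genes.
#' @param mixture named regime proportions (must sum to 1) over
#'   `conserved`, `drift`, `ou`, `shift_up`, `shift_down`. The default
#'   mirrors the study's findings: 3% conserved, 81% drift, 16% shifted.
#' @param replicates named replicate counts per species (2..12 each).
#' @param mu_range range of the root/global mean (log2 FPKM), drawn uniformly.
#' @param sigma2_range log-uniform range of the drift rate.
#' @param ou_alpha_range,ou_sigma2_range log-uniform OU parameter ranges.
#' @param shift_size_range uniform range of the absolute shift (log2 units).
#' @param delta2_meanlog,delta2_sdlog log-normal parameters of the
#'   within-species variances.
#' @param seed integer seed; the same seed yields a byte-identical data set.
#' @return list with `dataset` (an [expression_dataset()]) and `truth` (data
#'   frame: `gene`, `regime`, `foreground`, `mu`, `sigma2`, `alpha`, `theta`,
#'   `shift`, plus one `delta2_<species>` column per species).
#' @export
generate_dataset <- function(tree = fixture_tree(), n_genes = 500L,
                             mixture = c(conserved = 0.03, drift = 0.81,
                                         ou = 0, shift_up = 0.08,
                                         shift_down = 0.08),
                             replicates = default_replicates(),
                             mu_range = c(1, 9),
                             sigma2_range = c(0.05, 5),
                             ou_alpha_range = c(0.1, 1),
                             ou_sigma2_range = c(0.5, 5),
                             shift_size_range = c(2, 5),
                             delta2_meanlog = log(0.3), delta2_sdlog = 0.7,
                             seed = 1L) {
  regimes <- c("conserved", "drift", "ou", "shift_up", "shift_down")
  if (!setequal(names(mixture), regimes) || any(mixture < 0) ||
      abs(sum(mixture) - 1) > 1e-8)
    stop_("mixture must be named proportions over {%s} summing to 1",
          paste(regimes, collapse = ", "))
  species <- tree$tip.label
  if (!setequal(names(replicates), species))
    stop_("replicates must be named by the tree tips")
  if (any(replicates < 2L) || any(replicates > 12L))
    stop_("replicate counts must lie in [2, 12]")
  set.seed(seed)

  regime <- sample(regimes, n_genes, replace = TRUE, prob = mixture[regimes])
  genes <- sprintf("g%04d", seq_len(n_genes))
  nsamp <- sum(replicates)
  mat <- matrix(NA_real_, n_genes, nsamp)
  truth <- data.frame(gene = genes, regime = regime,
                      foreground = NA_character_, mu = NA_real_,
                      sigma2 = NA_real_, alpha = NA_real_, theta = NA_real_,
                      shift = NA_real_)
  d2 <- matrix(NA_real_, n_genes, length(species),
               dimnames = list(NULL, paste0("delta2_", species)))

  for (i in seq_len(n_genes)) {
    delta2 <- stats::setNames(
      stats::rlnorm(length(species), delta2_meanlog, delta2_sdlog), species)
    d2[i, ] <- delta2
    mu <- stats::runif(1L, mu_range[1L], mu_range[2L])
    truth$mu[i] <- mu
    g <- switch(regime[i],
      conserved = {
        simulate_gene(model_spec("EQUAL_MEANS"),
                      model_params(mu = mu, delta2 = delta2),
                      tree = NULL, replicates = replicates)
      },
      drift = {
        s2 <- rloguniform(1L, sigma2_range[1L], sigma2_range[2L])
        truth$sigma2[i] <- s2
        simulate_gene(model_spec("BM"),
                      model_params(sigma2 = s2, delta2 = delta2, root = mu),
                      tree, replicates)
      },
      ou = {
        s2 <- rloguniform(1L, ou_sigma2_range[1L], ou_sigma2_range[2L])
        a <- rloguniform(1L, ou_alpha_range[1L], ou_alpha_range[2L])
        truth$sigma2[i] <- s2; truth$alpha[i] <- a; truth$theta[i] <- mu
        simulate_gene(model_spec("OU"),
                      model_params(sigma2 = s2, alpha = a, theta = mu,
                                   delta2 = delta2),
                      tree, replicates)
      },
      { # shift_up / shift_down: drift plus a signed tip offset
        s2 <- rloguniform(1L, sigma2_range[1L], sigma2_range[2L])
        fg <- sample(species, 1L)
        sz <- stats::runif(1L, shift_size_range[1L], shift_size_range[2L]) *
          if (regime[i] == "shift_up") 1 else -1
        truth$sigma2[i] <- s2; truth$foreground[i] <- fg; truth$shift[i] <- sz
        g0 <- simulate_gene(model_spec("BM"),
                            model_params(sigma2 = s2, delta2 = delta2,
                                         root = mu),
                            tree, replicates)
        g0$values[[fg]] <- g0$values[[fg]] + sz
        g0
      })
    mat[i, ] <- unlist(g$values[species], use.names = FALSE)
  }

  sample_ids <- unlist(lapply(species, function(s) {
    sx <- .sex_split(replicates[[s]])
    c(sprintf("%s_F%d", s, seq_len(sx["F"])),
      sprintf("%s_M%d", s, seq_len(sx["M"])))
  }))
  dimnames(mat) <- list(genes, sample_ids)
  species_map <- stats::setNames(rep(species, replicates[species]), sample_ids)
  list(dataset = expression_dataset(mat, species_map),
       truth = cbind(truth, as.data.frame(d2)))
}

#' Write a synthetic bundle to disk
#'
#' Emits a ready-to-analyze bundle: the expression matrix as TSV of FPKM
#' values (`2^log2`, so [load_expression_table()] round-trips it), the
#' two-column sample-to-species map, the ground-truth table, and a JSON
#' summary.
#'
#' @param bundle the list returned by [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the four file paths, invisibly.
#' @export
write_dataset <- function(bundle, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- bundle$dataset
  paths <- file.path(dir, paste0(prefix, c("_fpkm.tsv", "_species.tsv",
                                           "_truth.tsv", "_summary.json")))
  fpkm <- data.frame(gene = rownames(ds$mat), 2^ds$mat, check.names = FALSE)
  utils::write.table(fpkm, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(ds$species),
                                species = unname(ds$species)),
                     paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(n_genes = nrow(ds$mat),
                            n_samples = ncol(ds$mat),
                            species = as.list(table(ds$species)),
                            regimes = as.list(table(bundle$truth$regime))),
                       paths[4L], auto_unbox = TRUE)
  invisible(paths)
}
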