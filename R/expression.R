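# Expression matrices, the expressed-everywhere filter, per-gene extraction
# and the within-species variance heterogeneity check.

#' Construct an expression data set
#'
#' A genes x samples matrix of log2 FPKM values plus a sample-to-species
#' mapping. Every sample must map to a species, every species must have at
#' least two replicates (within-species variance must be estimable), and the
#' matrix must be complete.
#'
#' @param mat numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids), values on the log2 FPKM scale.
#' @param species_map named character vector mapping sample id -> species, or
#'   a two-column data frame (sample, species).
#' @return an object of class `expression_dataset` with elements `mat` and
#'   `species` (named character vector, one entry per sample).
#' @export
expression_dataset <- function(mat, species_map) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop_("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(mat))) stop_("duplicated gene identifiers")
  if (anyDuplicated(colnames(mat))) stop_("duplicated sample identifiers")
  if (anyNA(mat)) stop_("missing values in expression matrix")
  species <- .as_species_map(species_map)
  missing <- setdiff(colnames(mat), names(species))
  if (length(missing))
    stop_("samples without a species assignment: %s",
          paste(missing, collapse = ", "))
  species <- species[colnames(mat)]
  if (any(table(species) < 2L))
    stop_("every species needs >= 2 replicate samples; offending: %s",
          paste(names(which(table(species) < 2L)), collapse = ", "))
  structure(list(mat = mat, species = species), class = "expression_dataset")
}

.as_species_map <- function(species_map) {
  if (is.data.frame(species_map)) {
    if (ncol(species_map) < 2L) stop_("species map needs two columns (sample, species)")
    out <- as.character(species_map[[2L]])
    names(out) <- as.character(species_map[[1L]])
    return(out)
  }
  if (is.character(species_map) && !is.null(names(species_map)))
    return(species_map)
  stop_("species map must be a named character vector or a two-column data frame")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples, %d species\n",
              nrow(x$mat), ncol(x$mat), length(unique(x$species))))
  invisible(x)
}

#' Load an expression matrix from TSV
#'
#' Reads a tab-separated table (header row of sample ids, first column gene
#' ids, numeric body of FPKM values), drops genes not expressed in every
#' sample (FPKM > 0 everywhere -- the "present and expressed in all species"
#' rule), and log2-transforms the retained values. No pseudocount is used
#' since zeros are excluded by the filter. The number of dropped genes is
#' reported via `message()` and stored in attribute `n_dropped`.
#'
#' @param path path to the TSV expression table (raw FPKM values).
#' @param species_map sample-to-species mapping: a named character vector, a
#'   two-column data frame, or a path to a two-column TSV (sample, species).
#' @param log2_transform set to `FALSE` if the table already holds log2 values
#'   (the zero-expression filter is then skipped).
#' @return an `expression_dataset` (log2 FPKM scale).
#' @export
load_expression_table <- function(path, species_map, log2_transform = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop_("expression table needs a gene column plus samples")
  genes <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body),
                dimnames = list(genes, colnames(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_("non-numeric expression value at gene '%s', sample '%s'",
          genes[bad[1L]], colnames(num)[bad[2L]])
  }
  if (is.character(species_map) && is.null(names(species_map)) &&
      length(species_map) == 1L) {
    species_map <- utils::read.delim(species_map, header = TRUE, sep = "\t",
                                     colClasses = "character")
  }
  n_dropped <- 0L
  if (log2_transform) {
    keep <- apply(num > 0, 1L, all)
    n_dropped <- sum(!keep)
    if (n_dropped > 0L)
      message(sprintf("dropped %d gene(s) not expressed (FPKM > 0) in every sample",
                      n_dropped))
    num <- log2(num[keep, , drop = FALSE])
  }
  ds <- expression_dataset(num, species_map)
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Per-gene observations grouped by species
#'
#' @param gene_id gene identifier.
#' @param values named list, one numeric vector of replicate log2 FPKM values
#'   per species.
#' @param min_replicates minimum replicates per species (default 2 so that
#'   within-species variance is estimable).
#' @return an object of class `gene_observations`.
#' @export
gene_observations <- function(gene_id, values, min_replicates = 2L) {
  stopifnot(is.list(values), !is.null(names(values)))
  n <- vapply(values, length, integer(1L))
  if (any(n < min_replicates))
    stop_("species with fewer than %d replicates: %s", min_replicates,
          paste(names(values)[n < min_replicates], collapse = ", "))
  if (anyNA(unlist(values))) stop_("missing replicate values")
  structure(list(gene_id = as.character(gene_id), values = values),
            class = "gene_observations")
}

#' Extract one gene from a data set
#'
#' @param dataset an `expression_dataset`.
#' @param gene_id gene identifier present in the data set.
#' @return a `gene_observations` object.
#' @export
get_gene <- function(dataset, gene_id) {
  stopifnot(inherits(dataset, "expression_dataset"))
  i <- match(gene_id, rownames(dataset$mat))
  if (is.na(i)) stop_("gene '%s' not in data set", gene_id)
  gene_observations(gene_id,
                    split(dataset$mat[i, ], dataset$species))
}

#' Within-species variance of a gene
#'
#' Sample variance (unbiased, n-1 denominator) of the replicate log2 FPKM
#' values around their species mean, one value per species.
#'
#' @param gene a `gene_observations` object.
#' @return named numeric vector of per-species variances.
#' @export
within_species_variance <- function(gene) {
  stopifnot(inherits(gene, "gene_observations"))
  vapply(gene$values, stats::var, numeric(1L))
}

#' Cross-species correlation of per-gene expression variances
#'
#' For every species, the per-gene within-species variances form a vector
#' across genes; this returns the Pearson correlation matrix of those vectors
#' between all species pairs. Uncorrelated (heterogeneous) variances justify
#' treating the within-species variance as an independent per-species nuisance
#' parameter in the evolutionary models.
#'
#' @param dataset an `expression_dataset` with at least 3 genes.
#' @return symmetric species x species correlation matrix with unit diagonal;
#'   a species with a constant variance vector yields `NA` entries
#'   (correlation undefined), never 0.
#' @export
variance_correlation_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (nrow(dataset$mat) < 3L) stop_("need at least 3 genes")
  sp <- sort(unique(dataset$species))
  V <- sapply(sp, function(s) {
    cols <- dataset$species == s
    apply(dataset$mat[, cols, drop = FALSE], 1L, stats::var)
  })
  sds <- apply(V, 2L, stats::sd)
  R <- suppressWarnings(stats::cor(V, method = "pearson"))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- ifelse(sds == 0, NA_real_, 1)
  dimnames(R) <- list(sp, sp)
  R
}
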