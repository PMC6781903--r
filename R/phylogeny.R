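# Tree I/O and validation. Trees are rooted, ultrametric, time-calibrated
# (branch lengths in million years) and represented as ape "phylo" objects;
# all downstream code assumes the invariants enforced here.

#' Parse a rooted time-calibrated Newick tree
#'
#' Wraps [ape::read.tree()] and enforces the invariants the evolutionary
#' models rely on: the tree is rooted, every branch has a non-negative length,
#' tip labels are unique and non-empty, and (by default) the tree is
#' ultrametric within a relative tolerance of `1e-6` of the root height.
#' Branch lengths are interpreted as time (million years); non-ultrametric
#' input is an error, never silently rescaled.
#'
#' @param text a Newick string (with branch lengths, rooted).
#' @param ultrametric require ultrametricity (default `TRUE`).
#' @param tol relative ultrametricity tolerance.
#' @return an object of class `phylo`.
#' @examples
#' phy <- parse_newick("((A:1,B:1):1,C:2):0;")
#' @export
parse_newick <- function(text, ultrametric = TRUE, tol = 1e-6) {
  stopifnot(is.character(text), length(text) == 1L)
  .newick_scan(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop_("malformed Newick string (offset %d): could not be parsed", nchar(text))
  validate_phylogeny(phy, ultrametric = ultrametric, tol = tol)
  phy
}

# cheap structural scan so parse errors can name an offset
.newick_scan <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop_("malformed Newick string: unbalanced ')' at offset %d", i)
    }
  }
  if (depth != 0L)
    stop_("malformed Newick string: %d unclosed '(' at offset %d",
          depth, length(chars))
  if (!any(chars == ";"))
    stop_("malformed Newick string: missing terminating ';' at offset %d",
          length(chars))
  invisible(TRUE)
}

#' Validate a phylogeny against the model assumptions
#'
#' @param phy a `phylo` object.
#' @inheritParams parse_newick
#' @return `phy`, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(phy, ultrametric = TRUE, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop_("not a phylo object")
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length))
    stop_("every branch must carry an explicit branch length (no silent default)")
  if (any(phy$edge.length < 0)) stop_("negative branch lengths are not allowed")
  lab <- phy$tip.label
  if (any(!nzchar(lab))) stop_("empty tip labels are not allowed")
  if (anyDuplicated(lab)) stop_("duplicated tip labels: %s",
                                paste(lab[duplicated(lab)], collapse = ", "))
  if (!ape::is.rooted(phy)) stop_("tree must be rooted")
  if (ultrametric && ape::Ntip(phy) > 1L) {
    depth <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
    H <- max(depth)
    if (H <= 0) stop_("tree has zero height")
    if (max(abs(depth - H)) / H > tol)
      stop_("tree is not ultrametric within relative tolerance %g (max deviation %g of root height %g)",
            tol, max(abs(depth - H)), H)
  }
  invisible(phy)
}

#' Write a tree as Newick
#'
#' Inverse of [parse_newick()]; round-trips topology and branch lengths to
#' numeric printing precision.
#'
#' @param phy a `phylo` object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(phy, digits = 15) {
  ape::write.tree(phy, digits = digits)
}

#' Root height of an ultrametric tree
#' @param phy a `phylo` object.
#' @return time from root to tips (million years).
#' @export
tree_height <- function(phy) {
  max(ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))])
}

# Resolve a foreground branch key to the child-node id of that edge.
# A character key names a tip (tip edge); an integer key is a node id whose
# parent edge is the foreground branch.
resolve_foreground <- function(phy, foreground) {
  if (is.null(foreground)) return(NULL)
  if (is.character(foreground)) {
    i <- match(foreground, phy$tip.label)
    if (is.na(i)) stop_("foreground tip '%s' not found in tree", foreground)
    return(i)
  }
  node <- as.integer(foreground)
  if (!node %in% phy$edge[, 2L])
    stop_("foreground node %d has no parent edge in tree", node)
  node
}

# Precompute the traversal/covariance structures the C++ core consumes:
# preorder parent pointers, edge lengths, foreground flags, node heights, MRCA
# positions and the background/foreground shared root-path matrices.
tree_precompute <- function(phy, foreground = NULL) {
  S <- ape::Ntip(phy)
  nn <- S + phy$Nnode
  fg_node <- resolve_foreground(phy, foreground)

  phy_cw <- ape::reorder.phylo(phy, "cladewise") # parents precede children
  root <- S + 1L
  ord <- c(root, phy_cw$edge[, 2L])              # node ids in preorder
  pos <- integer(nn); pos[ord] <- seq_len(nn)    # node id -> preorder position

  parent <- integer(nn); elen <- numeric(nn); isfg <- integer(nn)
  parent[1L] <- 0L
  for (k in seq_len(nrow(phy_cw$edge))) {
    child <- phy_cw$edge[k, 2L]
    parent[pos[child]] <- pos[phy_cw$edge[k, 1L]]
    elen[pos[child]] <- phy_cw$edge.length[k]
    if (!is.null(fg_node) && child == fg_node) isfg[pos[child]] <- 1L
  }

  height_id <- ape::node.depth.edgelength(phy)
  height <- height_id[ord]

  mrca_id <- ape::mrca(phy, full = FALSE)        # S x S node ids, diag = tip
  mrcapos <- matrix(pos[mrca_id], S, S)
  tippos <- pos[seq_len(S)]

  # cumulative background/foreground path lengths root -> node, in preorder
  accb <- numeric(nn); accf <- numeric(nn)
  for (k in 2:nn) {
    accb[k] <- accb[parent[k]] + if (isfg[k]) 0 else elen[k]
    accf[k] <- accf[parent[k]] + if (isfg[k]) elen[k] else 0
  }
  Sb <- matrix(accb[mrcapos], S, S)
  Sf <- matrix(accf[mrcapos], S, S)

  list(S = S, Sb = Sb, Sf = Sf, parent = parent, elen = elen, isfg = isfg,
       tippos = tippos, mrcapos = mrcapos, height = height,
       tips = phy$tip.label, H = max(height[tippos]))
}
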