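# Tree input/output and the Brownian-motion covariance structure used by the
# regression modules. Trees are "phylo" objects (ape); all functions here
# validate rather than repair.

#' Read a phylogeny from a Newick file
#'
#' Reads a rooted tree with branch lengths. Branch lengths are mandatory:
#' a Newick string without them is rejected rather than given defaults.
#' Tip labels are normalized (whitespace trimmed, spaces to underscores)
#' and must be unique afterwards. Polytomies are preserved.
#'
#' @param path Path to a Newick file, or a Newick string ending in ";".
#' @return An object of class \code{phylo}.
#' @export
read_newick <- function(path) {
  txt <- if (grepl(";\\s*$", path[1]) && !file.exists(path[1])) path[1]
         else paste(readLines(path, warn = FALSE), collapse = "")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    stop_dc("Newick parse error in '", substr(txt, 1, 60), "...'")
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree A \code{phylo} object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Validate a phylogeny
#'
#' Checks the invariants assumed throughout the package: a single root,
#' non-negative branch lengths on every edge, and unique normalized tip
#' labels. Returns the tree with normalized tip labels.
#'
#' @param tree A \code{phylo} object.
#' @return The validated tree (tip labels normalized).
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_dc("not a 'phylo' object")
  if (is.null(tree$edge.length))
    stop_dc("tree has no branch lengths; branch lengths are required")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop_dc("tree has missing or negative branch lengths")
  tree$tip.label <- normalize_taxon_names(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop_dc("duplicate tip labels after normalization: ",
            paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                  collapse = ", "))
  tree
}

#' Root-to-tip depths
#'
#' @param tree A \code{phylo} object.
#' @return Named numeric vector of root-to-tip path lengths.
#' @export
tip_depths <- function(tree) {
  n <- ape::Ntip(tree)
  d <- ape::node.depth.edgelength(tree)[seq_len(n)] +
    (tree$root.edge %||% 0)
  names(d) <- tree$tip.label
  d
}

#' Check ultrametricity
#'
#' A tree is treated as ultrametric when the largest absolute deviation of
#' any root-to-tip depth from the mean depth is at most \code{tol}.
#'
#' @param tree A \code{phylo} object.
#' @param tol Absolute tolerance in branch-length units.
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- tip_depths(tree)
  max(abs(d - mean(d))) <= tol
}

#' Phylogenetic (Brownian-motion) covariance matrix
#'
#' Entry \code{[i, j]} is the root-to-MRCA path length shared by taxa i and
#' j; the diagonal holds root-to-tip depths. This is the trait covariance
#' implied by Brownian motion with unit rate.
#'
#' @param tree A \code{phylo} object.
#' @return Symmetric positive semi-definite matrix with taxa as dimnames.
#' @export
tree_vcv <- function(tree) {
  tree <- validate_tree(tree)
  # a root stem (kept by pruning so original depths survive) is shared by
  # every pair of taxa and adds uniformly to the covariance
  ape::vcv.phylo(tree) + (tree$root.edge %||% 0)
}

#' Prune a tree to a set of taxa
#'
#' Retains exactly the requested tips, collapsing degree-2 internal nodes
#' and summing their branch lengths so that root-to-tip depths and pairwise
#' MRCA depths of retained taxa are unchanged.
#'
#' @param tree A \code{phylo} object.
#' @param taxa Character vector of tip labels to keep (normalized form).
#' @return The pruned \code{phylo} object.
#' @export
prune_to_taxa <- function(tree, taxa) {
  tree <- validate_tree(tree)
  taxa <- normalize_taxon_names(taxa)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop_dc("taxa not in tree: ", paste(unknown, collapse = ", "))
  if (length(taxa) < 1) stop_dc("no taxa to keep")
  if (setequal(taxa, tree$tip.label)) return(tree)
  stem0 <- tree$root.edge %||% 0
  if (length(taxa) == 1) {
    d <- tip_depths(tree)[taxa]
    return(read_newick(sprintf("(%s:%.12g);", taxa, d)))
  }
  # depth of the retained taxa's MRCA becomes a root stem, so root-to-tip
  # depths and pairwise MRCA depths are unchanged by pruning
  mrca <- ape::getMRCA(tree, taxa)
  stem <- ape::node.depth.edgelength(tree)[mrca]
  pruned <- ape::keep.tip(tree, taxa)
  pruned$root.edge <- stem0 + stem
  pruned
}

#' Rescale a tree to unit height
#'
#' Divides all branch lengths by the mean root-to-tip depth. Used to
#' condition covariance matrices before inversion; regression slopes are
#' invariant to this scaling.
#'
#' @param tree A \code{phylo} object.
#' @return The rescaled tree.
#' @export
scale_tree_height <- function(tree) {
  h <- mean(tip_depths(tree))
  if (h <= 0) stop_dc("tree height is zero")
  tree$edge.length <- tree$edge.length / h
  if (!is.null(tree$root.edge)) tree$root.edge <- tree$root.edge / h
  tree
}
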