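# Faith's phylogenetic diversity with minimum-spanning-subtree semantics:
# the spanning subtree is rooted at the most recent common ancestor of the
# selected tips, so edges between that ancestor and the tree root are never
# counted (picante's pd(include.root = FALSE) convention).

#' Faith's phylogenetic diversity of a tip set
#'
#' Sums the branch lengths of the minimal connected subtree spanning the
#' given tips, rooted at their most recent common ancestor; edges above
#' that ancestor (towards the tree root, including any root edge) are
#' excluded. A set of zero or one tips has PD 0.
#'
#' An edge belongs to the spanning subtree exactly when its child subtree
#' contains some but not all of the selected tips: edges whose subtree
#' contains all of them form the MRCA-to-root path, and edges with none are
#' off the subtree. The count per edge is accumulated in one postorder pass.
#'
#' @param tree an `ape` `phylo` tree with branch lengths.
#' @param tips character vector of tip labels (subset of the tree's tips).
#' @return Non-negative branch-length sum.
#' @export
faithPD <- function(tree, tips) {
  tips <- unique(tips)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "))
  nsel <- length(tips)
  if (nsel <= 1) return(0)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  counts <- numeric(ntip + tree$Nnode)
  counts[match(tips, tree$tip.label)] <- 1
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  for (i in seq_along(parent))
    counts[parent[i]] <- counts[parent[i]] + counts[child[i]]
  keep <- counts[child] >= 1 & counts[child] < nsel
  sum(tree$edge.length[keep])
}

#' Total branch length of a tree
#'
#' Sum over every branch, including the root edge if one is present in the
#' Newick (a root edge can never be part of a root-excluded spanning
#' subtree, but it does belong to the whole-tree denominator).
#'
#' @param tree an `ape` `phylo` tree.
#' @return Branch-length sum.
#' @export
totalBranchLength <- function(tree) {
  tot <- sum(tree$edge.length)
  if (!is.null(tree$root.edge)) tot <- tot + tree$root.edge
  tot
}

#' Ensemble-mean rescaled phylogenetic diversity
#'
#' For each tree in the ensemble, Faith's PD of the tip set is divided by
#' that tree's total branch length; the per-tree ratios are then averaged
#' (rescale-then-average, so the result is invariant to uniform rescaling
#' of any tree's branch lengths). Set `perTree = FALSE` for the alternative
#' average-then-rescale convention (mean raw PD divided by mean total
#' length), exposed for sensitivity checks.
#'
#' @param ensemble a [TreeEnsemble-class] (or list of `phylo`).
#' @param tips character vector of tip labels.
#' @param perTree rescale within each tree before averaging (default TRUE).
#' @return list with `mean` (in \[0, 1\]) and across-tree `sd`.
#' @export
scaledPD <- function(ensemble, tips, perTree = TRUE) {
  trees <- if (is(ensemble, "TreeEnsemble")) ensemble@trees else ensemble
  pd <- vapply(trees, faithPD, numeric(1), tips = tips)
  tot <- vapply(trees, totalBranchLength, numeric(1))
  if (any(tot <= 0))
    stop("tree with non-positive total branch length in ensemble")
  if (perTree) {
    ratios <- pd / tot
    list(mean = mean(ratios), sd = if (length(ratios) > 1) sd(ratios) else 0)
  } else {
    list(mean = mean(pd) / mean(tot),
         sd = if (length(pd) > 1) sd(pd) / mean(tot) else 0)
  }
}
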