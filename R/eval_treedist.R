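# --- rooted-tree plumbing on ape::phylo objects -----------------------------

# parent vector, node depths (edges from root) and tips-below sets
phylo_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depth <- rep(NA_integer_, n_all)
  depth[root] <- 0L
  # edges from ape are parent-before-child only after reordering
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(ord)))
    depth[ord[e, 2]] <- depth[ord[e, 1]] + 1L
  list(n_tip = n_tip, root = root, parent = parent, depth = depth)
}

# path root -> node (node ids)
node_ancestry <- function(idx, node) {
  path <- node
  while (node != idx$root) {
    node <- idx$parent[node]
    path <- c(node, path)
  }
  path
}

# MRCA (deepest common ancestor) of a set of tip indices
mrca_of_tips <- function(idx, tips) {
  paths <- lapply(tips, node_ancestry, idx = idx)
  common <- Reduce(intersect, paths)
  common[which.max(idx$depth[common])]
}

# tip-label sets of all internal nodes (as sorted collapsed strings)
internal_clades <- function(tree) {
  idx <- phylo_index(tree)
  labels <- tree$tip.label
  below <- vector("list", idx$n_tip + tree$Nnode)
  for (t in seq_len(idx$n_tip)) below[[t]] <- labels[t]
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(post)))
    below[[post[e, 1]]] <- c(below[[post[e, 1]]], below[[post[e, 2]]])
  internal <- (idx$n_tip + 1L):(idx$n_tip + tree$Nnode)
  sets <- lapply(below[internal], function(s) sort(unique(s)))
  keep <- vapply(sets, function(s) length(s) >= 2 && length(s) < idx$n_tip, logical(1))
  unique(vapply(sets[keep], paste, character(1), collapse = "\r"))
}

#' Build a tip-labeled phylogeny from clone genotypes
#'
#' Reconstructs the rooted perfect phylogeny of a binary genotype matrix and
#' returns it as an `ape::phylo` tree in which every clone is a tip:
#' ancestral (internal-node) clones become pendant tips attached to their
#' genotype's node, the germline is the tip `"Normal"`, and clones with
#' identical genotypes yield duplicated tips.  This mirrors maximum
#' parsimony reconstruction from clone genotypes with germline outgroup
#' rooting, the canonical preparation for tree-distance scoring.
#'
#' @param genotypes Binary clones-by-SNVs matrix.
#' @param labels Character vector relabeling each clone row (named by clone
#'   id, or unnamed in row order); duplicated labels are allowed and produce
#'   duplicated tips.
#' @return An `ape::phylo` object.
#' @export
genotype_phylo <- function(genotypes, labels = rownames(genotypes)) {
  if (is.null(names(labels))) names(labels) <- rownames(genotypes)
  tree <- tree_from_genotypes(genotypes)
  build <- function(node) {
    parts <- character(0)
    for (ch in children_of(tree, node)) parts <- c(parts, build(ch))
    attached <- tree$node_labels[[node]]
    if (node == tree$root_id) attached <- setdiff(attached, tree$root_id)
    tips <- unlist(labels[attached], use.names = FALSE)
    if (node == tree$root_id) tips <- c(tips, "Normal")
    if (length(parts) == 0 && length(tips) == 1) return(tips)
    paste0("(", paste(c(parts, tips), collapse = ","), ")")
  }
  str <- build(tree$root_id)
  if (!startsWith(str, "(")) str <- paste0("(", str, ")")
  ape::read.tree(text = paste0(str, ";"))
}

#' Multi-label tree vector (TreeVec) distance
#'
#' Topology distance for rooted clone phylogenies whose tips carry clone
#' labels, with duplicated labels allowed.  Monophyletic clades of
#' identically labeled tips collapse to a single tip; this is realized
#' implicitly by assigning each label group the most recent common ancestor
#' (MRCA) of all its tips.  For every unordered pair of labels the number of
#' edges between the root and the MRCA of the two label groups is recorded;
#' the distance is the Euclidean norm of the difference between the two
#' trees' vectors, over the shared (union) label-pair ordering.  A label
#' absent from one tree contributes depth-0 entries in that tree.
#'
#' @param true_tree,inferred_tree Rooted `ape::phylo` trees with labeled
#'   tips (duplicates allowed).
#' @return Non-negative distance; 0 for identically shaped labeled trees.
#' @export
treevec_distance <- function(true_tree, inferred_tree) {
  labels <- sort(union(unique(true_tree$tip.label), unique(inferred_tree$tip.label)))
  if (length(labels) < 2) return(0)
  vec <- function(tree) {
    idx <- phylo_index(tree)
    groups <- split(seq_len(idx$n_tip), tree$tip.label)
    out <- numeric(0)
    for (i in seq_len(length(labels) - 1)) {
      for (j in (i + 1):length(labels)) {
        g1 <- groups[[labels[i]]]
        g2 <- groups[[labels[j]]]
        out <- c(out, if (is.null(g1) || is.null(g2)) 0
                 else idx$depth[mrca_of_tips(idx, c(g1, g2))])
      }
    }
    out
  }
  sqrt(sum((vec(true_tree) - vec(inferred_tree))^2))
}

#' Rooted Robinson--Foulds distance, normalized
#'
#' Enumerates the nontrivial rooted clades (tip-label sets of internal
#' nodes, excluding singletons and the full set) of both trees; the
#' distance is the size of the symmetric difference divided by the total
#' number of clades in the two trees, giving a value in [0, 1].  Both trees
#' must carry the same tip label set with no duplicates; inferred trees
#' with surplus tips should first go through [prune_inferred_tips()].
#'
#' @param true_tree,inferred_tree Rooted `ape::phylo` trees.
#' @return Number in [0, 1]; 0 for identical topologies (0 also when
#'   neither tree has a nontrivial clade).
#' @export
rf_distance <- function(true_tree, inferred_tree) {
  l1 <- true_tree$tip.label
  l2 <- inferred_tree$tip.label
  if (anyDuplicated(l1) || anyDuplicated(l2))
    stop("rf_distance requires unique tip labels; prune/relabel first")
  if (!setequal(l1, l2))
    stop("tip label sets differ: '",
         c(setdiff(l1, l2), setdiff(l2, l1))[1], "'")
  c1 <- internal_clades(true_tree)
  c2 <- internal_clades(inferred_tree)
  denom <- length(c1) + length(c2)
  if (denom == 0) return(0)
  (sum(!c1 %in% c2) + sum(!c2 %in% c1)) / denom
}

#' Prune an inferred tree to one tip per true clone
#'
#' RF distance needs equal tip sets, but mapped inferred trees often carry
#' several tips annotated with the same true clone.  This keeps, for every
#' true clone, the mapped inferred tip with the smallest genotype distance
#' (ties broken lexicographically by inferred clone id), relabels it with
#' the true clone id, and drops the rest.  The `"Normal"` germline tip is
#' always kept.
#'
#' @param inferred_tree An `ape::phylo` whose tips are inferred clone ids
#'   (plus `"Normal"`).
#' @param mapping A `clone_mapping` from [map_clones()].
#' @return An `ape::phylo` with tips = mapped true clone ids + `"Normal"`.
#' @export
prune_inferred_tips <- function(inferred_tree, mapping) {
  keep <- do.call(rbind, lapply(split(mapping, mapping$true), function(g) {
    g <- g[order(g$distance, g$inferred), , drop = FALSE]
    g[1, c("inferred", "true")]
  }))
  missing <- setdiff(keep$inferred, inferred_tree$tip.label)
  if (length(missing))
    stop("inferred clone '", missing[1], "' is not a tip of the inferred tree")
  out <- ape::keep.tip(inferred_tree, c(keep$inferred, "Normal"))
  out$tip.label <- ifelse(out$tip.label == "Normal", "Normal",
                          keep$true[match(out$tip.label, keep$inferred)])
  out
}
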