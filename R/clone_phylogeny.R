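#' Clone phylogeny with mutations assigned to branches
#'
#' A clone phylogeny is a rooted tree whose root is the germline (normal
#' cell) and whose other nodes are tumor clones.  Somatic mutations (SNVs)
#' are placed on branches: `branch_mutations[[clone]]` holds the SNVs
#' acquired on the branch leading into that clone.  Under the infinite-sites
#' assumption each SNV occurs on exactly one branch, so the genotype of a
#' clone is the union of the branch-mutation sets along its root path.
#'
#' @param parent_of Named character vector mapping each non-root clone to its
#'   parent node id.
#' @param branch_mutations Named list mapping each non-root clone to a
#'   character vector of SNV ids acquired on its incoming branch (may be
#'   empty, giving a zero-length branch).
#' @param root_id Identifier of the germline node (default `"Normal"`).
#' @param node_labels Optional named list attaching extra clone labels to
#'   nodes (used when clones with identical genotypes were merged onto one
#'   node during tree reconstruction).
#' @return An object of class `clone_phylogeny`.
#' @export
clone_phylogeny <- function(parent_of, branch_mutations, root_id = "Normal",
                            node_labels = NULL) {
  parent_of <- unlist(parent_of) %||% stats::setNames(character(0), character(0))
  if (length(parent_of) == 0)
    parent_of <- stats::setNames(character(0), character(0))
  children <- names(parent_of)
  if (length(parent_of) && (is.null(children) || any(children == "")))
    stop("parent_of must be a named vector (child -> parent)")
  if (root_id %in% children)
    stop("root '", root_id, "' must not have a parent")
  if (is.null(node_labels))
    node_labels <- stats::setNames(as.list(c(root_id, children)), c(root_id, children))
  tree <- structure(
    list(clone_ids = c(root_id, children),
         root_id = root_id,
         parent_of = parent_of,
         branch_mutations = lapply(branch_mutations, as.character)[children],
         node_labels = node_labels),
    class = "clone_phylogeny")
  validate_clone_phylogeny(tree)
  tree
}

#' Validate a clone phylogeny
#'
#' Checks the structural invariants: one germline root carrying no somatic
#' mutations, a parent relation that connects every node to the root without
#' cycles, and infinite sites (every SNV on exactly one branch).
#'
#' @param tree A `clone_phylogeny`.
#' @return The tree, invisibly; errors otherwise.
#' @export
validate_clone_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "clone_phylogeny"))
  children <- names(tree$parent_of)
  nodes <- c(tree$root_id, children)
  if (anyDuplicated(nodes))
    stop("duplicate node ids: ", nodes[duplicated(nodes)][1])
  if (!all(tree$parent_of %in% nodes))
    stop("parent not in tree: ", setdiff(tree$parent_of, nodes)[1])
  # acyclicity + connectivity: walk each node to the root
  for (n in children) {
    seen <- character(0)
    cur <- n
    while (cur != tree$root_id) {
      if (cur %in% seen) stop("cycle detected at node '", cur, "'")
      seen <- c(seen, cur)
      cur <- unname(tree$parent_of[[cur]])
    }
  }
  if (!setequal(names(tree$branch_mutations), children))
    stop("branch_mutations must cover exactly the non-root clones")
  muts <- unlist(tree$branch_mutations, use.names = FALSE)
  if (anyDuplicated(muts))
    stop("infinite-sites violation: SNV '", muts[duplicated(muts)][1],
         "' appears on more than one branch")
  invisible(tree)
}

#' @export
print.clone_phylogeny <- function(x, ...) {
  cat("clone_phylogeny: ", length(x$clone_ids), " nodes (root '", x$root_id,
      "'), ", length(tree_snvs(x)), " SNVs\n", sep = "")
  invisible(x)
}

#' All SNV ids carried by a clone phylogeny
#' @param tree A `clone_phylogeny`.
#' @return Character vector of SNV ids, in branch preorder.
#' @export
tree_snvs <- function(tree) {
  unlist(tree$branch_mutations[preorder_nodes(tree)[-1]], use.names = FALSE) %||% character(0)
}

# nodes in preorder (root first), children in insertion order
preorder_nodes <- function(tree) {
  kids <- split(names(tree$parent_of), unname(tree$parent_of))
  out <- character(0)
  stack <- tree$root_id
  while (length(stack)) {
    n <- stack[1]
    stack <- stack[-1]
    out <- c(out, n)
    stack <- c(kids[[n]], stack)
  }
  out
}

# root path of a node: root, ..., node
root_path <- function(tree, node) {
  path <- node
  while (node != tree$root_id) {
    node <- unname(tree$parent_of[[node]])
    path <- c(node, path)
  }
  path
}

children_of <- function(tree, node) {
  names(tree$parent_of)[tree$parent_of == node]
}

#' Clone genotypes implied by a phylogeny
#'
#' Converts a clone phylogeny into its binary clone-by-SNV genotype matrix:
#' entry (c, s) is 1 iff SNV s lies on the root path of clone c.  The
#' germline row (all zeros) is included.  Because genotypes accumulate along
#' root paths, an ancestor's mutation set is always a subset of every
#' descendant's.
#'
#' @param tree A valid `clone_phylogeny`.
#' @return Integer matrix, rows = clones (germline first, then preorder),
#'   columns = SNV ids.
#' @export
genotypes_from_tree <- function(tree) {
  validate_clone_phylogeny(tree)
  ord <- preorder_nodes(tree)
  snvs <- tree_snvs(tree)
  M <- matrix(0L, nrow = length(ord), ncol = length(snvs),
              dimnames = list(ord, snvs))
  for (n in ord[-1]) {
    p <- unname(tree$parent_of[[n]])
    M[n, ] <- M[p, ]
    M[n, tree$branch_mutations[[n]]] <- 1L
  }
  M
}

# genotype (SNV set) of one node
node_genotype <- function(tree, node) {
  path <- root_path(tree, node)
  unlist(tree$branch_mutations[setdiff(path, tree$root_id)], use.names = FALSE) %||% character(0)
}

# collapse zero-length branches (no mutations) into the parent node,
# merging labels; used before mutational-tree export
collapse_empty_branches <- function(tree) {
  repeat {
    empty <- names(tree$branch_mutations)[lengths(tree$branch_mutations) == 0]
    if (!length(empty)) return(tree)
    n <- empty[1]
    p <- unname(tree$parent_of[[n]])
    kids <- children_of(tree, n)
    tree$parent_of[kids] <- p
    tree$parent_of <- tree$parent_of[names(tree$parent_of) != n]
    tree$branch_mutations[[n]] <- NULL
    tree$node_labels[[p]] <- unique(c(tree$node_labels[[p]], tree$node_labels[[n]]))
    tree$node_labels[[n]] <- NULL
    tree$clone_ids <- setdiff(tree$clone_ids, n)
  }
}
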