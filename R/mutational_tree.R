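#' Export a clone phylogeny as a mutational-tree table
#'
#' Produces the tabular parent/child + mutation-list representation consumed
#' by external multi-labeled tree edit distance (MLTED) implementations.
#' MLTED requires the inferred tree to carry the same SNV universe as the
#' true tree, so any SNV in `universe` that is absent from the tree (e.g.
#' dropped by an inference method) is appended to the root's mutation list.
#' Zero-length branches (no mutations) are collapsed before export.
#'
#' @param tree A `clone_phylogeny`.
#' @param universe Character vector of SNV ids; must contain every SNV of
#'   the tree.  Defaults to exactly the tree's SNVs.
#' @return A data.frame with columns `node_id`, `parent_id` (root's parent
#'   is `"-"`) and `mutations` (comma-separated SNV list, `""` if none).
#' @export
export_mutational_tree <- function(tree, universe = tree_snvs(tree)) {
  validate_clone_phylogeny(tree)
  snvs <- tree_snvs(tree)
  extra <- setdiff(snvs, universe)
  if (length(extra))
    stop("SNV '", extra[1], "' is in the tree but not in the universe")
  tree <- collapse_empty_branches(tree)
  ord <- preorder_nodes(tree)
  muts <- lapply(ord, function(n) {
    if (n == tree$root_id) setdiff(universe, snvs) else tree$branch_mutations[[n]]
  })
  data.frame(
    node_id = ord,
    parent_id = c("-", unname(tree$parent_of[ord[-1]]))[seq_along(ord)],
    mutations = vapply(muts, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
}

#' Parse a mutational-tree table back into a clone phylogeny
#'
#' Inverse of [export_mutational_tree()].  SNVs listed on the root row are
#' the "unassigned" mutations; they are returned in the `unassigned`
#' attribute, not placed on a branch.
#'
#' @param table Data frame with columns `node_id`, `parent_id`, `mutations`.
#' @return A `clone_phylogeny` with attribute `unassigned`.
#' @export
parse_mutational_tree <- function(table) {
  stopifnot(all(c("node_id", "parent_id", "mutations") %in% names(table)))
  root <- table$node_id[table$parent_id == "-"]
  if (length(root) != 1) stop("mutational tree must have exactly one root row")
  split_muts <- function(s) if (!nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
  kids <- table[table$parent_id != "-", , drop = FALSE]
  tree <- clone_phylogeny(
    stats::setNames(kids$parent_id, kids$node_id),
    stats::setNames(lapply(kids$mutations, split_muts), kids$node_id),
    root_id = root)
  attr(tree, "unassigned") <- split_muts(table$mutations[table$parent_id == "-"])
  tree
}
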