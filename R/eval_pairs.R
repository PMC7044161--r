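#' Classify all SNV pairs of a mutational tree
#'
#' Every unordered pair of SNVs in a clone phylogeny falls in exactly one
#' category: \emph{concurrent} pairs sit on the same branch (their relative
#' order is unknowable from the phylogeny), \emph{sequential} pairs sit on
#' an ancestral branch and one of its descendant branches (possibly
#' separated by intervening branches), and \emph{parallel} pairs sit on
#' sibling lineages that diverged from their common ancestor.
#'
#' @param tree A `clone_phylogeny`.
#' @return An object of class `mutation_pair_set`: data frame with columns
#'   `snv1`, `snv2` (with `snv1 < snv2`) and `category`; the tree's SNV ids
#'   are kept in attribute `snvs`.
#' @export
classify_mutation_pairs <- function(tree) {
  validate_clone_phylogeny(tree)
  snvs <- tree_snvs(tree)
  branch_of <- stats::setNames(
    rep(names(tree$branch_mutations), lengths(tree$branch_mutations)),
    unlist(tree$branch_mutations, use.names = FALSE))
  # ancestor lookup between branches (a branch is identified with its child
  # node); node u is an ancestor-branch of v iff u lies on v's root path
  nodes <- setdiff(tree$clone_ids, tree$root_id)
  paths <- lapply(stats::setNames(nodes, nodes),
                  function(n) setdiff(root_path(tree, n), tree$root_id))

  if (length(snvs) < 2) {
    out <- data.frame(snv1 = character(0), snv2 = character(0),
                      category = character(0), stringsAsFactors = FALSE)
  } else {
    idx <- utils::combn(length(snvs), 2)
    a <- snvs[idx[1, ]]
    b <- snvs[idx[2, ]]
    ba <- branch_of[a]
    bb <- branch_of[b]
    category <- ifelse(ba == bb, "concurrent",
                       ifelse(mapply(function(x, y) x %in% paths[[y]] || y %in% paths[[x]], ba, bb),
                              "sequential", "parallel"))
    swap <- a > b
    out <- data.frame(snv1 = ifelse(swap, b, a), snv2 = ifelse(swap, a, b),
                      category = category, stringsAsFactors = FALSE)
  }
  attr(out, "snvs") <- snvs
  class(out) <- c("mutation_pair_set", "data.frame")
  out
}

#' Error rate of ordering mutations in one category
#'
#' Compares a true and an inferred mutation-pair classification within one
#' category.  The rate is the average of two proportions: the fraction of
#' true pairs of the category not recovered by the inferred tree (pairs
#' whose SNVs are absent from the inferred tree count here as
#' "unassigned"), and the fraction of inferred pairs of the category that
#' are not of that category in the truth.  When the truth has pairs in the
#' category but the inferred tree has none, the rate is flagged undefined
#' (the error would be infinite), signaling method failure as for
#' degenerate star/line phylogenies.  When the truth itself has no pairs in
#' the category, the missing-pair term contributes 0.
#'
#' @param true_pairs,inferred_pairs `mutation_pair_set` objects.
#' @param category One of `"concurrent"`, `"sequential"`, `"parallel"`.
#' @return List with elements `category`, `rate` (in [0,1], `NA` when
#'   undefined), `undefined` (logical), `n_true`, `n_inferred`, `n_missing`,
#'   `n_incorrect`.
#' @export
ordering_error_rate <- function(true_pairs, inferred_pairs,
                                category = c("concurrent", "sequential", "parallel")) {
  category <- match.arg(category)
  tk <- pair_key(true_pairs$snv1, true_pairs$snv2)
  ik <- pair_key(inferred_pairs$snv1, inferred_pairs$snv2)
  t_cat <- tk[true_pairs$category == category]
  i_cat <- ik[inferred_pairs$category == category]

  if (length(i_cat) == 0 && length(t_cat) > 0) {
    return(list(category = category, rate = NA_real_, undefined = TRUE,
                n_true = length(t_cat), n_inferred = 0L,
                n_missing = length(t_cat), n_incorrect = NA_integer_))
  }
  n_missing <- sum(!t_cat %in% i_cat)
  n_incorrect <- sum(!i_cat %in% t_cat)
  miss_frac <- if (length(t_cat)) n_missing / length(t_cat) else 0
  false_frac <- if (length(i_cat)) n_incorrect / length(i_cat) else 0
  list(category = category, rate = (miss_frac + false_frac) / 2,
       undefined = FALSE, n_true = length(t_cat), n_inferred = length(i_cat),
       n_missing = n_missing, n_incorrect = n_incorrect)
}

#' Ordering error rates for all three categories
#'
#' @param true_pairs,inferred_pairs `mutation_pair_set` objects.
#' @return Named list of [ordering_error_rate()] results.
#' @export
ordering_error_rates <- function(true_pairs, inferred_pairs) {
  cats <- c("concurrent", "sequential", "parallel")
  stats::setNames(lapply(cats, function(cc)
    ordering_error_rate(true_pairs, inferred_pairs, cc)), cats)
}

#' Flag star- or line-shaped (degenerate) clone phylogenies
#'
#' Some methods occasionally emit phylogenies with no sequential mutation
#' pairs (all branches radiate from the root: a star) or no parallel pairs
#' (a single chain: a line).  Ordering error rates in the missing category
#' are infinite on such trees, so they are treated as method failures.
#'
#' @param tree A `clone_phylogeny`.
#' @return `"star"`, `"line"`, or `"ok"`.  A single-branch tree (neither
#'   sequential nor parallel pairs possible) is reported as `"star"`.
#' @export
detect_degenerate_topology <- function(tree) {
  pairs <- classify_mutation_pairs(tree)
  if (!any(pairs$category == "sequential")) return("star")
  if (!any(pairs$category == "parallel")) return("line")
  "ok"
}
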