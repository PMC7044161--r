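#' Generate a random clone phylogeny with localized tumor samples
#'
#' Emulates benchmark datasets in which random clone phylogenies arise from
#' a birth--death-like process and every tumor sample is populated by one
#' tip clone together with all of its ancestral clones (the "localized
#' sampling" design, which leaves ancestral clones persisting alongside
#' their descendants).
#'
#' The topology grows by a Yule-type split process: starting from a single
#' founder clone below the germline, a uniformly chosen tip is repeatedly
#' split into two daughter clones (one daughter only when a single clone of
#' budget remains); optionally, after each split a uniformly chosen tip dies
#' with probability `death_prob`, leaving unifurcating ancestors.  Each
#' branch carries `mutations_per_branch(1)` brand-new SNVs (default: uniform
#' on 1..10).  Each sample is assigned a distinct tip; the frequencies of
#' the tip and its ancestors are drawn from a symmetric Dirichlet(1) and sum
#' to 1 (100% tumor purity).
#'
#' @param n_clones Total number of clones excluding the germline (>= 2).
#' @param n_samples Number of tumor samples; must not exceed the number of
#'   tips of the generated topology.
#' @param mutations_per_branch Function drawing `n` positive integers,
#'   the number of mutations per branch.
#' @param death_prob Probability that a random tip dies after each split.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list of class `clone_dataset` with elements `tree`
#'   (`clone_phylogeny`), `genotypes` (clones x SNVs, germline row included)
#'   and `composition` (samples x clones frequency matrix over non-germline
#'   clones).
#' @export
generate_random_dataset <- function(n_clones, n_samples,
                                    mutations_per_branch = function(n) sample.int(10L, n, replace = TRUE),
                                    death_prob = 0, seed) {
  stopifnot(n_clones >= 2, n_samples >= 1)
  set.seed(seed)

  parent <- c(C1 = "Normal")
  tips <- "C1"
  nclone <- 1L
  while (nclone < n_clones) {
    t <- tips[sample.int(length(tips), 1L)]
    k <- min(2L, n_clones - nclone)
    new_ids <- sprintf("C%d", nclone + seq_len(k))
    parent[new_ids] <- t
    tips <- c(setdiff(tips, t), new_ids)
    nclone <- nclone + k
    if (death_prob > 0 && length(tips) > 1L && stats::runif(1) < death_prob) {
      dead <- tips[sample.int(length(tips), 1L)]
      # a dead tip is pruned only if it leaves the clone budget intact
      if (nclone >= n_clones) next
      parent <- parent[names(parent) != dead]
      tips <- setdiff(names(parent), unname(parent))
      nclone <- nclone - 1L
    }
  }
  clones <- names(parent)

  nmut <- mutations_per_branch(length(clones))
  if (any(nmut < 1)) stop("mutations_per_branch must return positive counts")
  snv_ids <- sprintf("s%d", seq_len(sum(nmut)))
  branch_mutations <- split(snv_ids, rep(seq_along(clones), nmut))
  names(branch_mutations) <- clones

  tree <- clone_phylogeny(parent, branch_mutations, root_id = "Normal")
  tips <- setdiff(clones, unname(parent))
  if (n_samples > length(tips))
    stop("n_samples (", n_samples, ") exceeds tip count (", length(tips), ")")

  sampled_tips <- sample(tips, n_samples)
  comp <- matrix(0, nrow = n_samples, ncol = length(clones),
                 dimnames = list(sprintf("T%d", seq_len(n_samples)), clones))
  for (i in seq_len(n_samples)) {
    present <- setdiff(root_path(tree, sampled_tips[i]), "Normal")
    w <- stats::rgamma(length(present), shape = 1)
    comp[i, present] <- w / sum(w)
  }

  structure(list(tree = tree,
                 genotypes = genotypes_from_tree(tree),
                 composition = comp),
            class = "clone_dataset")
}

#' @export
print.clone_dataset <- function(x, ...) {
  cat("clone_dataset: ", nrow(x$composition), " samples, ",
      ncol(x$composition), " clones, ", ncol(x$genotypes), " SNVs\n", sep = "")
  invisible(x)
}

#' Ancestral clones of a simulated dataset
#'
#' Ancestral clones are internal-node clones (clones with descendants) that
#' are present at nonzero frequency in at least one tumor sample.
#'
#' @param dataset A `clone_dataset`.
#' @return Character vector of ancestral clone ids.
#' @export
ancestral_clones <- function(dataset) {
  tree <- dataset$tree
  internal <- setdiff(unique(unname(tree$parent_of)), tree$root_id)
  present <- colnames(dataset$composition)[colSums(dataset$composition) > 0]
  intersect(internal, present)
}
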