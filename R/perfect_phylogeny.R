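#' Reconstruct a clone phylogeny from binary genotypes
#'
#' Builds the rooted perfect phylogeny implied by a binary clone-by-SNV
#' genotype matrix, rooted at the all-zero germline state.  Because
#' simulated mutations arise only once, maximum parsimony on such data
#' reduces to the classic perfect-phylogeny construction on rooted binary
#' characters: sites are sorted by decreasing mutant count and each clone's
#' mutation list then spells a root path in a mutation trie.  Clones with
#' identical genotypes are merged onto a single node (all contributing clone
#' labels are kept in `node_labels`); nodes required by the character
#' patterns but matching no input row become anonymous internal nodes.
#'
#' @param genotypes Binary matrix, rows = clones, columns = SNV ids.
#'   All-zero columns (SNVs carried by no clone) are dropped.
#' @return A `clone_phylogeny`.  `genotypes_from_tree()` on the result
#'   reproduces the input (up to merged duplicate genotypes) whenever the
#'   input contains the genotype of every ancestor, as matrices produced by
#'   `genotypes_from_tree()` do.
#' @export
tree_from_genotypes <- function(genotypes) {
  M <- assert_binary_matrix(genotypes)
  storage.mode(M) <- "integer"
  check_perfect_phylogeny(M)
  M <- M[, colSums(M) > 0, drop = FALSE]

  # stable column order: decreasing number of carriers, ties by column index
  ord <- order(-colSums(M), seq_len(ncol(M)))
  M <- M[, ord, drop = FALSE]
  snvs <- colnames(M)

  # mutation trie: each SNV is one node; parent = preceding SNV on the
  # carrier's sorted mutation list (or the root)
  parent_mut <- stats::setNames(rep(NA_character_, length(snvs)), snvs)
  for (cl in rownames(M)) {
    path <- snvs[M[cl, ] == 1L]
    if (!length(path)) next
    par <- c(".root", path[-length(path)])
    for (i in seq_along(path)) {
      known <- parent_mut[[path[i]]]
      if (is.na(known)) parent_mut[[path[i]]] <- par[i]
      else if (known != par[i])
        stop("internal error: inconsistent mutation trie at SNV '", path[i], "'")
    }
  }

  # clones attach to the trie node of their last mutation
  attach_at <- vapply(rownames(M), function(cl) {
    path <- snvs[M[cl, ] == 1L]
    if (length(path)) path[length(path)] else ".root"
  }, character(1))

  # compress: an unlabeled trie node with a single child donates its SNV to
  # the child's branch (concurrent mutations on one branch)
  node_mut <- stats::setNames(as.list(snvs), snvs)
  node_clones <- split(names(attach_at), attach_at)
  alive <- snvs
  repeat {
    kids <- split(alive, unname(parent_mut[alive]))
    merged <- FALSE
    for (u in alive) {
      if (length(node_clones[[u]] %||% character(0)) > 0) next
      ch <- kids[[u]] %||% character(0)
      if (length(ch) != 1L) next
      node_mut[[ch]] <- c(node_mut[[u]], node_mut[[ch]])
      parent_mut[[ch]] <- parent_mut[[u]]
      alive <- setdiff(alive, u)
      merged <- TRUE
      break
    }
    if (!merged) break
  }

  # assemble clone_phylogeny: node ids from clone labels where available
  root_clones <- node_clones[[".root"]] %||% character(0)
  root_id <- if (length(root_clones)) sort(root_clones)[1] else "Normal"
  anon <- 0L
  ids <- stats::setNames(character(length(alive)), alive)
  for (u in alive) {
    lab <- sort(node_clones[[u]] %||% character(0))
    if (length(lab)) {
      ids[[u]] <- lab[1]
    } else {
      anon <- anon + 1L
      ids[[u]] <- sprintf("node%d", anon)
    }
  }
  parent_of <- stats::setNames(
    vapply(alive, function(u) {
      p <- unname(parent_mut[[u]])
      if (p == ".root") root_id else ids[[p]]
    }, character(1)),
    ids[alive])
  branch_mutations <- stats::setNames(node_mut[alive], ids[alive])
  node_labels <- stats::setNames(
    lapply(alive, function(u) sort(node_clones[[u]] %||% character(0))), ids[alive])
  node_labels[[root_id]] <- sort(unique(c(root_clones)))
  clone_phylogeny(parent_of, branch_mutations, root_id = root_id,
                  node_labels = node_labels)
}

#' Test binary characters for perfect-phylogeny compatibility
#'
#' Two rooted binary characters are compatible iff the carrier sets are
#' nested or disjoint; equivalently the patterns (1,1), (1,0) and (0,1) must
#' not all occur.  Errors on the first conflicting SNV pair.
#'
#' @param genotypes Binary clone-by-SNV matrix.
#' @return Invisibly `TRUE`; errors on conflict.
#' @export
check_perfect_phylogeny <- function(genotypes) {
  M <- genotypes
  storage.mode(M) <- "double"
  n11 <- crossprod(M)                      # pairs of columns both 1
  cs <- colSums(M)
  n10 <- outer(cs, rep(1, length(cs))) - n11
  n01 <- t(n10)
  conflict <- n11 > 0 & n10 > 0 & n01 > 0
  if (any(conflict)) {
    idx <- sort(which(conflict, arr.ind = TRUE)[1, ])
    stop("perfect-phylogeny violation: SNVs '", colnames(M)[idx[1]],
         "' and '", colnames(M)[idx[2]], "' are incompatible")
  }
  invisible(TRUE)
}
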