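# fixture builders and independent oracles used across the suite

# small hand-built clone phylogeny in the style of the classic mutational
# tree figure: root -> V1(A) -> V2(B) with V2 -> V3(C,D) and V2 -> V4(E),
# V2 -> V5(F): (A,B) sequential, (C,D) concurrent, (E,F) parallel
fig_tree <- function() {
  clone_phylogeny(
    parent_of = c(V1 = "Normal", V2 = "V1", V3 = "V2", V4 = "V2", V5 = "V2"),
    branch_mutations = list(V1 = "A", V2 = "B", V3 = c("C", "D"),
                            V4 = "E", V5 = "F"))
}

chain_tree <- function() {
  clone_phylogeny(parent_of = c(A = "Normal", B = "A"),
                  branch_mutations = list(A = "m1", B = "m2"))
}

star_tree <- function() {
  clone_phylogeny(parent_of = c(A = "Normal", B = "Normal"),
                  branch_mutations = list(A = "m1", B = "m2"))
}

random_mutational_tree <- function(seed, n_clones = NULL) {
  set.seed(seed)
  n <- n_clones %||% sample(3:8, 1)
  generate_random_dataset(
    n, 1, mutations_per_branch = function(k) sample.int(3L, k, replace = TRUE),
    seed = seed)$tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) brute-force pair classifier via an explicit ancestor table built by
# parent hops (independent of the package's vectorized root-path route)
oracle_classify_pairs <- function(tree) {
  branches <- setdiff(tree$clone_ids, tree$root_id)
  anc <- matrix(FALSE, length(branches), length(branches),
                dimnames = list(branches, branches))
  for (v in branches) {
    u <- unname(tree$parent_of[[v]])
    while (u != tree$root_id) {
      anc[u, v] <- TRUE
      u <- unname(tree$parent_of[[u]])
    }
  }
  branch_of <- character(0)
  for (b in branches)
    for (m in tree$branch_mutations[[b]]) branch_of[m] <- b
  snvs <- names(branch_of)
  out <- list()
  if (length(snvs) >= 2) {
    for (i in seq_len(length(snvs) - 1)) {
      for (j in (i + 1):length(snvs)) {
        a <- snvs[i]; b <- snvs[j]
        ba <- branch_of[[a]]; bb <- branch_of[[b]]
        cat_ <- if (ba == bb) "concurrent"
                else if (anc[ba, bb] || anc[bb, ba]) "sequential"
                else "parallel"
        key <- paste(sort(c(a, b)), collapse = "\r")
        out[[key]] <- cat_
      }
    }
  }
  unlist(out) %||% character(0)
}

# naive per-pair MRCA-depth TreeVec oracle built on ape primitives
# (getMRCA + nodepath), independent of the package's parent-vector code
oracle_treevec <- function(t1, t2) {
  labels <- sort(union(unique(t1$tip.label), unique(t2$tip.label)))
  vec <- function(phy) {
    root <- length(phy$tip.label) + 1L
    depth_of <- function(node) {
      if (node == root) 0L else length(ape::nodepath(phy, root, node)) - 1L
    }
    out <- numeric(0)
    for (i in seq_len(length(labels) - 1)) {
      for (j in (i + 1):length(labels)) {
        tips <- which(phy$tip.label %in% c(labels[i], labels[j]))
        out <- c(out,
                 if (!all(c(labels[i], labels[j]) %in% phy$tip.label)) 0
                 else if (length(tips) < 2) 0
                 else depth_of(ape::getMRCA(phy, tips)))
      }
    }
    out
  }
  sqrt(sum((vec(t1) - vec(t2))^2))
}

# exhaustive rooted-clade RF oracle via ape::prop.part
oracle_rf <- function(t1, t2) {
  clades <- function(phy) {
    pp <- ape::prop.part(phy)
    sets <- lapply(pp, function(idx) sort(phy$tip.label[idx]))
    keep <- vapply(sets, function(s)
      length(s) >= 2 && length(s) < length(phy$tip.label), logical(1))
    unique(vapply(sets[keep], paste, character(1), collapse = "\r"))
  }
  c1 <- clades(t1); c2 <- clades(t2)
  if (length(c1) + length(c2) == 0) return(0)
  (sum(!c1 %in% c2) + sum(!c2 %in% c1)) / (length(c1) + length(c2))
}

# minimal hand-rolled lattice_tumor stand-in for clone-calling edge cases
synthetic_tumor <- function(new_mutations) {
  n <- length(new_mutations)
  structure(list(coords = matrix(0L, n, 3), parent = rep(0L, n),
                 depth = rep(1L, n), new_mutations = new_mutations,
                 n_mutations = length(unique(unlist(new_mutations))),
                 model = "constant", k = 10, rate = 1, N = n,
                 mutation_mean = 1),
            class = "lattice_tumor")
}
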