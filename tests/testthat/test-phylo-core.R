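test_that("genotypes_from_tree accumulates mutations along root paths", {
  G <- genotypes_from_tree(chain_tree())
  expect_equal(G["Normal", ], c(m1 = 0L, m2 = 0L))
  expect_equal(G["A", ], c(m1 = 1L, m2 = 0L))
  expect_equal(G["B", ], c(m1 = 1L, m2 = 1L))

  # root with no children: single all-zero germline row
  lone <- clone_phylogeny(character(0), list())
  expect_equal(dim(genotypes_from_tree(lone)), c(1L, 0L))
})

# local helper: root path by parent hops
root_path_oracle <- function(tree, node) {
  p <- character(0)
  while (node != tree$root_id) {
    node <- unname(tree$parent_of[[node]])
    p <- c(p, node)
  }
  p
}

test_that("ancestor genotypes are subsets of descendant genotypes", {
  tree <- random_mutational_tree(42, n_clones = 8)
  G <- genotypes_from_tree(tree)
  for (a in rownames(G)) {
    for (d in rownames(G)) {
      if (a == d) next
      if (a %in% root_path_oracle(tree, d))
        expect_true(all(G[a, ] <= G[d, ]),
                    info = paste(a, "not subset of", d))
    }
  }
})

test_that("infinite-sites violations are rejected", {
  expect_error(
    clone_phylogeny(c(A = "Normal", B = "A"),
                    list(A = "m1", B = "m1")),
    "infinite-sites")
})

test_that("tree_from_genotypes round-trips tree-derived matrices", {
  for (seed in 1:5) {
    tree <- random_mutational_tree(seed)
    G <- genotypes_from_tree(tree)
    back <- genotypes_from_tree(tree_from_genotypes(G))
    expect_setequal(rownames(back), rownames(G))
    expect_equal(back[rownames(G), colnames(G)], G)
  }
})

test_that("tree_from_genotypes handles minimal and conflicting inputs", {
  # single clone plus germline: one branch carrying m1
  G <- matrix(c(0L, 1L), 2, 1, dimnames = list(c("Normal", "A"), "m1"))
  tree <- tree_from_genotypes(G)
  expect_equal(sort(tree$clone_ids), c("A", "Normal"))
  expect_equal(tree$branch_mutations$A, "m1")

  # columns conflict: {m1}, {m2}, {m1,m2} has (1,1),(1,0),(0,1) patterns
  bad <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L), 3, 2,
                dimnames = list(c("x", "y", "z"), c("m1", "m2")))
  expect_error(tree_from_genotypes(bad), "perfect-phylogeny violation.*m1.*m2")
})

test_that("generated datasets satisfy the localized-sampling design", {
  ds <- generate_random_dataset(7, 4, seed = 7)
  comp <- ds$composition
  expect_true(all(comp >= 0))
  expect_equal(unname(rowSums(comp)), rep(1, nrow(comp)), tolerance = 1e-12)
  # each sample's support is a root path: one tip plus all its ancestors
  for (s in rownames(comp)) {
    present <- colnames(comp)[comp[s, ] > 0]
    deepest <- present[which.max(vapply(present, function(cl)
      length(root_path_oracle(ds$tree, cl)), numeric(1)))]
    expect_setequal(present,
                    c(deepest, setdiff(root_path_oracle(ds$tree, deepest), "Normal")))
  }
})

test_that("generate_random_dataset is deterministic and validates inputs", {
  a <- generate_random_dataset(6, 3, seed = 99)
  b <- generate_random_dataset(6, 3, seed = 99)
  expect_identical(a, b)
  expect_error(generate_random_dataset(2, 50, seed = 1), "exceeds tip count")
  small <- generate_random_dataset(2, 1, seed = 3)
  expect_equal(sum(small$composition), 1, tolerance = 1e-12)
})

test_that("mutational-tree export follows the unassigned-at-root rule", {
  tree <- chain_tree()
  tab <- export_mutational_tree(tree, universe = c("m1", "m2", "m9"))
  root_row <- tab[tab$parent_id == "-", ]
  expect_equal(root_row$mutations, "m9")

  # universe equal to the tree's SNVs: empty root list
  tab2 <- export_mutational_tree(tree)
  expect_equal(tab2$mutations[tab2$parent_id == "-"], "")

  # SNV in tree but absent from universe is an error
  expect_error(export_mutational_tree(tree, universe = "m1"), "not in the universe")

  # round-trip preserves branch-mutation sets exactly
  tree2 <- random_mutational_tree(8)
  back <- parse_mutational_tree(export_mutational_tree(tree2))
  expect_equal(back$branch_mutations[names(tree2$branch_mutations)],
               tree2$branch_mutations)
  expect_equal(attr(back, "unassigned"), character(0))
})
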