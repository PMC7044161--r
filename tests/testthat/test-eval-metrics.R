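test_that("the canonical tree classifies its pair examples correctly", {
  pairs <- classify_mutation_pairs(fig_tree())
  lookup <- stats::setNames(pairs$category, paste(pairs$snv1, pairs$snv2))
  expect_equal(unname(lookup["C D"]), "concurrent")
  expect_equal(unname(lookup["A B"]), "sequential")
  expect_equal(unname(lookup["E F"]), "parallel")
  # two mutations on one branch are concurrent regardless of position
  expect_equal(nrow(pairs), choose(6, 2))
})

test_that("pair classification matches the ancestor-table brute force", {
  for (seed in 1:25) {
    tree <- random_mutational_tree(seed)
    pairs <- classify_mutation_pairs(tree)
    got <- stats::setNames(pairs$category, paste(pairs$snv1, pairs$snv2, sep = "\r"))
    want <- oracle_classify_pairs(tree)
    expect_equal(got[sort(names(got))], want[sort(names(want))], info = seed)
  }
})

test_that("ordering error rates follow the miss/false average", {
  tree <- fig_tree()
  pairs <- classify_mutation_pairs(tree)
  self <- ordering_error_rates(pairs, pairs)
  expect_equal(unname(vapply(self, `[[`, numeric(1), "rate")), c(0, 0, 0))

  # truth has 3 concurrent pairs; inference keeps 2 and invents 1 spurious
  truth <- clone_phylogeny(c(A = "Normal"), list(A = c("m1", "m2", "m3")))
  inf <- clone_phylogeny(c(A = "Normal", B = "A"),
                         list(A = c("m1", "m2"), B = c("m3", "m4")))
  r <- ordering_error_rate(classify_mutation_pairs(truth),
                           classify_mutation_pairs(inf), "concurrent")
  expect_equal(r$n_true, 3L)
  expect_equal(r$n_missing, 2L)  # (m1,m3), (m2,m3) lost to sequential
  expect_equal(r$n_incorrect, 1L)  # (m3,m4) spurious
  expect_equal(r$rate, (2 / 3 + 1 / 2) / 2)
})

test_that("a star-shaped inference flags the sequential category undefined", {
  truth_pairs <- classify_mutation_pairs(chain_tree())
  star_pairs <- classify_mutation_pairs(star_tree())
  seq_rate <- ordering_error_rate(truth_pairs, star_pairs, "sequential")
  expect_true(seq_rate$undefined)
  expect_true(is.na(seq_rate$rate))
  # the spurious parallel pair scores 1/1 false with no true parallel pairs
  par_rate <- ordering_error_rate(truth_pairs, star_pairs, "parallel")
  expect_false(par_rate$undefined)
  expect_equal(par_rate$rate, 0.5)
  # empty category on both sides is a clean 0, not a failure
  self_par <- ordering_error_rate(truth_pairs, truth_pairs, "parallel")
  expect_equal(self_par$rate, 0)
})

test_that("rates are invariant under consistent SNV relabeling", {
  tree <- random_mutational_tree(33, n_clones = 6)
  relabel <- function(tree, map) {
    tree$branch_mutations <- lapply(tree$branch_mutations,
                                    function(m) unname(map[m]))
    tree
  }
  snvs <- tree_snvs(tree)
  map <- stats::setNames(sprintf("x%03d", rev(seq_along(snvs))), snvs)
  r1 <- ordering_error_rates(classify_mutation_pairs(tree),
                             classify_mutation_pairs(tree))
  tree2 <- relabel(tree, map)
  r2 <- ordering_error_rates(classify_mutation_pairs(tree2),
                             classify_mutation_pairs(tree2))
  expect_equal(vapply(r1, `[[`, numeric(1), "rate"),
               vapply(r2, `[[`, numeric(1), "rate"))
})

test_that("clone mapping pairs greedily then attaches the surplus", {
  G_true <- matrix(c(1L, 1L, 0L, 1L), 2, 2,
                   dimnames = list(c("A", "B"), c("m1", "m2")))
  # inferred: copy of A, copy of B, and B plus an extra private SNV
  G_inf <- matrix(c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 0L, 1L), 3, 3,
                  dimnames = list(c("i1", "i2", "i3"), c("m1", "m2", "m3")))
  mp <- map_clones(G_true, G_inf)
  expect_equal(mp$true[match(c("i1", "i2", "i3"), mp$inferred)],
               c("A", "B", "B"))
  expect_equal(mp$distance[mp$inferred == "i3"], 1L)
  expect_equal(sum(mp$primary), 2L)

  identity_map <- map_clones(G_true, G_true)
  expect_true(all(identity_map$distance == 0))
  expect_error(map_clones(G_true, G_true[0, , drop = FALSE]), "no clones")
})

test_that("SNV assignment error averages mapped Hamming distances", {
  G <- genotypes_from_tree(random_mutational_tree(44, n_clones = 5))
  G <- G[rownames(G) != "Normal", , drop = FALSE]
  expect_equal(snv_assignment_error(G, G), 0)

  flipped <- G
  flipped[1, 1:2] <- 1L - flipped[1, 1:2]
  err <- snv_assignment_error(G, flipped)
  expect_equal(err, 2 / nrow(G))
  # invariant under SNV column permutation
  perm <- sample(ncol(flipped))
  expect_equal(snv_assignment_error(G[, perm], flipped[, perm]), err)
})

test_that("tree distances agree with their oracles on random tree pairs", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    t1 <- ape::rtree(n, rooted = TRUE, br = NULL)
    t2 <- ape::rtree(n, rooted = TRUE, br = NULL)
    expect_equal(rf_distance(t1, t2), oracle_rf(t1, t2), info = i)
    expect_equal(treevec_distance(t1, t2), oracle_treevec(t1, t2), info = i)
    expect_equal(rf_distance(t1, t1), 0)
    expect_equal(treevec_distance(t2, t2), 0)
    expect_equal(rf_distance(t1, t2), rf_distance(t2, t1))
    expect_equal(treevec_distance(t1, t2), treevec_distance(t2, t1))
  }
})

test_that("reversed caterpillars are maximally far apart under RF", {
  mk_caterpillar <- function(labels) {
    str <- labels[1]
    for (l in labels[-1]) str <- paste0("(", str, ",", l, ")")
    ape::read.tree(text = paste0(str, ";"))
  }
  labs <- sprintf("t%d", 1:6)
  t1 <- mk_caterpillar(labs)
  t2 <- mk_caterpillar(rev(labs))
  expect_equal(rf_distance(t1, t2), oracle_rf(t1, t2))
  expect_gt(rf_distance(t1, t2), 0.7)
})

test_that("duplicated labels collapse monophyletic clades in TreeVec", {
  # cherry of two X tips collapses onto its MRCA: distance 0 to a single X
  dup <- ape::read.tree(text = "(((X,X),A),B);")
  single <- ape::read.tree(text = "((X,A),B);")
  expect_equal(treevec_distance(dup, single), 0)
  expect_equal(treevec_distance(dup, single), oracle_treevec(dup, single))
})

test_that("ancestral-clone detection counts exact matches through the map", {
  ds <- generate_random_dataset(9, 3, seed = 55)
  G <- ds$genotypes[colnames(ds$composition), , drop = FALSE]
  anc <- ancestral_clones(ds)
  expect_gt(length(anc), 0)
  expect_equal(count_detected_ancestral(ds, G), length(anc))

  # deleting k ancestral genotypes loses exactly k detections
  k <- min(2L, length(anc))
  pruned <- G[setdiff(rownames(G), anc[seq_len(k)]), , drop = FALSE]
  expect_equal(count_detected_ancestral(ds, pruned), length(anc) - k)

  # an inference with no internal genotypes detects none
  tips <- setdiff(rownames(G), ancestral_clones(ds))
  only_tips <- G[setdiff(tips, anc), , drop = FALSE]
  expect_equal(count_detected_ancestral(ds, only_tips), 0L)
})
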