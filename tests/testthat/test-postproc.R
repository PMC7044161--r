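# noiseless read table with exact integer counts at the given depth
exact_reads <- function(V, depth) {
  structure(list(mutant = round(V * depth), total = V * 0 + depth,
                 expected_vaf = V, expected_depth = V * 0 + depth),
            class = "read_count_table")
}

chain_genotypes <- function(n_clones, snvs_per_branch = 1) {
  snvs <- sprintf("s%d", seq_len(n_clones * snvs_per_branch))
  G <- matrix(0L, n_clones, length(snvs),
              dimnames = list(sprintf("C%d", seq_len(n_clones)), snvs))
  for (i in seq_len(n_clones))
    G[i:n_clones, (i - 1) * snvs_per_branch + seq_len(snvs_per_branch)] <- 1L
  G
}

test_that("frequency regression is exact on noiseless identifiable data", {
  G <- chain_genotypes(3)
  f <- matrix(c(0.2, 0.3, 0.4), 1, 3, dimnames = list("T1", rownames(G)))
  V <- expected_vaf_neutral(f, G)
  fhat <- estimate_clone_frequencies(G, exact_reads(V, 200))
  expect_lt(max(abs(fhat - f)), 1e-6)

  # single clone, V = 0.25 everywhere: half f M inverts to f = 0.5
  G1 <- matrix(1L, 1, 4, dimnames = list("A", sprintf("s%d", 1:4)))
  V1 <- matrix(0.25, 1, 4, dimnames = list("T1", colnames(G1)))
  fhat1 <- estimate_clone_frequencies(G1, exact_reads(V1, 100))
  expect_equal(unname(fhat1[1, 1]), 0.5, tolerance = 1e-8)
})

test_that("read filters exclude unreliable SNVs from the fit", {
  G <- chain_genotypes(2, snvs_per_branch = 2)
  f <- matrix(c(0.4, 0.5), 1, 2, dimnames = list("T1", rownames(G)))
  V <- expected_vaf_neutral(f, G)
  reads <- exact_reads(V, 100)
  # corrupt s1 but push its total below the 50-read floor: fit unaffected
  reads$mutant[, "s1"] <- 29
  reads$total[, "s1"] <- 30
  fhat <- estimate_clone_frequencies(G, reads)
  expect_lt(max(abs(fhat - f)), 1e-6)
  # dropping every SNV is an error
  reads$total[] <- 10
  expect_error(estimate_clone_frequencies(G, reads), "no SNV survives")
})

test_that("regression recovers frequencies under 100x counting noise", {
  G <- chain_genotypes(3, snvs_per_branch = 5)
  f <- matrix(c(0.2, 0.3, 0.4), 1, 3, dimnames = list("T1", rownames(G)))
  V <- expected_vaf_neutral(f, G)
  errs <- vapply(1:20, function(i) {
    reads <- sample_read_counts(V, 100, seed = 1000 + i)
    mean(abs(estimate_clone_frequencies(G, reads) - f))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("spurious ancestors are removed or retained by the VAF t-test", {
  tree <- clone_phylogeny(c(A = "Normal", B = "A"),
                          list(A = sprintf("a%d", 1:20), B = sprintf("b%d", 1:20)))
  G <- genotypes_from_tree(tree)[c("A", "B"), ]
  comp <- matrix(c(0.3, 0.6), 1, 2, dimnames = list("T1", c("A", "B")))

  # well-separated groups (shared ~0.45, unique ~0.15): ancestor retained
  V_alt <- matrix(c(rep(0.45, 20), rep(0.15, 20)), 1, 40,
                  dimnames = list("T1", colnames(G)))
  reads_alt <- sample_read_counts(V_alt, 100, seed = 61)
  out <- filter_spurious_ancestors(tree, G, comp, reads_alt)
  expect_equal(nrow(out$removed), 0L)
  expect_equal(out$composition, comp)

  # identical distributions: ancestor removed, mass moved to the descendant
  V_null <- matrix(0.3, 1, 40, dimnames = list("T1", colnames(G)))
  reads_null <- sample_read_counts(V_null, 100, seed = 62)
  out0 <- filter_spurious_ancestors(tree, G, comp, reads_null)
  expect_equal(out0$removed$clone, "A")
  expect_equal(unname(out0$composition[1, "B"]), 0.9)

  # ancestor never co-occurring with a descendant is untouched
  comp_solo <- matrix(c(1, 0), 1, 2, dimnames = list("T1", c("A", "B")))
  solo <- filter_spurious_ancestors(tree, G, comp_solo, reads_null)
  expect_equal(unname(solo$composition["T1", "A"]), 1)

  # idempotence
  again <- filter_spurious_ancestors(tree, out0$genotypes, out0$composition,
                                     reads_null)
  expect_equal(again$composition, out0$composition)
})

test_that("rare clones are discarded strictly below the threshold", {
  comp <- matrix(c(0.015, 0.985), 1, 2, dimnames = list("T1", c("A", "B")))
  out <- discard_rare_clones(comp)
  expect_equal(colnames(out), "B")
  expect_equal(unname(out[1, "B"]), 1)

  # boundary: exactly 2% is retained
  comp2 <- matrix(c(0.02, 0.98), 1, 2, dimnames = list("T1", c("A", "B")))
  expect_equal(discard_rare_clones(comp2), comp2)

  # identity above threshold, and idempotence
  comp3 <- generate_random_dataset(5, 3, seed = 77)$composition
  comp3[comp3 > 0 & comp3 < 0.02] <- 0.05
  comp3 <- comp3 / rowSums(comp3)
  once <- discard_rare_clones(comp3)
  expect_equal(discard_rare_clones(once), once)
})

test_that("degenerate topologies are flagged as star or line", {
  expect_equal(detect_degenerate_topology(star_tree()), "star")
  expect_equal(detect_degenerate_topology(chain_tree()), "line")
  expect_equal(detect_degenerate_topology(fig_tree()), "ok")
})
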