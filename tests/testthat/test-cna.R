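test_that("SNVs are packed into chromosomes of at most the capacity", {
  snvs <- sprintf("s%d", 1:89)
  a <- assign_snvs_to_haplotypes(snvs, seed = 1)
  expect_setequal(a$snv_id, snvs)
  expect_equal(as.integer(sort(table(a$chromosome), decreasing = TRUE)),
               c(30L, 30L, 29L))
  expect_true(all(a$haplotype %in% c("paternal", "maternal")))

  one <- assign_snvs_to_haplotypes("s1", seed = 2)
  expect_equal(nrow(one), 1L)
  expect_equal(one$chromosome, 1L)
  expect_error(assign_snvs_to_haplotypes(character(0), seed = 1), "non-empty")
})

test_that("haplotype tagging is an unbiased coin flip", {
  a <- assign_snvs_to_haplotypes(sprintf("s%d", 1:10000), seed = 3)
  frac <- mean(a$haplotype == "paternal")
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("event placement interleaves with branch mutations deterministically", {
  tree <- fig_tree()
  ev <- place_cna_events(tree, 1:3, seed = 5)
  ev2 <- place_cna_events(tree, 1:3, seed = 5)
  expect_identical(ev, ev2)
  expect_true(all(ev$branch %in% setdiff(tree$clone_ids, "Normal")))
  for (b in unique(ev$branch)) {
    idx <- ev$order_index[ev$branch == b]
    total <- length(tree$branch_mutations[[b]]) + length(idx)
    expect_false(anyDuplicated(idx) > 0)
    expect_true(all(idx >= 1 & idx <= total))
  }

  none <- place_cna_events(tree, 1:3, events_per_chromosome = function(n) rep(0L, n),
                           seed = 6)
  expect_equal(nrow(none), 0L)
})

test_that("copy states replay mutations and CNA events in branch order", {
  # 2-node tree, one mutation; events appended after the mutation
  tree <- clone_phylogeny(c(C1 = "Normal"), list(C1 = "s1"))
  assignment <- data.frame(snv_id = "s1", chromosome = 1L,
                           haplotype = "paternal", stringsAsFactors = FALSE)
  mk_event <- function(type, hap) {
    structure(data.frame(chromosome = 1L, haplotype = hap, event_type = type,
                         branch = "C1", order_index = 2L,
                         stringsAsFactors = FALSE),
              class = c("cna_events", "data.frame"))
  }

  # mutation then gain of the mutant haplotype: (mutant, wild) = (2, 1)
  cs <- evolve_copy_states(tree, mk_event("gain", "paternal"), assignment)
  expect_equal(cs$mutant["C1", "s1"], 2L)
  expect_equal(cs$wild["C1", "s1"], 1L)

  # mutation then LOH deleting the wild haplotype: (2, 0), multiplier 1
  cs <- evolve_copy_states(tree, mk_event("LOH", "maternal"), assignment)
  expect_equal(cs$mutant["C1", "s1"], 2L)
  expect_equal(cs$wild["C1", "s1"], 0L)

  # loss of the mutant haplotype removes the mutation: (0, 1)
  cs <- evolve_copy_states(tree, mk_event("loss", "paternal"), assignment)
  expect_equal(cs$mutant["C1", "s1"], 0L)
  expect_equal(cs$wild["C1", "s1"], 1L)

  # germline row stays diploid wild type
  expect_equal(cs$mutant["Normal", "s1"], 0L)
  expect_equal(cs$wild["Normal", "s1"], 2L)
})

test_that("zero events give the copy-neutral table implied by the genotypes", {
  tree <- random_mutational_tree(11, n_clones = 6)
  assignment <- assign_snvs_to_haplotypes(tree_snvs(tree), seed = 12)
  no_events <- place_cna_events(tree, unique(assignment$chromosome),
                                events_per_chromosome = function(n) rep(0L, n),
                                seed = 13)
  cs <- evolve_copy_states(tree, no_events, assignment)
  G <- genotypes_from_tree(tree)
  neutral <- neutral_copy_states(G)
  expect_equal(cs$mutant[rownames(G), colnames(G)], neutral$mutant)
  expect_equal(cs$wild[rownames(G), colnames(G)], neutral$wild)
})

test_that("a root-branch gain is inherited by every descendant clone", {
  tree <- clone_phylogeny(c(C1 = "Normal", C2 = "C1", C3 = "C1"),
                          list(C1 = "s1", C2 = "s2", C3 = "s3"))
  assignment <- data.frame(snv_id = c("s1", "s2", "s3"), chromosome = 1L,
                           haplotype = "paternal", stringsAsFactors = FALSE)
  gain <- structure(data.frame(chromosome = 1L, haplotype = "paternal",
                               event_type = "gain", branch = "C1",
                               order_index = 2L, stringsAsFactors = FALSE),
                    class = c("cna_events", "data.frame"))
  cs <- evolve_copy_states(tree, gain, assignment)
  tot <- cs$mutant + cs$wild
  for (clone in c("C1", "C2", "C3"))
    expect_true(all(tot[clone, ] == 3L), info = clone)
  # copy states differ from the parent's only via the clone's own branch:
  # s1's extra mutant copy is carried down unchanged
  expect_equal(cs$mutant[c("C2", "C3"), "s1"], c(C2 = 2L, C3 = 2L))
})

test_that("events on exhausted haplotypes are logged no-ops", {
  tree <- clone_phylogeny(c(C1 = "Normal"), list(C1 = "s1"))
  assignment <- data.frame(snv_id = "s1", chromosome = 1L,
                           haplotype = "paternal", stringsAsFactors = FALSE)
  ev <- structure(data.frame(chromosome = 1L,
                             haplotype = c("maternal", "maternal"),
                             event_type = c("loss", "loss"), branch = "C1",
                             order_index = c(2L, 3L), stringsAsFactors = FALSE),
                  class = c("cna_events", "data.frame"))
  cs <- evolve_copy_states(tree, ev, assignment)
  expect_equal(cs$wild["C1", "s1"], 0L)
  expect_gt(length(cs$log), 0L)
})
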