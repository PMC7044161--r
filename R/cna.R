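#' Assign SNVs to chromosomes and haplotypes
#'
#' SNVs are partitioned into abstract chromosomes holding at most
#' `per_chromosome_capacity` sites (the trailing chromosome may hold fewer),
#' and each SNV is placed on either the paternal or the maternal haplotype
#' uniformly at random.  Chromosomes here are whole-haplotype copy counters,
#' without base-pair coordinates.
#'
#' @param snv_ids Non-empty character vector of SNV ids.
#' @param per_chromosome_capacity Maximum SNVs per chromosome (default 30).
#' @param seed Integer seed.
#' @return Data frame with columns `snv_id`, `chromosome` (integer) and
#'   `haplotype` (`"paternal"` or `"maternal"`).
#' @export
assign_snvs_to_haplotypes <- function(snv_ids, per_chromosome_capacity = 30L, seed) {
  if (!length(snv_ids)) stop("snv_ids must be non-empty")
  set.seed(seed)
  shuffled <- sample(snv_ids)
  chrom <- ceiling(seq_along(shuffled) / per_chromosome_capacity)
  data.frame(
    snv_id = shuffled,
    chromosome = as.integer(chrom),
    haplotype = sample(c("paternal", "maternal"), length(shuffled), replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Place CNA/LOH events on branches of a clone phylogeny
#'
#' For each chromosome a random number of events is drawn (default
#' Poisson(1)); each event is a copy-number gain, loss or LOH with equal
#' probability, strikes the paternal or maternal haplotype uniformly, and
#' occurs on a uniformly chosen branch of the phylogeny.  Within a branch,
#' events are interleaved at random positions among that branch's somatic
#' mutations; `order_index` records the event's slot in the combined
#' mutation+event sequence of its branch (mutations fill the remaining
#' slots in their stored order).
#'
#' @param tree A `clone_phylogeny`.
#' @param chromosomes Integer vector of chromosome indices (e.g.
#'   `unique(assignment$chromosome)`).
#' @param events_per_chromosome Function drawing `n` non-negative event
#'   counts; default `rpois(n, 1)`.
#' @param seed Integer seed.
#' @return Data frame of class `cna_events` with columns `chromosome`,
#'   `haplotype`, `event_type`, `branch`, `order_index`.
#' @export
place_cna_events <- function(tree, chromosomes,
                             events_per_chromosome = function(n) stats::rpois(n, 1),
                             seed) {
  validate_clone_phylogeny(tree)
  set.seed(seed)
  branches <- setdiff(tree$clone_ids, tree$root_id)
  counts <- events_per_chromosome(length(chromosomes))
  ev <- data.frame(chromosome = rep(as.integer(chromosomes), counts),
                   stringsAsFactors = FALSE)
  n <- nrow(ev)
  ev$haplotype <- if (n) sample(c("paternal", "maternal"), n, replace = TRUE) else character(0)
  ev$event_type <- if (n) sample(c("gain", "loss", "LOH"), n, replace = TRUE) else character(0)
  ev$branch <- if (n) sample(branches, n, replace = TRUE) else character(0)
  ev$order_index <- rep(NA_integer_, n)
  for (b in unique(ev$branch)) {
    idx <- which(ev$branch == b)
    total <- length(tree$branch_mutations[[b]]) + length(idx)
    ev$order_index[idx] <- sample.int(total, length(idx))
  }
  class(ev) <- c("cna_events", "data.frame")
  ev
}

# per-branch item sequence: events at their order_index slots, mutations in
# stored order filling the rest.  Items are list(kind, id) records.
branch_sequence <- function(tree, events, branch) {
  muts <- tree$branch_mutations[[branch]]
  idx <- which(events$branch == branch)
  total <- length(muts) + length(idx)
  slots <- vector("list", total)
  for (i in idx)
    slots[[events$order_index[i]]] <- list(kind = "event", row = i)
  free <- which(vapply(slots, is.null, logical(1)))
  for (j in seq_along(muts))
    slots[[free[j]]] <- list(kind = "mutation", id = muts[j])
  slots
}

#' Evolve per-clone per-SNV copy states along a phylogeny
#'
#' Replays, for every clone, the somatic mutations and CNA/LOH events of the
#' branches on its root path in their within-branch order, maintaining the
#' set of chromosome copies per chromosome.  A gain duplicates one surviving
#' copy of the affected haplotype (total +1); a loss deletes one copy; LOH
#' deletes one copy of the affected haplotype and duplicates one copy of the
#' other.  A mutation lands on the first surviving copy of its assigned
#' haplotype; if all copies of that haplotype were lost earlier, the mutant
#' copy count stays 0 (logged).  Events striking a haplotype with no
#' surviving copies are no-ops (logged), never errors.
#'
#' @param tree A `clone_phylogeny`.
#' @param events A `cna_events` data frame (may have zero rows).
#' @param assignment Output of [assign_snvs_to_haplotypes()]; must cover all
#'   SNVs of the tree.
#' @return An object of class `copy_state_table`: list with integer matrices
#'   `mutant` and `wild` (clones x SNVs, germline row included) and a
#'   character vector `log` of no-op diagnostics.
#' @export
evolve_copy_states <- function(tree, events, assignment) {
  validate_clone_phylogeny(tree)
  snvs <- tree_snvs(tree)
  missing <- setdiff(snvs, assignment$snv_id)
  if (length(missing))
    stop("assignment does not cover SNV '", missing[1], "'")
  chrom_of <- stats::setNames(assignment$chromosome, assignment$snv_id)
  hap_of <- stats::setNames(assignment$haplotype, assignment$snv_id)

  ord <- preorder_nodes(tree)
  mutant <- matrix(0L, length(ord), length(snvs), dimnames = list(ord, snvs))
  wild <- matrix(2L, length(ord), length(snvs), dimnames = list(ord, snvs))
  logs <- character(0)

  # chromosome state: list chrom -> list of copies, each copy =
  # list(hap = haplotype of origin, muts = character set carried)
  init_state <- function() {
    st <- list()
    for (k in unique(assignment$chromosome))
      st[[as.character(k)]] <- list(list(hap = "paternal", muts = character(0)),
                                    list(hap = "maternal", muts = character(0)))
    st
  }

  apply_branch <- function(state, branch) {
    for (item in branch_sequence(tree, events, branch)) {
      if (item$kind == "mutation") {
        s <- item$id
        k <- as.character(chrom_of[[s]])
        hit <- which(vapply(state[[k]], function(cp) cp$hap == hap_of[[s]], logical(1)))
        if (length(hit)) {
          state[[k]][[hit[1]]]$muts <- c(state[[k]][[hit[1]]]$muts, s)
        } else {
          logs <<- c(logs, sprintf("mutation %s: no surviving %s copy of chr %s on branch %s",
                                   s, hap_of[[s]], k, branch))
        }
      } else {
        e <- events[item$row, ]
        k <- as.character(e$chromosome)
        hit <- which(vapply(state[[k]], function(cp) cp$hap == e$haplotype, logical(1)))
        if (!length(hit)) {
          logs <<- c(logs, sprintf("%s on chr %s (%s) at branch %s: haplotype already lost, no-op",
                                   e$event_type, k, e$haplotype, branch))
          next
        }
        i <- hit[1]
        if (e$event_type == "gain") {
          state[[k]][[length(state[[k]]) + 1L]] <- state[[k]][[i]]
        } else if (e$event_type == "loss") {
          state[[k]][[i]] <- NULL
        } else { # LOH: delete affected copy, duplicate one copy of the other
          other <- setdiff(c("paternal", "maternal"), e$haplotype)
          state[[k]][[i]] <- NULL
          j <- which(vapply(state[[k]], function(cp) cp$hap == other, logical(1)))
          if (length(j)) {
            state[[k]][[length(state[[k]]) + 1L]] <- state[[k]][[j[1]]]
          } else {
            logs <<- c(logs, sprintf("LOH on chr %s at branch %s: no %s copy to duplicate",
                                     k, branch, other))
          }
        }
      }
    }
    state
  }

  record <- function(state, clone) {
    for (s in snvs) {
      k <- as.character(chrom_of[[s]])
      total <- length(state[[k]])
      mut <- sum(vapply(state[[k]], function(cp) s %in% cp$muts, logical(1)))
      mutant[clone, s] <<- as.integer(mut)
      wild[clone, s] <<- as.integer(total - mut)
    }
  }

  walk <- function(node, state) {
    if (node != tree$root_id) state <- apply_branch(state, node)
    record(state, node)
    for (ch in children_of(tree, node)) walk(ch, state)
  }
  walk(tree$root_id, init_state())

  structure(list(mutant = mutant, wild = wild, log = logs),
            class = "copy_state_table")
}

#' Copy-neutral copy-state table implied by a genotype matrix
#'
#' Every mutated site is heterozygous (1 mutant, 1 wild copy); unmutated
#' sites are diploid wild type (0, 2).
#'
#' @param genotypes Binary clone-by-SNV matrix.
#' @return A `copy_state_table`.
#' @export
neutral_copy_states <- function(genotypes) {
  M <- assert_binary_matrix(genotypes)
  storage.mode(M) <- "integer"
  structure(list(mutant = M, wild = 2L - M, log = character(0)),
            class = "copy_state_table")
}

#' @export
print.copy_state_table <- function(x, ...) {
  cat("copy_state_table: ", nrow(x$mutant), " clones x ", ncol(x$mutant),
      " SNVs; ", length(x$log), " no-op log entries\n", sep = "")
  invisible(x)
}
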