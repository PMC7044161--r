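# align two genotype matrices on the union of their SNV universes,
# treating absent SNVs as wild type (0)
align_genotypes <- function(true_genotypes, inferred_genotypes) {
  snvs <- union(colnames(true_genotypes), colnames(inferred_genotypes))
  pad <- function(M) {
    out <- matrix(0L, nrow(M), length(snvs), dimnames = list(rownames(M), snvs))
    out[, colnames(M)] <- M
    out
  }
  list(true = pad(true_genotypes), inferred = pad(inferred_genotypes))
}

#' Map inferred clones onto true clones by genotype similarity
#'
#' Two-step mapping used before tree-distance and detection scoring.
#' Step 1 greedily pairs (true, inferred) clone couples in ascending Hamming
#' distance, each clone used at most once (ties broken lexicographically by
#' true then inferred clone id).  Step 2 attaches every remaining inferred
#' clone to its most similar true clone, so the mapping is total on inferred
#' clones and may be many-to-one.  SNVs absent from either matrix are
#' treated as 0 in it.
#'
#' @param true_genotypes,inferred_genotypes Binary clones-by-SNVs matrices.
#' @return An object of class `clone_mapping`: data frame with columns
#'   `inferred`, `true`, `distance`, and logical `primary` (paired in
#'   step 1).
#' @export
map_clones <- function(true_genotypes, inferred_genotypes) {
  if (nrow(inferred_genotypes) == 0)
    stop("inferred genotype matrix is empty: method produced no clones")
  al <- align_genotypes(true_genotypes, inferred_genotypes)
  tn <- rownames(al$true)
  im <- rownames(al$inferred)
  D <- matrix(0L, length(tn), length(im), dimnames = list(tn, im))
  for (i in seq_along(tn))
    for (j in seq_along(im))
      D[i, j] <- hamming(al$true[i, ], al$inferred[j, ])

  # step 1: greedy ascending-distance pairing, deterministic tie-break
  ord_t <- order(tn)
  ord_i <- order(im)
  free_t <- rep(TRUE, length(tn))
  free_i <- rep(TRUE, length(im))
  pairs <- list()
  while (any(free_t) && any(free_i)) {
    sub <- D[free_t, free_i, drop = FALSE]
    best <- min(sub)
    hit <- NULL
    for (tcl in sort(rownames(sub))) {
      row <- stats::setNames(sub[tcl, ], colnames(sub))
      if (min(row) == best) {
        icl <- sort(names(row)[row == best])[1]
        hit <- c(tcl, icl)
        break
      }
    }
    pairs[[length(pairs) + 1L]] <-
      data.frame(inferred = hit[2], true = hit[1],
                 distance = D[hit[1], hit[2]], primary = TRUE,
                 stringsAsFactors = FALSE)
    free_t[match(hit[1], tn)] <- FALSE
    free_i[match(hit[2], im)] <- FALSE
  }

  # step 2: leftover inferred clones go to their nearest true clone
  for (icl in sort(im[free_i])) {
    col <- D[, icl]
    tcl <- sort(tn[col == min(col)])[1]
    pairs[[length(pairs) + 1L]] <-
      data.frame(inferred = icl, true = tcl, distance = min(col),
                 primary = FALSE, stringsAsFactors = FALSE)
  }
  mapping <- do.call(rbind, pairs)
  rownames(mapping) <- NULL
  class(mapping) <- c("clone_mapping", "data.frame")
  mapping
}

#' Average SNV assignment error per inferred clone
#'
#' The Hamming distance between each inferred clone genotype and its mapped
#' true clone genotype, averaged over inferred clones.  Used e.g. to rank
#' alternative solutions produced by a method.
#'
#' @param true_genotypes,inferred_genotypes Binary clones-by-SNVs matrices.
#' @param mapping A `clone_mapping` from [map_clones()] (computed if
#'   omitted).
#' @return Single number >= 0.
#' @export
snv_assignment_error <- function(true_genotypes, inferred_genotypes,
                                 mapping = map_clones(true_genotypes, inferred_genotypes)) {
  al <- align_genotypes(true_genotypes, inferred_genotypes)
  d <- vapply(seq_len(nrow(mapping)), function(r)
    hamming(al$true[mapping$true[r], ], al$inferred[mapping$inferred[r], ]),
    numeric(1))
  mean(d)
}

#' Count true ancestral clones recovered by an inference
#'
#' An ancestral clone (an internal-node clone present in at least one tumor
#' sample) counts as identified when at least one inferred clone maps to it
#' with genotype distance at most `tolerance` (default 0: exact match; the
#' threshold is configurable because "identified" admits interpretations).
#'
#' @param dataset A `clone_dataset` (provides the tree and composition).
#' @param inferred_genotypes Binary clones-by-SNVs matrix.
#' @param mapping A `clone_mapping` (computed if omitted).
#' @param tolerance Maximum genotype mismatches allowed (default 0).
#' @return Integer count of detected ancestral clones.
#' @export
count_detected_ancestral <- function(dataset, inferred_genotypes,
                                     mapping = map_clones(dataset$genotypes[colnames(dataset$composition), , drop = FALSE],
                                                          inferred_genotypes),
                                     tolerance = 0) {
  anc <- ancestral_clones(dataset)
  hit <- mapping$true[mapping$distance <= tolerance]
  sum(anc %in% hit)
}
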