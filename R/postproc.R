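# Lawson--Hanson non-negative least squares: min ||Ax - b||^2, x >= 0
nnls_solve <- function(A, b, tol = NULL, max_iter = NULL) {
  n <- ncol(A)
  tol <- tol %||% (10 * .Machine$double.eps * max(abs(A)) * max(dim(A)))
  max_iter <- max_iter %||% (30L * n)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol) {
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) break
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) {
        x <- z
        break
      }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    if (iter > max_iter) break
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Estimate clone frequencies from read counts by constrained regression
#'
#' Given predicted clone genotypes M and observed variant allele
#' frequencies V = mutant/total, recovers per-sample clone frequencies f
#' from the copy-neutral mixture relationship V = 1/2 f M by least squares
#' under f >= 0 and sum(f) <= 1 (the remainder is the normal fraction).
#' SNVs with small total (< `min_total`) or mutant (< `min_mutant`) read
#' counts are excluded from the fit as unreliable.  The constrained problem
#' is solved by active-set non-negative least squares with an explicit
#' normal-fraction slack variable.
#'
#' @param genotypes Binary clones-by-SNVs matrix (no germline row needed).
#' @param reads A `read_count_table` covering the genotype's SNVs.
#' @param min_total Minimum total read count for an SNV to enter the fit.
#' @param min_mutant Minimum mutant read count.
#' @return Samples-by-clones frequency matrix (a sample composition).  A
#'   warning is issued when the filtered design is rank deficient
#'   (frequencies not identifiable).
#' @export
estimate_clone_frequencies <- function(genotypes, reads,
                                       min_total = 50, min_mutant = 2) {
  M <- assert_binary_matrix(genotypes)
  snvs <- colnames(M)
  missing <- setdiff(snvs, colnames(reads$total))
  if (length(missing))
    stop("reads do not cover SNV '", missing[1], "'")
  samples <- rownames(reads$total)
  comp <- matrix(0, length(samples), nrow(M),
                 dimnames = list(samples, rownames(M)))
  rho <- 1e4   # weight of the sum-to-at-most-one (slack) equality row
  for (s in samples) {
    tot <- reads$total[s, snvs]
    mut <- reads$mutant[s, snvs]
    keep <- tot >= min_total & mut >= min_mutant
    if (!any(keep))
      stop("no SNV survives the read filters in sample '", s, "'")
    A <- 0.5 * t(M[, keep, drop = FALSE])
    if (qr(A)$rank < ncol(A))
      warning("rank-deficient genotype design in sample '", s,
              "': clone frequencies are not identifiable")
    v <- mut[keep] / tot[keep]
    A_aug <- rbind(cbind(A, 0), c(rep(rho, ncol(A)), rho))
    b_aug <- c(v, rho)
    x <- nnls_solve(A_aug, b_aug)
    comp[s, ] <- x[seq_len(nrow(M))]
  }
  comp
}

#' Remove spurious ancestral clones by a shared-vs-unique VAF test
#'
#' When an ancestral clone truly coexists with a descendant in a sample,
#' SNVs shared by both clones must show higher observed frequencies than
#' SNVs unique to the descendant (the ancestor adds carrier cells to shared
#' sites only).  For each sample where an ancestor and a descendant are
#' both present, the observed VAFs of shared and descendant-unique SNVs are
#' compared by a one-sided Welch t-test (shared > unique); when no such
#' test is significant (all p > `alpha`), the ancestor's presence in that
#' sample is judged spurious and removed, its frequency reassigned to the
#' nearest retained descendant present in the sample.  Tests with fewer
#' than 2 SNVs in either group are skipped and the ancestor retained.
#'
#' @param tree A `clone_phylogeny` relating the clones.
#' @param genotypes Binary clones-by-SNVs matrix.
#' @param composition Samples-by-clones frequency matrix.
#' @param reads A `read_count_table`.
#' @param alpha Significance level (default 0.05).
#' @param alternative t-test alternative, default `"greater"` (one-sided).
#' @return List with filtered `genotypes` and `composition` and a data
#'   frame `removed` (sample, clone, p-value of the least insignificant
#'   test).
#' @export
filter_spurious_ancestors <- function(tree, genotypes, composition, reads,
                                      alpha = 0.05, alternative = "greater") {
  clones <- colnames(composition)
  comp <- composition
  removed <- list()
  for (s in rownames(comp)) {
    present <- clones[comp[s, ] > 0]
    for (a in present) {
      desc <- present[vapply(present, function(d)
        d != a && a %in% root_path(tree, d), logical(1))]
      if (!length(desc)) next
      pvals <- c()
      for (d in desc) {
        shared <- colnames(genotypes)[genotypes[a, ] == 1 & genotypes[d, ] == 1]
        uniq <- colnames(genotypes)[genotypes[a, ] == 0 & genotypes[d, ] == 1]
        shared <- shared[reads$total[s, shared] > 0]
        uniq <- uniq[reads$total[s, uniq] > 0]
        if (length(shared) < 2 || length(uniq) < 2) next
        v_sh <- reads$mutant[s, shared] / reads$total[s, shared]
        v_un <- reads$mutant[s, uniq] / reads$total[s, uniq]
        pvals <- c(pvals, stats::t.test(v_sh, v_un, alternative = alternative)$p.value)
      }
      if (length(pvals) && all(pvals > alpha)) {
        # reassign frequency to the nearest retained descendant in the tree
        dist_to <- vapply(desc, function(d)
          length(root_path(tree, d)) - length(root_path(tree, a)), numeric(1))
        target <- desc[order(dist_to, desc)][1]
        comp[s, target] <- comp[s, target] + comp[s, a]
        comp[s, a] <- 0
        removed[[length(removed) + 1L]] <-
          data.frame(sample = s, clone = a, p = min(pvals),
                     stringsAsFactors = FALSE)
      }
    }
  }
  dropped <- colnames(comp)[colSums(comp) == 0 & colSums(composition) > 0]
  keep_clones <- colnames(comp)[colSums(comp) > 0 | colSums(composition) == 0]
  list(genotypes = genotypes[intersect(rownames(genotypes), keep_clones), , drop = FALSE],
       composition = comp[, keep_clones, drop = FALSE],
       removed = if (length(removed)) do.call(rbind, removed)
                 else data.frame(sample = character(0), clone = character(0), p = numeric(0)))
}

#' Discard clones at negligible frequency
#'
#' Clones below `threshold` (strict <) in a sample are removed from that
#' sample; clones removed from every sample are dropped entirely.  The
#' remaining frequencies in each sample are re-normalized to their original
#' row sum, so tumor purity is preserved.  The filter is idempotent.
#'
#' @param composition Samples-by-clones frequency matrix.
#' @param threshold Frequency cutoff (default 0.02).
#' @return Filtered samples-by-clones matrix.
#' @export
discard_rare_clones <- function(composition, threshold = 0.02) {
  check_composition(composition)
  out <- composition
  for (s in seq_len(nrow(out))) {
    drop <- out[s, ] > 0 & out[s, ] < threshold
    if (all(out[s, ] == 0 | drop))
      stop("all clones discarded in sample '", rownames(out)[s], "'")
    kept_sum <- sum(out[s, !drop])
    row_sum <- sum(out[s, ])
    out[s, drop] <- 0
    if (kept_sum > 0) out[s, ] <- out[s, ] * row_sum / kept_sum
  }
  out[, colSums(out) > 0, drop = FALSE]
}
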